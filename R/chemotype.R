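#' Chemotype calling from seed glucosinolate profiles
#'
#' Aliphatic glucosinolate (GSL) structure in *Arabidopsis thaliana* is
#' controlled by three epistatically interacting loci. `call_mam`,
#' `call_aop` and `call_gsoh` infer the functional state of each locus
#' from the relative amounts of the nine canonical short-chain aliphatic
#' GSLs, and `classify_chemotype` combines the three states into one of
#' seven discrete chemotypes:
#'
#' | MAM  | AOP      | GS-OH         | chemotype        |
#' |------|----------|---------------|------------------|
#' | MAM2 | AOP_null | (masked)      | 3MSO             |
#' | MAM1 | AOP_null | (masked)      | 4MSO             |
#' | MAM2 | AOP3     | (masked)      | 3OHP             |
#' | MAM1 | AOP3     | (masked)      | 4OHB             |
#' | MAM2 | AOP2     | (masked)      | Allyl            |
#' | MAM1 | AOP2     | nonfunctional | 3-Butenyl        |
#' | MAM1 | AOP2     | functional    | 2-OH-3-Butenyl   |
#'
#' GS-OH hydroxylates 3-Butenyl GSL; its state is phenotypically visible
#' only in accessions that make the substrate (MAM1 + AOP2 backgrounds)
#' and is reported as `"masked"` everywhere else (functional epistasis).
#'
#' @param profile named numeric vector of per-compound amounts
#'   (µmol per g seed); compounds absent from the vector count as zero.
#' @param registry compound registry, see [compound_registry()].
#' @param floor detection floor: if the short-chain aliphatic total is
#'   below this value the accession is `undetermined`. Default 0.
#' @return `call_mam`: list with `c3_total`, `c4_total`, `mam_state`
#'   (`"MAM1"`, `"MAM2"` or `"undetermined"`).
#' @examples
#' call_mam(c(Allyl = 8, `3MSO` = 1, `4MSO` = 1))
#' call_aop(c(Allyl = 8, `3MSO` = 1, `3OHP` = 1))
#' @name chemotype-calls
NULL

.profile_amounts <- function(profile, registry) {
  if (is.null(names(profile)) && length(profile) > 0) {
    stop("`profile` must be a named numeric vector of compound amounts")
  }
  if (any(profile < 0, na.rm = TRUE)) {
    stop("negative amounts in profile")
  }
  short <- registry$compound[registry$short_chain]
  amt <- stats::setNames(numeric(length(short)), short)
  hit <- intersect(names(profile), short)
  amt[hit] <- profile[hit]
  amt[is.na(amt)] <- 0
  amt
}

#' @rdname chemotype-calls
#' @export
call_mam <- function(profile, registry = compound_registry(), floor = 0) {
  .check_registry(registry)
  amt <- .profile_amounts(profile, registry)
  cl <- registry$chain_length[match(names(amt), registry$compound)]
  c3 <- sum(amt[cl == 3])
  c4 <- sum(amt[cl == 4])
  state <- if ((c3 + c4) <= floor || c3 == c4) {
    "undetermined"
  } else if (c3 > c4) "MAM2" else "MAM1"
  list(c3_total = c3, c4_total = c4, mam_state = state)
}

#' @rdname chemotype-calls
#' @details
#' `call_aop` computes three ratios with the total short-chain aliphatic
#' GSL (all nine compounds, methylthio included) as denominator:
#' alkenyl = (Allyl + 3-Butenyl + 2-OH-3-Butenyl) / total,
#' alkyl = (3OHP + 4OHB) / total, MSO = (3MSO + 4MSO) / total.
#' Because the MT compounds appear only in the denominator the three
#' ratios can sum to less than one. The expressed enzyme is the strict
#' maximum: alkenyl majority = AOP2, alkyl majority = AOP3, MSO
#' majority = AOP null; ties (or a zero denominator) are undetermined.
#' A profile whose short-chain total is more than half methylthio
#' compounds triggers an `MT-dominated` warning.
#' @export
call_aop <- function(profile, registry = compound_registry(), floor = 0) {
  .check_registry(registry)
  amt <- .profile_amounts(profile, registry)
  total <- sum(amt)
  if (total <= floor || total == 0) {
    return(list(alkenyl_ratio = NA_real_, alkyl_ratio = NA_real_,
                mso_ratio = NA_real_, aop_state = "undetermined"))
  }
  alkenyl <- (amt[["Allyl"]] + amt[["3-Butenyl"]] + amt[["2-OH-3-Butenyl"]]) / total
  alkyl <- (amt[["3OHP"]] + amt[["4OHB"]]) / total
  mso <- (amt[["3MSO"]] + amt[["4MSO"]]) / total
  mt_frac <- (amt[["3MT"]] + amt[["4MT"]]) / total
  ratios <- c(AOP2 = alkenyl, AOP3 = alkyl, AOP_null = mso)
  top <- max(ratios)
  state <- if (sum(ratios == top) > 1) "undetermined" else names(ratios)[which.max(ratios)]
  if (state != "undetermined" && mt_frac > 0.5) {
    warning("MT-dominated profile: methylthio compounds exceed half of the ",
            "short-chain total; AOP call is based on a small remainder")
  }
  list(alkenyl_ratio = unname(alkenyl), alkyl_ratio = unname(alkyl),
       mso_ratio = unname(mso), aop_state = state)
}

#' @rdname chemotype-calls
#' @param mam_state,aop_state states already called for the accession.
#' @param threshold proportion of 2-OH-3-Butenyl among the two butenyl
#'   GSLs above which GS-OH is called functional. Default 0.5.
#' @details
#' `call_gsoh` evaluates the 2-OH-3-Butenyl : 3-Butenyl balance, and only
#' for MAM1 + AOP2 accessions; all other backgrounds lack the substrate
#' and return `"masked"`. If both butenyl amounts are zero in an
#' informative background the state is `"undetermined"` with a warning.
#' @export
call_gsoh <- function(profile, mam_state, aop_state, threshold = 0.5) {
  if (!(identical(mam_state, "MAM1") && identical(aop_state, "AOP2"))) {
    return("masked")
  }
  ohb <- if ("2-OH-3-Butenyl" %in% names(profile)) profile[["2-OH-3-Butenyl"]] else 0
  but <- if ("3-Butenyl" %in% names(profile)) profile[["3-Butenyl"]] else 0
  if (ohb + but == 0) {
    warning("MAM1/AOP2 accession with no butenyl glucosinolates; ",
            "GS-OH state undetermined")
    return("undetermined")
  }
  if (ohb / (ohb + but) > threshold) "functional" else "nonfunctional"
}

#' Map enzyme states to a chemotype label
#'
#' @inheritParams chemotype-calls
#' @param gsoh_state GS-OH state (`"functional"`, `"nonfunctional"`,
#'   `"masked"` or `"undetermined"`).
#' @return one of `3MSO`, `4MSO`, `3OHP`, `4OHB`, `Allyl`, `3-Butenyl`,
#'   `2-OH-3-Butenyl`, `undetermined`.
#' @examples
#' classify_chemotype("MAM2", "AOP2", "masked") # "Allyl"
#' @export
classify_chemotype <- function(mam_state, aop_state, gsoh_state) {
  if (mam_state == "undetermined" || aop_state == "undetermined") {
    return("undetermined")
  }
  key <- paste(mam_state, aop_state, sep = "/")
  fixed <- c("MAM2/AOP_null" = "3MSO", "MAM1/AOP_null" = "4MSO",
             "MAM2/AOP3" = "3OHP", "MAM1/AOP3" = "4OHB",
             "MAM2/AOP2" = "Allyl")
  if (key %in% names(fixed)) {
    return(unname(fixed[key]))
  }
  # MAM1/AOP2: GS-OH state decides between the two butenyl chemotypes
  switch(gsoh_state,
         functional = "2-OH-3-Butenyl",
         nonfunctional = "3-Butenyl",
         "undetermined")
}

#' Call chemotypes for a whole cohort
#'
#' Runs the full enzyme-state and chemotype assignment on an
#' accession-by-compound matrix of adjusted means (see
#' [compute_emmeans()]) and tabulates chemotype frequencies.
#'
#' @param emmeans accession × compound numeric matrix (row names are
#'   accession ids, column names compound names), or an object returned
#'   by [compute_emmeans()].
#' @inheritParams chemotype-calls
#' @param gsoh_threshold passed to [call_gsoh()].
#' @return list of class `gsl_chemotypes` with
#'   * `calls`: data.frame, one row per accession, with totals, ratios,
#'     the three enzyme states and the chemotype;
#'   * `frequencies`: data.frame of chemotype counts and percentages of
#'     classified (non-`undetermined`) accessions.
#' @export
classify_all <- function(emmeans, registry = compound_registry(),
                         gsoh_threshold = 0.5, floor = 0) {
  if (inherits(emmeans, "gsl_emmeans")) {
    emmeans <- emmeans$matrix
  }
  stopifnot(is.matrix(emmeans), !is.null(rownames(emmeans)),
            !is.null(colnames(emmeans)))
  .check_registry(registry)
  x <- pmax(emmeans, 0)  # adjusted means can dip below zero on trace compounds
  calls <- lapply(rownames(x), function(acc) {
    profile <- x[acc, ]
    mam <- call_mam(profile, registry, floor = floor)
    aop <- suppressWarnings(call_aop(profile, registry, floor = floor))
    gsoh <- suppressWarnings(
      call_gsoh(profile, mam$mam_state, aop$aop_state, threshold = gsoh_threshold)
    )
    ohb <- if ("2-OH-3-Butenyl" %in% names(profile)) profile[["2-OH-3-Butenyl"]] else 0
    but <- if ("3-Butenyl" %in% names(profile)) profile[["3-Butenyl"]] else 0
    data.frame(
      accession_id = acc,
      c3_total = mam$c3_total, c4_total = mam$c4_total,
      alkenyl_ratio = aop$alkenyl_ratio, alkyl_ratio = aop$alkyl_ratio,
      mso_ratio = aop$mso_ratio,
      butenyl_oh_ratio = if (ohb + but > 0) ohb / (ohb + but) else NA_real_,
      mam_state = mam$mam_state, aop_state = aop$aop_state,
      gsoh_state = gsoh,
      chemotype = classify_chemotype(mam$mam_state, aop$aop_state, gsoh),
      stringsAsFactors = FALSE
    )
  })
  calls <- do.call(rbind, calls)
  classified <- calls$chemotype[calls$chemotype != "undetermined"]
  tab <- table(factor(classified, levels = chemotype_levels()))
  freq <- data.frame(
    chemotype = names(tab),
    count = as.integer(tab),
    percent = if (length(classified) > 0) 100 * as.integer(tab) / length(classified) else rep(NA_real_, length(tab)),
    stringsAsFactors = FALSE
  )
  structure(list(calls = calls, frequencies = freq,
                 n_classified = length(classified),
                 n_undetermined = nrow(calls) - length(classified)),
            class = "gsl_chemotypes")
}

#' The seven chemotype labels
#' @return character vector of the seven chemotype labels in pathway order.
#' @export
chemotype_levels <- function() {
  c("3MSO", "4MSO", "3OHP", "4OHB", "Allyl", "3-Butenyl", "2-OH-3-Butenyl")
}

#' @export
print.gsl_chemotypes <- function(x, ...) {
  cat("Chemotype calls for", nrow(x$calls), "accessions (",
      x$n_undetermined, "undetermined )\n")
  print(x$frequencies, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write chemotype calls and frequencies to TSV
#' @param x a `gsl_chemotypes` object.
#' @param calls_path,freq_path output paths (either may be `NULL` to skip).
#' @export
write_chemotypes <- function(x, calls_path = NULL, freq_path = NULL) {
  stopifnot(inherits(x, "gsl_chemotypes"))
  if (!is.null(calls_path)) {
    utils::write.table(x$calls, calls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(freq_path)) {
    utils::write.table(x$frequencies, freq_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}
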