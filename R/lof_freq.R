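#' Round half away from zero
#'
#' Display rounding used for the loss-of-function frequency tables
#' (base R's `round` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Split accessions by GS-OH phenotypic informativeness
#'
#' GS-OH activity is only visible in accessions that synthesize its
#' substrate, 3-Butenyl GSL: the C4-alkenyl chemotypes. These form the
#' `expressed` set (chemotype `3-Butenyl` or `2-OH-3-Butenyl`); all
#' other classified accessions form the `masked` set, where GS-OH
#' alleles are hidden by epistasis at the upstream loci. Undetermined
#' accessions belong to neither set.
#'
#' @param calls a `gsl_chemotypes` object, its `calls` data.frame, or a
#'   named chemotype vector.
#' @return list with character vectors `expressed` and `masked`.
#' @export
partition_by_epistasis <- function(calls) {
  if (inherits(calls, "gsl_chemotypes")) {
    calls <- calls$calls
  }
  if (is.data.frame(calls)) {
    calls <- stats::setNames(calls$chemotype, calls$accession_id)
  }
  expressed <- names(calls)[calls %in% c("3-Butenyl", "2-OH-3-Butenyl")]
  masked <- names(calls)[!calls %in%
                           c("3-Butenyl", "2-OH-3-Butenyl", "undetermined")]
  list(expressed = expressed, masked = masked)
}

#' Epistasis-conditioned loss-of-function frequency table
#'
#' For each mutation class, the carrier *fraction* is the number of
#' carriers among phenotypically informative (C4-alkenyl) accessions
#' divided by the size of that set, and the *observed frequency* is the
#' number of carriers among masked (non-C4-alkenyl) accessions divided
#' by the size of the masked set. Exact ratios are kept alongside
#' 3-decimal display values rounded half away from zero. A missing
#' masked carrier count (`NA`) yields an unknown observed frequency
#' rather than propagating `NaN`.
#'
#' @param carriers data.frame with columns `class`, `carriers_expressed`
#'   and `carriers_masked` (the latter may be `NA` when the masked
#'   carrier count is unknown).
#' @param n_expressed,n_masked sizes of the two sets (e.g. from
#'   [partition_by_epistasis()]).
#' @return data.frame of class `gsl_lof_table` with exact fractions,
#'   display values and the count columns.
#' @examples
#' compute_lof_frequencies(
#'   data.frame(class = "premature_stop",
#'              carriers_expressed = 2, carriers_masked = 38),
#'   n_expressed = 226, n_masked = 564)
#' @export
compute_lof_frequencies <- function(carriers, n_expressed, n_masked) {
  need <- c("class", "carriers_expressed", "carriers_masked")
  stopifnot(all(need %in% names(carriers)))
  if (n_expressed < 0 || n_masked < 0) {
    stop("set sizes must be non-negative")
  }
  if (any(carriers$carriers_expressed > n_expressed, na.rm = TRUE) ||
      any(carriers$carriers_masked > n_masked, na.rm = TRUE)) {
    stop("carrier counts exceed set sizes")
  }
  frac <- if (n_expressed > 0) {
    carriers$carriers_expressed / n_expressed
  } else {
    rep(NA_real_, nrow(carriers))
  }
  if (n_expressed == 0) {
    warning("expressed set is empty; fractions undefined")
  }
  obs <- ifelse(is.na(carriers$carriers_masked), NA_real_,
                if (n_masked > 0) carriers$carriers_masked / n_masked else NA_real_)
  out <- data.frame(
    class = carriers$class,
    carriers_expressed = carriers$carriers_expressed,
    n_expressed = n_expressed,
    fraction = frac,
    fraction_display = round_half_away(frac, 3),
    carriers_masked = carriers$carriers_masked,
    n_masked = n_masked,
    observed_frequency = obs,
    observed_frequency_display = round_half_away(obs, 3),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gsl_lof_table", "data.frame")
  out
}

#' Test enrichment of LOF alleles in the masked set
#'
#' One-sided Fisher exact test per mutation class (and pooled over the
#' classes with known masked counts) of the hypothesis that the
#' loss-of-function allele is more frequent among masked accessions
#' than among phenotypically informative ones. The odds ratio is the
#' conditional maximum-likelihood estimate from the exact test. Classes
#' with unknown masked counts are skipped; degenerate margins give
#' p = 1 with a note.
#'
#' @param table a `gsl_lof_table` from [compute_lof_frequencies()].
#' @return data.frame with one row per class plus a `pooled` row:
#'   `class`, `odds_ratio`, `p_value`, `note`.
#' @export
test_enrichment <- function(table) {
  stopifnot(inherits(table, "gsl_lof_table"))
  known <- table[!is.na(table$carriers_masked), , drop = FALSE]
  one_test <- function(cm, nm, ce, ne, label) {
    m <- matrix(c(cm, nm - cm, ce, ne - ce), nrow = 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      return(data.frame(class = label, odds_ratio = NA_real_, p_value = 1,
                        note = "degenerate margins",
                        stringsAsFactors = FALSE))
    }
    ft <- stats::fisher.test(m, alternative = "greater")
    data.frame(class = label, odds_ratio = unname(ft$estimate),
               p_value = ft$p.value, note = "", stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(known)), function(i) {
    one_test(known$carriers_masked[i], known$n_masked[i],
             known$carriers_expressed[i], known$n_expressed[i],
             known$class[i])
  })
  pooled <- one_test(sum(known$carriers_masked), known$n_masked[1],
                     sum(known$carriers_expressed), known$n_expressed[1],
                     "pooled")
  do.call(rbind, c(rows, list(pooled)))
}

#' Count mutation-class carriers in the two epistasis sets
#'
#' Turns a long carrier table (one row per carrier accession with its
#' mutation class) and an expressed/masked partition into the count
#' layout consumed by [compute_lof_frequencies()].
#'
#' @param carriers data.frame with columns `class` and `accession_id`.
#' @param partition output of [partition_by_epistasis()].
#' @return data.frame with `class`, `carriers_expressed`,
#'   `carriers_masked`.
#' @export
count_lof_carriers <- function(carriers, partition) {
  stopifnot(all(c("class", "accession_id") %in% names(carriers)))
  cls <- unique(carriers$class)
  do.call(rbind, lapply(cls, function(cl) {
    ids <- carriers$accession_id[carriers$class == cl]
    data.frame(class = cl,
               carriers_expressed = sum(ids %in% partition$expressed),
               carriers_masked = sum(ids %in% partition$masked),
               stringsAsFactors = FALSE)
  }))
}

#' Curated GS-OH loss-of-function carrier counts
#'
#' The published carrier counts of the four GS-OH lesion classes in the
#' 797-accession European panel: carriers among the 226 C4-alkenyl
#' (phenotypically informative) accessions and among the 564 other
#' classified accessions. The masked carrier count of the
#' unidentified-lesion class is unknown (`NA`).
#'
#' @return list with `carriers` (data.frame), `n_expressed`, `n_masked`.
#' @export
gsoh_lof_counts <- function() {
  path <- system.file("extdata", "gsoh_lof_carriers.tsv",
                      package = "gslchemo", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  list(carriers = tab[, c("class", "carriers_expressed", "carriers_masked")],
       n_expressed = tab$n_expressed[1],
       n_masked = tab$n_masked[1])
}
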