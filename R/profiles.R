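#' Read and validate a glucosinolate measurement table
#'
#' Long-format replicated measurements: one row per
#' (accession, replicate, plate position, compound) with the amount in
#' µmol per g seed. This is the shape in which HPLC quantifications are
#' exported after normalisation to sample weight.
#'
#' @param path TSV file with columns `accession`, `replicate`, `plate`,
#'   `compound`, `amount`.
#' @param registry compound registry used to flag unknown compounds
#'   (flagged with a warning but retained).
#' @return validated data.frame of class `gsl_measurements`.
#' @export
read_measurements <- function(path, registry = compound_registry()) {
  if (!file.exists(path)) {
    stop("measurement file not found: ", path)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(amount = "numeric"))
  validate_measurements(tab, registry = registry)
}

#' @rdname read_measurements
#' @param table a data.frame to validate in place of a file.
#' @export
validate_measurements <- function(table, registry = compound_registry()) {
  need <- c("accession", "replicate", "plate", "compound", "amount")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0) {
    stop("measurement table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!is.na(table$amount) & table$amount < 0)
  if (length(bad) > 0) {
    stop("negative amount in row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(table$accession, table$replicate, table$compound, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (accession, replicate, compound) keys, e.g. row ",
         which(duplicated(key))[1])
  }
  unknown <- setdiff(unique(table$compound), registry$compound)
  if (length(unknown) > 0) {
    warning("unknown compound(s) retained: ", paste(unknown, collapse = ", "))
  }
  class(table) <- c("gsl_measurements", "data.frame")
  table
}

#' @rdname read_measurements
#' @export
write_measurements <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fit the per-compound linear model amount ~ accession + replicate + plate,
# dropping factors with fewer than 2 levels. Returns NULL if the compound
# is observed in fewer than 2 accessions.
.fit_compound_model <- function(sub) {
  sub$accession <- factor(sub$accession)
  sub$replicate <- factor(sub$replicate)
  sub$plate <- factor(sub$plate)
  if (nlevels(sub$accession) < 2) {
    return(NULL)
  }
  terms <- "accession"
  if (nlevels(sub$replicate) > 1) terms <- c(terms, "replicate")
  if (nlevels(sub$plate) > 1) terms <- c(terms, "plate")
  form <- stats::as.formula(paste("amount ~", paste(terms, collapse = " + ")))
  stats::lm(form, data = sub)
}

#' Broad-sense heritability by ANOVA variance partitioning
#'
#' For each compound fits the fixed-effects linear model
#' `amount ~ accession + replicate + plate` (sequential ANOVA in that
#' order) and partitions the phenotypic variance into accession,
#' replicate, plate and residual components by the method of moments:
#' each factor's variance component is `(MS_factor - MS_residual) / m`
#' where `m` is the average number of observations per level of that
#' factor, truncated at zero. Broad-sense heritability is the accession
#' component divided by the component total. The sequential
#' sum-of-squares share of the accession term (eta squared) is also
#' reported; with only two replicates per accession it is strongly
#' inflated by residual noise (its null expectation is the accession
#' degrees-of-freedom share, about one half), which is why the variance
#' component ratio is the primary estimate.
#'
#' @param table a `gsl_measurements` table (see [read_measurements()]);
#'   at least 2 replicates and 2 accessions.
#' @return object of class `gsl_heritability`: data.frame with one row
#'   per compound (`h2`, variance shares summing to 1, `eta2_accession`)
#'   plus attribute `median_h2`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_accessions = 40, seed = 1))
#' h <- estimate_heritability(cohort$measurements)
#' attr(h, "median_h2")
#' @export
estimate_heritability <- function(table) {
  stopifnot(is.data.frame(table))
  if (length(unique(table$replicate)) < 2) {
    stop("heritability needs at least 2 replicates")
  }
  if (length(unique(table$accession)) < 2) {
    stop("heritability needs at least 2 accessions")
  }
  out <- lapply(split(table, table$compound), function(sub) {
    fit <- .fit_compound_model(sub)
    if (is.null(fit)) {
      warning("compound ", sub$compound[1],
              " observed in fewer than 2 accessions; skipped")
      return(NULL)
    }
    aov_tab <- stats::anova(fit)
    ms <- aov_tab[["Mean Sq"]]
    df <- aov_tab[["Df"]]
    terms <- rownames(aov_tab)
    n_obs <- nrow(sub)
    ms_res <- ms[terms == "Residuals"]
    comp <- c(accession = 0, replicate = 0, plate = 0)
    for (tm in names(comp)) {
      i <- which(terms == tm)
      if (length(i) == 1) {
        m <- n_obs / (df[i] + 1)  # average observations per level
        comp[tm] <- max(0, (ms[i] - ms_res) / m)
      }
    }
    total <- sum(comp) + ms_res
    ss <- aov_tab[["Sum Sq"]]
    data.frame(
      compound = sub$compound[1],
      h2 = comp[["accession"]] / total,
      share_accession = comp[["accession"]] / total,
      share_replicate = comp[["replicate"]] / total,
      share_plate = comp[["plate"]] / total,
      share_residual = ms_res / total,
      eta2_accession = ss[terms == "accession"] / sum(ss),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  rownames(out) <- NULL
  class(out) <- c("gsl_heritability", "data.frame")
  attr(out, "median_h2") <- stats::median(out$h2)
  out
}

#' Estimated marginal means per accession
#'
#' Adjusted per-accession means for every compound, from the same
#' `amount ~ accession + replicate + plate` model used for heritability:
#' the model prediction for each accession averaged uniformly over the
#' observed replicate and plate levels (computed with the emmeans
#' package). In a balanced design this is the arithmetic mean of the
#' accession's measurements; in unbalanced designs it corrects for
#' replicate and plate effects.
#'
#' @inheritParams estimate_heritability
#' @return object of class `gsl_emmeans`: list with `matrix`
#'   (accession × compound adjusted means) and `compounds`.
#' @export
compute_emmeans <- function(table) {
  stopifnot(is.data.frame(table))
  accessions <- sort(unique(as.character(table$accession)))
  compounds <- sort(unique(as.character(table$compound)))
  mat <- matrix(NA_real_, nrow = length(accessions), ncol = length(compounds),
                dimnames = list(accessions, compounds))
  for (cmp in compounds) {
    sub <- table[table$compound == cmp, , drop = FALSE]
    fit <- .fit_compound_model(sub)
    if (is.null(fit)) {
      warning("compound ", cmp, " observed in fewer than 2 accessions; skipped")
      next
    }
    em <- emmeans::emmeans(fit, "accession", rg.limit = 1e6)
    em <- as.data.frame(em)
    mat[as.character(em$accession), cmp] <- em$emmean
  }
  if (anyNA(mat)) {
    warning("accession/compound cells never measured set to 0")
    mat[is.na(mat)] <- 0
  }
  structure(list(matrix = mat, compounds = compounds), class = "gsl_emmeans")
}

#' @export
print.gsl_emmeans <- function(x, ...) {
  cat("Adjusted means:", nrow(x$matrix), "accessions x",
      ncol(x$matrix), "compounds\n")
  invisible(x)
}

#' Write an emmeans matrix to TSV (and read it back)
#' @param x a `gsl_emmeans` object (or its matrix).
#' @param path output path.
#' @export
write_emmeans <- function(x, path) {
  mat <- if (inherits(x, "gsl_emmeans")) x$matrix else x
  df <- data.frame(accession = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emmeans
#' @export
read_emmeans <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  structure(list(matrix = mat, compounds = colnames(mat)),
            class = "gsl_emmeans")
}

#' Principal component analysis of the accession x compound matrix
#'
#' Columns are centred and (by default) scaled to unit variance before
#' the singular value decomposition. Zero-variance columns are dropped
#' with a warning when scaling. Component signs are fixed so that the
#' largest-magnitude loading of every component is positive.
#'
#' @param emmeans a `gsl_emmeans` object or accession × compound matrix.
#' @param scale logical; divide each column by its standard deviation.
#' @return object of class `gsl_pca`: list with `scores`
#'   (accession × component), `loadings` (compound × component),
#'   `variance_explained` (proportions summing to 1, decreasing) and
#'   `center`/`scale` vectors.
#' @export
run_pca <- function(emmeans, scale = TRUE) {
  mat <- if (inherits(emmeans, "gsl_emmeans")) emmeans$matrix else emmeans
  stopifnot(is.matrix(mat), nrow(mat) >= 2, ncol(mat) >= 2)
  if (anyNA(mat)) {
    stop("PCA input has missing cells")
  }
  if (scale) {
    sds <- apply(mat, 2, stats::sd)
    if (any(sds == 0)) {
      warning("zero-variance column(s) dropped: ",
              paste(colnames(mat)[sds == 0], collapse = ", "))
      mat <- mat[, sds > 0, drop = FALSE]
    }
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale)
  scores <- pc$x
  loadings <- pc$rotation
  for (k in seq_len(ncol(loadings))) {
    if (loadings[which.max(abs(loadings[, k])), k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve,
                 center = pc$center,
                 scale = if (scale) pc$scale else NULL),
            class = "gsl_pca")
}

#' @export
print.gsl_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "accessions,", ncol(x$scores), "components\n")
  cat("Variance explained (first 5):",
      paste0(round(100 * utils::head(x$variance_explained, 5), 1), "%",
             collapse = ", "), "\n")
  invisible(x)
}
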