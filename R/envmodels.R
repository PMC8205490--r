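#' Default north/south mountain-chain boundary
#'
#' A piecewise-constant latitude-by-longitude polyline approximating the
#' Pyrenees--Alps--Carpathians chain used to split accessions into a
#' northern and a southern collection: latitude 42.5°N west of 2°E
#' (Pyrenees), 45.5°N between 2°E and 18°E (Alps), 46.5°N east of 18°E
#' (Carpathians).
#'
#' @return data.frame with columns `lon_min`, `lon_max`, `lat`.
#' @export
default_boundary <- function() {
  data.frame(
    lon_min = c(-Inf, 2, 18),
    lon_max = c(2, 18, Inf),
    lat = c(42.5, 45.5, 46.5)
  )
}

#' Assign accessions to the northern or southern collection
#'
#' An accession is `south` when its latitude is strictly below the
#' boundary latitude at its longitude, `north` otherwise (a point
#' exactly on the boundary is north). Longitudes outside the boundary's
#' range are assigned from the nearest segment with a warning.
#'
#' @param meta data.frame with `latitude` and `longitude` columns.
#' @param boundary data.frame with `lon_min`, `lon_max`, `lat` rows
#'   describing a piecewise-constant boundary; default
#'   [default_boundary()].
#' @return character vector of `"north"` / `"south"` labels.
#' @examples
#' assign_region(data.frame(latitude = 40.4, longitude = -3.7)) # south
#' @export
assign_region <- function(meta, boundary = default_boundary()) {
  stopifnot(all(c("latitude", "longitude") %in% names(meta)),
            all(c("lon_min", "lon_max", "lat") %in% names(boundary)))
  if (any(!is.finite(meta$latitude)) || any(!is.finite(meta$longitude))) {
    stop("coordinates must be finite")
  }
  boundary <- boundary[order(boundary$lon_min), , drop = FALSE]
  lat_at <- vapply(meta$longitude, function(lon) {
    i <- which(lon >= boundary$lon_min & lon < boundary$lon_max)
    if (length(i) == 0) {
      # outside the covered range: nearest segment
      warning("longitude ", lon, " outside boundary range; ",
              "using nearest segment")
      i <- if (lon < boundary$lon_min[1]) 1L else nrow(boundary)
    }
    boundary$lat[i[1]]
  }, numeric(1))
  ifelse(meta$latitude < lat_at, "south", "north")
}

.ENV_COVARS <- c("bio5", "bio6", "bio13", "bio14", "coast_distance")

#' Fit the chemotype ~ environment linear models
#'
#' Ordinary-least-squares linear models relating a binary chemotype
#' contrast to demography, geography and environment. Two responses are
#' supported:
#' * `chemotype_pair`: only Allyl and 2-OH-3-Butenyl accessions are
#'   retained; the response is 1 for 2-OH-3-Butenyl, 0 for Allyl
#'   (a linear probability model).
#' * `chain_length`: the response is the side-chain carbon number coded
#'   from the MAM state (MAM2 = 3, MAM1 = 4), all classified accessions.
#'
#' With `region_filter` `"north"` or `"south"` the model is
#' `response ~ genomic_group + bio5 + bio6 + bio13 + bio14 +
#' coast_distance` on that subset. With `"all"` the geography (region)
#' main effect and all geography × covariate and geography ×
#' genomic-group interactions are added, fitted on the pooled data.
#' Per-term p-values are Type-II partial F-tests (`car::Anova`). Factor
#' levels with fewer than 2 observations are merged into `"other"` with
#' a warning; aliased (rank-deficient) terms are reported in the
#' `aliased` field rather than silently dropped.
#'
#' @param calls data.frame with `accession_id`, `chemotype` and
#'   `mam_state` columns — either the `calls` element of
#'   [classify_all()] output or a ground-truth table with columns
#'   renamed accordingly (see [as_calls()]).
#' @param meta `AccessionMeta` data.frame with `accession_id`,
#'   `genomic_group`, the five covariates, and `region` (computed with
#'   [assign_region()] if absent).
#' @param response `"chemotype_pair"` or `"chain_length"`.
#' @param region_filter `"north"`, `"south"` or `"all"`.
#' @param boundary boundary used when `region` is missing from `meta`.
#' @return object of class `gsl_model_report`: list with `terms`
#'   (data.frame of term, df, sum of squares, F and p), `coefficients`,
#'   `n`, `response`, `region_filter`, `aliased`.
#' @export
fit_region_model <- function(calls, meta,
                             response = c("chemotype_pair", "chain_length"),
                             region_filter = c("all", "north", "south"),
                             boundary = default_boundary()) {
  response <- match.arg(response)
  region_filter <- match.arg(region_filter)
  if (is.list(calls) && !is.data.frame(calls) && !is.null(calls$calls)) {
    calls <- calls$calls
  }
  stopifnot(all(c("accession_id", "chemotype", "mam_state") %in% names(calls)))
  if (!"region" %in% names(meta)) {
    meta$region <- assign_region(meta, boundary)
  }
  dat <- merge(calls, meta, by = "accession_id")
  if (nrow(dat) == 0) {
    stop("no accessions shared between `calls` and `meta`")
  }
  if (response == "chemotype_pair") {
    dat <- dat[dat$chemotype %in% c("Allyl", "2-OH-3-Butenyl"), , drop = FALSE]
    dat$y <- as.numeric(dat$chemotype == "2-OH-3-Butenyl")
    coding <- "2-OH-3-Butenyl = 1, Allyl = 0"
  } else {
    dat <- dat[dat$mam_state %in% c("MAM1", "MAM2"), , drop = FALSE]
    dat$y <- ifelse(dat$mam_state == "MAM2", 3, 4)
    coding <- "side-chain carbons: MAM2 = 3, MAM1 = 4"
  }
  if (region_filter != "all") {
    dat <- dat[dat$region == region_filter, , drop = FALSE]
  }
  if (nrow(dat) < 10) {
    stop("too few accessions (", nrow(dat), ") for the model")
  }
  dat$genomic_group <- .merge_rare_levels(factor(dat$genomic_group))
  dat$region <- factor(dat$region)
  covars <- .ENV_COVARS
  rhs <- c("genomic_group", covars)
  if (region_filter == "all" && nlevels(dat$region) > 1) {
    rhs <- c(rhs, "region", paste("region", c("genomic_group", covars),
                                  sep = ":"))
  }
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  an <- car::Anova(fit, type = 2, singular.ok = TRUE)
  terms <- data.frame(
    term = rownames(an),
    df = an$Df,
    sumsq = an[["Sum Sq"]],
    statistic = an[["F value"]],
    p_value = an[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  terms <- terms[terms$term != "Residuals", , drop = FALSE]
  structure(list(
    terms = terms,
    coefficients = stats::coef(fit),
    n = nrow(dat),
    response = response,
    response_coding = coding,
    region_filter = region_filter,
    aliased = aliased,
    fit = fit
  ), class = "gsl_model_report")
}

# merge factor levels observed fewer than twice into "other"
.merge_rare_levels <- function(f) {
  tab <- table(f)
  rare <- names(tab)[tab < 2]
  if (length(rare) > 0) {
    warning("factor level(s) with < 2 observations merged into 'other': ",
            paste(rare, collapse = ", "))
    lv <- levels(f)
    lv[lv %in% rare] <- "other"
    levels(f) <- lv
  }
  droplevels(f)
}

#' @export
print.gsl_model_report <- function(x, ...) {
  cat("Linear model (", x$response, ", region = ", x$region_filter,
      "), n = ", x$n, "\n", sep = "")
  cat("Response coding:", x$response_coding, "\n")
  print(x$terms, row.names = FALSE, digits = 4)
  if (length(x$aliased) > 0) {
    cat("Aliased coefficients:", paste(x$aliased, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reshape a ground-truth table into the calls layout
#'
#' Utility to run [fit_region_model()] directly on simulator ground
#' truth (columns `chemotype_true` / `mam_state`).
#'
#' @param truth a `gsl_truth` data.frame.
#' @return data.frame with `accession_id`, `chemotype`, `mam_state`.
#' @export
as_calls <- function(truth) {
  data.frame(accession_id = truth$accession_id,
             chemotype = truth$chemotype_true,
             mam_state = truth$mam_state,
             stringsAsFactors = FALSE)
}

#' Write a model report to TSV
#' @param x a `gsl_model_report`.
#' @param path output path.
#' @export
write_model_report <- function(x, path) {
  stopifnot(inherits(x, "gsl_model_report"))
  utils::write.table(x$terms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
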