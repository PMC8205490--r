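#' Compound registry for short-chain aliphatic glucosinolates
#'
#' The chemotype caller needs to know, for every measured compound, its
#' side-chain carbon number and side-chain class. The default registry
#' covers the nine canonical short-chain (C3/C4) aliphatic glucosinolates
#' that determine the seven seed chemotypes, plus the common long-chain
#' aliphatic, indolic and aromatic compounds seen in seed profiles (all
#' classed `other`; they never enter a chemotype call).
#'
#' Canonical short-chain compounds and their classes:
#' * C3: 3MT (methylthio), 3MSO (methylsulfinyl), 3OHP (hydroxyalkyl),
#'   Allyl (alkenyl)
#' * C4: 4MT, 4MSO, 4OHB (hydroxyalkyl), 3-Butenyl (alkenyl),
#'   2-OH-3-Butenyl (hydroxyalkenyl)
#'
#' @param extra optional data.frame with columns `compound`,
#'   `chain_length`, `side_class`, `short_chain` appended to the default
#'   registry (e.g. for unusual compounds in a custom panel).
#' @return data.frame with columns `compound` (character),
#'   `chain_length` (integer), `side_class` (one of `MT`, `MSO`,
#'   `hydroxyalkyl`, `alkenyl`, `OH-alkenyl`, `other`) and `short_chain`
#'   (logical; `TRUE` exactly for the nine canonical C3/C4 compounds).
#' @examples
#' reg <- compound_registry()
#' reg[reg$short_chain, ]
#' @export
compound_registry <- function(extra = NULL) {
  reg <- data.frame(
    compound = c(
      "3MT", "3MSO", "3OHP", "Allyl",
      "4MT", "4MSO", "4OHB", "3-Butenyl", "2-OH-3-Butenyl",
      "5MSO", "6MSO", "7MSO", "8MSO", "5MT", "6MT", "7MT", "8MT",
      "I3M", "4OHI3M", "4MOI3M", "1MOI3M", "Benzyl", "2PE"
    ),
    chain_length = c(
      3L, 3L, 3L, 3L,
      4L, 4L, 4L, 4L, 4L,
      5L, 6L, 7L, 8L, 5L, 6L, 7L, 8L,
      NA, NA, NA, NA, NA, NA
    ),
    side_class = c(
      "MT", "MSO", "hydroxyalkyl", "alkenyl",
      "MT", "MSO", "hydroxyalkyl", "alkenyl", "OH-alkenyl",
      rep("other", 8L),
      rep("other", 6L)
    ),
    short_chain = c(rep(TRUE, 9L), rep(FALSE, 14L)),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    need <- c("compound", "chain_length", "side_class", "short_chain")
    if (!all(need %in% names(extra))) {
      stop("`extra` must have columns ", paste(need, collapse = ", "))
    }
    reg <- rbind(reg, extra[, need])
  }
  if (anyDuplicated(reg$compound)) {
    stop("duplicate compound names in registry")
  }
  reg
}

#' @keywords internal
.canonical_compounds <- function() {
  c("3MT", "3MSO", "3OHP", "Allyl",
    "4MT", "4MSO", "4OHB", "3-Butenyl", "2-OH-3-Butenyl")
}

# check a registry covers the canonical nine with the expected classes
.check_registry <- function(registry) {
  missing <- setdiff(.canonical_compounds(), registry$compound)
  if (length(missing) > 0) {
    stop("registry is missing canonical compounds: ",
         paste(missing, collapse = ", "))
  }
  invisible(registry)
}

#' Read or write a compound registry as TSV
#'
#' @param path file path.
#' @return for `read_registry`, a validated registry data.frame.
#' @seealso [compound_registry()]
#' @export
read_registry <- function(path) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("compound", "chain_length", "side_class", "short_chain")
  if (!all(need %in% names(reg))) {
    stop("registry file must have columns ", paste(need, collapse = ", "))
  }
  reg$short_chain <- as.logical(reg$short_chain)
  .check_registry(reg)
  reg
}

#' @rdname read_registry
#' @param registry a registry data.frame.
#' @export
write_registry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
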