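# shared fixtures built in code

# small balanced measurement table: `means` is accession x compound,
# replicate shifts added per replicate, same plate throughout
make_table <- function(means, rep_shift = c(0, 0), plates = NULL) {
  acc <- rownames(means)
  cmp <- colnames(means)
  rows <- expand.grid(accession = acc, replicate = seq_along(rep_shift),
                      compound = cmp, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  rows$plate <- if (is.null(plates)) "P1" else plates[rows$replicate]
  rows$amount <- means[cbind(rows$accession, rows$compound)] +
    rep_shift[rows$replicate]
  validate_measurements(rows[, c("accession", "replicate", "plate",
                                 "compound", "amount")],
                        registry = compound_registry())
}

# adjusted Rand index (independent of any clustering package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# additive distance matrix from a phylo tree (path lengths between tips)
tree_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}

# chemotype recovery fraction of a cohort
recovery_rate <- function(cohort, what = "chemotype") {
  em <- compute_emmeans(cohort$measurements)
  ct <- suppressWarnings(classify_all(em))
  truth <- cohort$truth
  idx <- match(ct$calls$accession_id, truth$accession_id)
  if (what == "chemotype") {
    mean(ct$calls$chemotype == truth$chemotype_true[idx])
  } else {
    mean(ct$calls$mam_state == truth$mam_state[idx])
  }
}
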