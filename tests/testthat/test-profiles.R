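# measurement ingestion, heritability, adjusted means, PCA

test_that("measurement validation enforces columns, keys and signs", {
  tab <- data.frame(accession = c("a", "a", "b"), replicate = c(1, 2, 1),
                    plate = "P1", compound = "Allyl", amount = c(1, 2, 3))
  expect_s3_class(validate_measurements(tab), "gsl_measurements")

  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.tsv")
  write_measurements(tab, path)
  back <- read_measurements(path)
  expect_equal(nrow(back), 3)

  expect_error(validate_measurements(tab[, -3]), "missing column")
  bad <- tab; bad$amount[2] <- -1
  expect_error(validate_measurements(bad), "negative amount")
  dup <- rbind(tab, tab[1, ])
  expect_error(validate_measurements(dup), "duplicate")
  unk <- tab; unk$compound <- "mystery"
  expect_warning(validate_measurements(unk), "unknown compound")
})

test_that("heritability is 1 with identical replicates and differing accessions", {
  means <- matrix(c(1, 5, 9, 2, 4, 8), nrow = 3,
                  dimnames = list(c("a", "b", "c"), c("Allyl", "3MSO")))
  tab <- make_table(means)
  h <- suppressWarnings(estimate_heritability(tab))
  expect_equal(h$h2, c(1, 1), tolerance = 1e-12)
  expect_equal(h$share_accession + h$share_replicate + h$share_plate +
                 h$share_residual, rep(1, 2), tolerance = 1e-9)
})

test_that("heritability is near its null expectation under pure noise", {
  # accession effect zero: variance-component estimate should sit at ~0
  # (truncation at zero leaves a small positive remainder)
  set.seed(11)
  est <- replicate(120, {
    tab <- data.frame(
      accession = rep(sprintf("a%02d", 1:30), each = 2),
      replicate = rep(1:2, 30),
      plate = "P1",
      compound = "Allyl",
      amount = rnorm(60, 10, 1)
    )
    estimate_heritability(validate_measurements(tab))$h2
  })
  expect_lt(median(est), 0.12)
  expect_lt(mean(est), 0.15)
})

test_that("simulated heritability targets are recovered within 0.05", {
  for (h_target in c(0.3, 0.8)) {
    cfg <- sim_config(n_accessions = 200, seed = 20 + round(100 * h_target),
                      heritability_target = h_target)
    coh <- simulate_cohort(cfg, sequences = FALSE)
    h <- estimate_heritability(coh$measurements)
    expect_lt(abs(attr(h, "median_h2") - h_target), 0.05)
  }
})

test_that("heritability is invariant under affine rescaling of amounts", {
  cfg <- sim_config(n_accessions = 40, seed = 13)
  coh <- simulate_cohort(cfg, sequences = FALSE)
  h1 <- estimate_heritability(coh$measurements)
  scaled <- coh$measurements
  scaled$amount <- 3.7 * scaled$amount + 2
  h2 <- estimate_heritability(scaled)
  expect_equal(h1$h2, h2$h2, tolerance = 1e-8)
})

test_that("sequential ANOVA exactly partitions the total sum of squares", {
  cfg <- sim_config(n_accessions = 25, seed = 14)
  coh <- simulate_cohort(cfg, sequences = FALSE)
  sub <- coh$measurements[coh$measurements$compound == "Allyl", ]
  sub$accession <- factor(sub$accession)
  sub$replicate <- factor(sub$replicate)
  sub$plate <- factor(sub$plate)
  fit <- lm(amount ~ accession + replicate + plate, data = sub)
  an <- anova(fit)
  total_ss <- sum((sub$amount - mean(sub$amount))^2)
  expect_equal(sum(an[["Sum Sq"]]), total_ss, tolerance = 1e-9 * total_ss)
})

test_that("adjusted means equal arithmetic means in balanced designs and
           shift by c when a constant is added", {
  means <- matrix(c(1, 5, 9, 2, 4, 8), nrow = 3,
                  dimnames = list(c("a", "b", "c"), c("Allyl", "3MSO")))
  tab <- make_table(means, rep_shift = c(0, 2))
  em <- suppressWarnings(compute_emmeans(tab))
  expect_equal(em$matrix[c("a", "b", "c"), "Allyl"],
               means[, "Allyl"] + 1, tolerance = 1e-9,
               ignore_attr = TRUE)

  shifted <- tab
  shifted$amount <- shifted$amount + 4.2
  em2 <- suppressWarnings(compute_emmeans(shifted))
  expect_equal(em2$matrix, em$matrix + 4.2, tolerance = 1e-9)
})

test_that("adjusted means correct for plate bias in unbalanced designs
           (normal-equations oracle)", {
  # accession a measured only on the biased plate P2; the adjusted mean
  # must subtract the plate effect estimated from b and c
  tab <- data.frame(
    accession = c("a", "a", "b", "b", "c", "c"),
    replicate = c(1, 2, 1, 2, 1, 2),
    plate = c("P2", "P2", "P1", "P2", "P1", "P2"),
    compound = "Allyl",
    amount = c(13, 13.4, 5, 8.2, 7, 10.2)
  )
  em <- suppressWarnings(compute_emmeans(validate_measurements(tab)))
  # explicit OLS on the same design, prediction averaged over the
  # uniform (replicate x plate) grid
  X <- model.matrix(~ accession + factor(replicate) + plate, data = tab)
  beta <- solve(t(X) %*% X, t(X) %*% tab$amount)
  grid <- expand.grid(accession = c("a", "b", "c"), replicate = 1:2,
                      plate = c("P1", "P2"))
  Xg <- model.matrix(~ accession + factor(replicate) + plate, data = grid)
  pred <- as.vector(Xg %*% beta)
  oracle <- tapply(pred, grid$accession, mean)
  expect_equal(unname(em$matrix[c("a", "b", "c"), "Allyl"]),
               as.numeric(oracle[c("a", "b", "c")]), tolerance = 1e-9)
  # the raw mean of accession a (13.2) is pulled down, since P2 is high
  expect_lt(em$matrix["a", "Allyl"], 13.2)
})

test_that("PCA: rank-1 input, eigen oracle, reconstruction, sign fix", {
  # rank-1 matrix
  x <- outer(c(1, 2, 3, 4), c(2, -1, 0.5))
  dimnames(x) <- list(paste0("a", 1:4), paste0("c", 1:3))
  p1 <- run_pca(x, scale = FALSE)
  expect_equal(p1$variance_explained[1], 1, tolerance = 1e-12)
  expect_equal(sum(p1$variance_explained), 1, tolerance = 1e-9)

  # eigen-decomposition oracle on a small matrix
  set.seed(3)
  y <- matrix(rnorm(21), 7, 3, dimnames = list(paste0("a", 1:7),
                                               paste0("c", 1:3)))
  p2 <- run_pca(y, scale = FALSE)
  ev <- eigen(cov(y), symmetric = TRUE)$values
  expect_equal(p2$variance_explained, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(p2$variance_explained) <= 1e-12))

  # reconstruction: scores %*% t(loadings) recovers the centred input
  centred <- sweep(y, 2, colMeans(y))
  expect_equal(p2$scores %*% t(p2$loadings), centred, tolerance = 1e-8)

  # sign convention: the largest-magnitude loading of each component >= 0
  for (k in seq_len(ncol(p2$loadings))) {
    expect_gte(p2$loadings[which.max(abs(p2$loadings[, k])), k], 0)
  }

  # zero-variance column dropped with a warning when scaling
  z <- cbind(y, c0 = 5)
  expect_warning(p3 <- run_pca(z, scale = TRUE), "zero-variance")
  expect_equal(ncol(p3$loadings), 3)
})

test_that("emmeans matrix round-trips through TSV", {
  cfg <- sim_config(n_accessions = 10, seed = 15)
  coh <- simulate_cohort(cfg, sequences = FALSE)
  em <- compute_emmeans(coh$measurements)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_emmeans(em, path)
  back <- read_emmeans(path)
  expect_equal(back$matrix, em$matrix, tolerance = 1e-6)
})
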