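# distances, neighbor joining, rooting, bootstrap, clade cutting

test_that("p-distances count mismatches over comparable sites", {
  aln <- c(a = "ACGT", b = "ACGA", c = "ACGT")
  d <- p_distance_matrix(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  # pairwise deletion of gaps and N
  aln2 <- c(a = "AC-T", b = "ACGT", c = "NNTT")
  d2 <- p_distance_matrix(aln2)
  expect_equal(d2["a", "b"], 0)        # 3 comparable sites, all equal
  expect_equal(d2["a", "c"], 0)        # only site 4 comparable
  expect_equal(d2["b", "c"], 0.5)      # sites 3,4: one mismatch

  # a pair with no comparable site errors with the pair named
  expect_error(p_distance_matrix(c(a = "AC--", b = "--GT", c = "ACGT")),
               "a.*b")
  expect_error(p_distance_matrix(c(a = "ACG", b = "AC")), "aligned")
})

test_that("p-distances agree with ape's raw pairwise-deletion distance", {
  cfg <- sim_config(n_accessions = 20, seed = 41)
  tr <- simulate_accessions(cfg)
  seqs <- simulate_sequences(tr, cfg)
  d <- p_distance_matrix(seqs)
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  d_ape <- as.matrix(ape::dist.dna(bin, model = "raw",
                                   pairwise.deletion = TRUE))
  expect_equal(d[rownames(d_ape), colnames(d_ape)], d_ape, tolerance = 1e-12)
})

test_that("3-taxon neighbor joining matches the closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(len[["A"]], 1, tolerance = 1e-12)
  expect_equal(len[["B"]], 1, tolerance = 1e-12)
  expect_equal(len[["C"]], 3, tolerance = 1e-12)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  d_bad <- d; d_bad[1, 2] <- 9
  expect_error(neighbor_joining(d_bad), "symmetric")
})

test_that("NJ recovers additive trees exactly (n <= 6), cross-checked
           against exhaustive least-squares topology search", {
  set.seed(42)
  for (n in 4:6) {
    for (rep in 1:5) {
      true <- ape::rtree(n, rooted = FALSE,
                         br = function(k) runif(k, 0.05, 1))
      d <- tree_distances(true)
      est <- neighbor_joining(d)
      # topology identical
      expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                   ignore_attr = TRUE)
      # additive matrices are reproduced exactly by the estimated tree
      d_est <- tree_distances(est)
      expect_equal(d_est[rownames(d), colnames(d)], d, tolerance = 1e-9)
    }
  }
  # oracle: for 4 taxa, enumerate the 3 unrooted topologies and fit
  # branch lengths by least squares; the best-fit topology must be NJ's
  true <- ape::rtree(4, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  d <- tree_distances(true)
  taxa <- rownames(d)
  topologies <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  rss <- vapply(topologies, function(tp) {
    # path matrix for ((a,b),(c,d)): edges ea, eb, ec, ed, internal
    a <- taxa[tp[1]]; b <- taxa[tp[2]]; cc <- taxa[tp[3]]; dd <- taxa[tp[4]]
    pairs <- t(combn(taxa, 2))
    A <- matrix(0, nrow(pairs), 5,
                dimnames = list(NULL, c(a, b, cc, dd, "int")))
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      A[i, p] <- 1
      split1 <- c(a, b)
      if (sum(p %in% split1) == 1) A[i, "int"] <- 1
    }
    y <- d[pairs]
    fit <- qr.solve(A, y)
    sum((y - A %*% fit)^2)
  }, numeric(1))
  best <- topologies[[which.min(rss)]]
  nj <- neighbor_joining(d)
  oracle_tree <- ape::unroot(ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
    taxa[best[1]], taxa[best[2]], taxa[best[3]], taxa[best[4]])))
  expect_equal(ape::dist.topo(oracle_tree, nj), 0, ignore_attr = TRUE)
})

test_that("NJ topology is preserved under external-branch extension", {
  set.seed(43)
  true <- ape::rtree(6, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  d <- tree_distances(true)
  # lengthening every external branch by a constant adds 2c to every
  # pairwise distance
  d2 <- d + 2 * 0.35
  diag(d2) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d2)
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("outgroup rooting is forced, idempotent and path-preserving", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  rt <- root_by_outgroup(tr, "C")
  expect_true(ape::is.rooted(rt))
  # ingroup clade (A,B)
  og_free <- ape::drop.tip(rt, "C")
  expect_setequal(og_free$tip.label, c("A", "B"))
  # idempotent
  rt2 <- root_by_outgroup(rt, "C")
  expect_equal(rt2$edge, rt$edge)
  expect_equal(rt2$edge.length, rt$edge.length)
  # tip-to-tip path lengths preserved
  expect_equal(tree_distances(rt)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  expect_error(root_by_outgroup(tr, "Z"), "not a tip")

  # larger random tree: distances preserved through rooting
  set.seed(44)
  big <- ape::rtree(8, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  rb <- root_by_outgroup(big, big$tip.label[1])
  expect_equal(tree_distances(rb)[big$tip.label, big$tip.label],
               tree_distances(big)[big$tip.label, big$tip.label],
               tolerance = 1e-9)
})

test_that("bootstrap supports are deterministic, bounded, and perfect for
           clean splits", {
  # two clearly separated clades, no homoplasy
  block_a <- paste(rep("A", 60), collapse = "")
  block_c <- paste(rep("C", 60), collapse = "")
  base <- paste(rep("G", 60), collapse = "")
  aln <- c(t1 = paste0(block_a, base), t2 = paste0(block_a, base),
           t3 = paste0(block_c, base), t4 = paste0(block_c, base))
  # one distinguishing site inside each clade so distances are not tied
  substr(aln[["t1"]], 61, 61) <- "T"
  substr(aln[["t3"]], 62, 62) <- "T"
  tr <- neighbor_joining(p_distance_matrix(aln))
  bs <- bootstrap_support(aln, tr, n_reps = 50, seed = 10)
  s <- attr(bs, "support")
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(unname(s), rep(1, length(s)))
  # determinism
  bs2 <- bootstrap_support(aln, tr, n_reps = 50, seed = 10)
  expect_equal(attr(bs2, "support"), attr(bs, "support"))
  expect_error(bootstrap_support(aln, tr, n_reps = 0), "positive")
})

test_that("bootstrap counts agree with ape's bipartition counting oracle", {
  cfg <- sim_config(n_accessions = 6, seed = 45, sequence_length = 300)
  tr <- simulate_accessions(cfg)
  seqs <- simulate_sequences(tr, cfg)
  m <- gslchemo:::.aln_matrix(seqs)
  tree <- neighbor_joining(p_distance_matrix(m))
  n_reps <- 30
  bs <- bootstrap_support(m, tree, n_reps = n_reps, seed = 77)
  # oracle: rebuild the same replicate trees and count with prop.clades
  boots <- withr::with_seed(77L, lapply(seq_len(n_reps), function(b) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    neighbor_joining(p_distance_matrix(m[, cols, drop = FALSE]))
  }))
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  support <- attr(bs, "support")
  keys <- gslchemo:::.bipartition_keys(tree, sort(tree$tip.label)[1])
  sets <- gslchemo:::.node_tip_sets(tree)
  ntip <- ape::Ntip(tree)
  for (i in seq_along(keys$nodes)) {
    node <- keys$nodes[i]
    expect_equal(unname(support[keys$keys[i]]),
                 counts[node - ntip] / n_reps)
  }
})

test_that("clade cutting spans the trivial cases and recovers the
           simulated clades", {
  cfg <- sim_config(n_accessions = 80, seed = 46)
  tr <- simulate_accessions(cfg)
  seqs <- simulate_sequences(tr, cfg)
  tree <- root_by_outgroup(neighbor_joining(p_distance_matrix(seqs)),
                           cfg$outgroup_id)
  n_in <- length(setdiff(tree$tip.label, cfg$outgroup_id))
  cl1 <- cut_clades(tree, 1)
  expect_equal(unname(unique(cl1)), 1L)
  expect_length(cl1, n_in)
  cln <- cut_clades(tree, n_in)
  expect_equal(sort(unique(cln)), seq_len(n_in))
  expect_error(cut_clades(tree, 0), "between 1")
  expect_error(cut_clades(tree, n_in + 1), "between 1")

  cl8 <- cut_clades(tree, 8)
  truth_cl <- tr$mam_clade[match(names(cl8), tr$accession_id)]
  expect_equal(adjusted_rand(cl8, truth_cl), 1)
  # outgroup excluded
  expect_false(cfg$outgroup_id %in% names(cl8))
})

test_that("clade purity scores concordance and ignores label names", {
  clades <- c(a1 = 1, a2 = 1, a3 = 1, b1 = 2, b2 = 2, b3 = 2)
  chem <- c(a1 = "Allyl", a2 = "Allyl", a3 = "Allyl",
            b1 = "3MSO", b2 = "3MSO", b3 = "3MSO")
  cc <- clade_chemotype_concordance(clades, chem)
  expect_equal(cc$overall, 1)

  mixed <- c(a1 = "Allyl", a2 = "3MSO", b1 = "Allyl", b2 = "3MSO")
  cc2 <- clade_chemotype_concordance(c(a1 = 1, a2 = 1, b1 = 2, b2 = 2), mixed)
  expect_equal(cc2$per_clade$purity, c(0.5, 0.5))
  expect_equal(cc2$overall, 0.5)

  # permuting chemotype label names leaves purity unchanged
  perm <- c(Allyl = "X", `3MSO` = "Y")
  cc3 <- clade_chemotype_concordance(c(a1 = 1, a2 = 1, b1 = 2, b2 = 2),
                                     setNames(perm[mixed], names(mixed)))
  expect_equal(cc3$overall, cc2$overall)
  expect_error(clade_chemotype_concordance(c(x = 1), c(y = "Allyl")),
               "share no accessions")
})

test_that("trees round-trip through Newick with lengths and supports", {
  cfg <- sim_config(n_accessions = 12, seed = 47)
  tr <- simulate_accessions(cfg)
  seqs <- simulate_sequences(tr, cfg)
  tree <- neighbor_joining(p_distance_matrix(seqs))
  tree <- bootstrap_support(seqs, tree, n_reps = 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- read_newick(path)
  expect_equal(ape::dist.topo(tree, back), 0, ignore_attr = TRUE)
  d1 <- tree_distances(tree)
  expect_equal(tree_distances(back)[rownames(d1), colnames(d1)], d1,
               tolerance = 1e-10)
  expect_equal(back$node.label, tree$node.label)
})
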