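#' Read and write aligned FASTA
#'
#' Thin wrappers around ape's FASTA support, returning alignments as
#' named uppercase character strings over `A,C,G,T,N,-`. All sequences
#' must be the same length.
#'
#' @param path FASTA file.
#' @param outgroup optional id recorded as the designated outgroup
#'   (attribute `outgroup`); must be present in the file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, outgroup = NULL) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    stop("sequences are not aligned: lengths differ")
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% names(seqs)) {
      stop("outgroup '", outgroup, "' not present in alignment")
    }
    attr(seqs, "outgroup") <- outgroup
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(c(paste0(">", id), seqs[[id]]), con)
  }
  invisible(path)
}

# alignment as a character matrix (rows = sequences)
.aln_matrix <- function(aln) {
  if (is.matrix(aln)) {
    return(aln)
  }
  lens <- nchar(aln)
  if (length(unique(lens)) > 1) {
    stop("sequences are not aligned: lengths differ")
  }
  m <- t(vapply(aln, function(s) strsplit(toupper(s), "")[[1]],
                character(lens[1])))
  rownames(m) <- names(aln)
  m
}

#' Pairwise p-distance matrix with pairwise deletion
#'
#' `d(i, j)` is the proportion of mismatched sites among the sites where
#' both sequences carry an unambiguous base (`A`, `C`, `G`, `T`); gaps
#' and `N` are deleted pairwise.
#'
#' @param aln named character vector of aligned sequences (or a
#'   character matrix, rows = sequences).
#' @return symmetric numeric matrix with zero diagonal.
#' @examples
#' p_distance_matrix(c(a = "ACGT", b = "ACGA", c = "ACGT"))["a", "b"]
#' @export
p_distance_matrix <- function(aln) {
  m <- .aln_matrix(aln)
  if (nrow(m) < 3) {
    stop("need at least 3 sequences")
  }
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  comparable <- valid %*% t(valid)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in c("A", "C", "G", "T")) {
    hit <- (m == b) * 1
    matches <- matches + hit %*% t(hit)
  }
  if (any(comparable[upper.tri(comparable)] == 0)) {
    bad <- which(comparable == 0 & upper.tri(comparable), arr.ind = TRUE)[1, ]
    stop("no comparable sites between '", rownames(m)[bad[1]], "' and '",
         rownames(m)[bad[2]], "'")
  }
  d <- (comparable - matches) / comparable
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighbor-joining tree
#'
#' Saitou--Nei agglomeration with the Studier--Keppler Q criterion and
#' the standard branch-length formulas. Taxa are processed in
#' lexicographic label order and Q ties are broken by the smallest
#' (row, column) index pair, so the result is fully deterministic.
#' Negative branch lengths are clamped to zero with the deficit
#' transferred to the sibling branch of the join, preserving the
#' distance between the joined pair.
#'
#' @param d symmetric distance matrix with zero diagonal and labelled
#'   rows/columns; at least 3 taxa.
#' @return unrooted `phylo` tree (class from the ape package).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighbor_joining(d)$edge.length  # 1, 1, 3
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (nrow(d) < 3) {
    stop("need at least 3 taxa")
  }
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix is not symmetric")
  }
  if (any(diag(d) != 0)) {
    stop("distance matrix diagonal must be zero")
  }
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  # each active node is represented by its (partial) newick substring
  nodes <- rownames(d)
  fmt <- function(x) sprintf("%.15g", x)
  while (length(nodes) > 3) {
    n <- length(nodes)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    hits <- which(q - qmin <= 0, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_label <- paste0("(", nodes[i], ":", fmt(li), ",",
                        nodes[j], ":", fmt(lj), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nodes <- c(nodes[keep], new_label)
    rownames(d2) <- colnames(d2) <- NULL
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  nwk <- paste0("(", nodes[1], ":", fmt(lens[1]), ",",
                nodes[2], ":", fmt(lens[2]), ",",
                nodes[3], ":", fmt(lens[3]), ");")
  ape::read.tree(text = nwk)
}

#' Root a tree on the outgroup's pendant edge
#'
#' Places the root at the midpoint of the outgroup's pendant edge; the
#' ingroup topology and all tip-to-tip path lengths are unchanged.
#' Rooting an already-rooted tree on the same outgroup is a no-op.
#'
#' @param tree a `phylo` tree containing the outgroup tip.
#' @param outgroup_id tip label of the outgroup.
#' @return rooted `phylo` tree with attribute `outgroup`.
#' @export
root_by_outgroup <- function(tree, outgroup_id) {
  stopifnot(inherits(tree, "phylo"))
  tip <- which(tree$tip.label == outgroup_id)
  if (length(tip) != 1) {
    stop("outgroup '", outgroup_id, "' is not a tip of the tree")
  }
  root_node <- ape::Ntip(tree) + 1L
  parent <- tree$edge[tree$edge[, 2] == tip, 1]
  if (ape::is.rooted(tree) && parent == root_node) {
    attr(tree, "outgroup") <- outgroup_id
    return(tree)
  }
  rt <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
  root_node <- ape::Ntip(rt) + 1L
  tip <- which(rt$tip.label == outgroup_id)
  e_og <- which(rt$edge[, 1] == root_node & rt$edge[, 2] == tip)
  e_in <- which(rt$edge[, 1] == root_node & rt$edge[, 2] != tip)
  total <- sum(rt$edge.length[c(e_og, e_in)])
  rt$edge.length[e_og] <- total / 2
  rt$edge.length[e_in] <- total / 2
  attr(rt, "outgroup") <- outgroup_id
  rt
}

# tips (labels) descending from each node; list indexed by node number
.node_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  # edges in post order: children before parents
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# canonical bipartition keys for the internal edges of a tree: the tip
# side not containing the reference tip, sorted and concatenated
.bipartition_keys <- function(tree, ref_tip) {
  sets <- .node_tip_sets(tree)
  all_tips <- sort(tree$tip.label)
  ntip <- ape::Ntip(tree)
  keys <- character(0)
  nodes <- integer(0)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    s <- sets[[node]]
    if (length(s) <= 1 || length(s) >= length(all_tips) - 1) next
    side <- if (ref_tip %in% s) setdiff(all_tips, s) else s
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, node)
  }
  list(keys = keys, nodes = nodes)
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the neighbor-joining tree from each pseudo-alignment, and scores each
#' internal edge of `tree` by the fraction of replicate trees containing
#' the same tip bipartition. Supports are stored as internal node labels
#' (root and trivial bipartitions get `NA`).
#'
#' @param aln the alignment the tree was built from.
#' @param tree the tree to annotate; if `NULL`, built from `aln` with
#'   [p_distance_matrix()] + [neighbor_joining()].
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer seed making the resampling reproducible.
#' @return `tree` with `node.label` set to supports in `[0, 1]`.
#' @export
bootstrap_support <- function(aln, tree = NULL, n_reps = 100, seed = 1L) {
  if (!is.numeric(n_reps) || n_reps < 1) {
    stop("`n_reps` must be a positive integer")
  }
  m <- .aln_matrix(aln)
  if (is.null(tree)) {
    tree <- neighbor_joining(p_distance_matrix(m))
  }
  ref_tip <- sort(tree$tip.label)[1]
  orig <- .bipartition_keys(tree, ref_tip)
  counts <- stats::setNames(rep(0, length(orig$keys)), orig$keys)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      bt <- neighbor_joining(p_distance_matrix(m[, cols, drop = FALSE]))
      bk <- unique(.bipartition_keys(bt, ref_tip)$keys)
      hit <- orig$keys %in% bk
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- counts / n_reps
  ntip <- ape::Ntip(tree)
  labels <- rep("", tree$Nnode)
  labels[orig$nodes - ntip] <- formatC(support, format = "g")
  tree$node.label <- labels
  attr(tree, "support") <- stats::setNames(support, orig$keys)
  tree
}

# connected components of the tree after deleting `removed` edge indices;
# returns component id per node
.forest_components <- function(tree, removed) {
  nn <- ape::Ntip(tree) + tree$Nnode
  keep <- setdiff(seq_len(nrow(tree$edge)), removed)
  adj <- vector("list", nn)
  for (e in keep) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(nn)
  cid <- 0L
  for (s in seq_len(nn)) {
    if (comp[s] == 0L) {
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
          if (comp[w] == 0L) {
            comp[w] <- cid
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  comp
}

#' Cut a rooted tree into k clades
#'
#' Partitions the ingroup tips into `k` clades by deleting tree edges in
#' a deterministic priority order until `k` tip groups exist. An edge
#' deletion only counts if it increases the number of groups containing
#' at least one ingroup tip, so exactly `k` clades result. Two priority
#' orders are available:
#' * `"length"` (default): longest edges first — haplotype groups
#'   diverged from a common ancestral sequence hang on long stem edges
#'   separated by a short backbone, so the longest edges are the clade
#'   stems;
#' * `"depth"`: edges closest to the root first (child node depth
#'   counted in edges), ties by edge order.
#'
#' The outgroup (attribute `outgroup` of the tree, or the `outgroup`
#' argument) is excluded from the clades.
#'
#' @param tree rooted `phylo` tree (see [root_by_outgroup()]).
#' @param k number of clades, between 1 and the number of ingroup tips.
#' @param method edge priority, `"length"` or `"depth"`.
#' @param outgroup outgroup tip label; defaults to the tree attribute.
#' @return named integer vector: clade id (1..k) per ingroup tip, in
#'   order of first appearance in the tip labels.
#' @export
cut_clades <- function(tree, k, method = c("length", "depth"),
                       outgroup = attr(tree, "outgroup")) {
  method <- match.arg(method)
  stopifnot(inherits(tree, "phylo"))
  ingroup <- setdiff(tree$tip.label, outgroup)
  if (k < 1 || k > length(ingroup)) {
    stop("`k` must be between 1 and the number of ingroup tips (",
         length(ingroup), ")")
  }
  ntip <- ape::Ntip(tree)
  ingroup_idx <- which(tree$tip.label %in% ingroup)
  og_idx <- which(tree$tip.label %in% outgroup)
  candidates <- setdiff(seq_len(nrow(tree$edge)),
                        which(tree$edge[, 2] %in% og_idx))
  if (method == "length") {
    ord <- candidates[order(-tree$edge.length[candidates])]
  } else {
    depth <- ape::node.depth.edgelength(tree)  # in branch lengths
    depth_e <- integer(ntip + tree$Nnode)
    # recompute depth in edge counts from the root
    root <- ntip + 1L
    depth_e[root] <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      depth_e[tree$edge[e, 2]] <- depth_e[tree$edge[e, 1]] + 1L
    }
    ord <- candidates[order(depth_e[tree$edge[candidates, 2]])]
  }
  removed <- integer(0)
  n_groups <- function(rm) {
    comp <- .forest_components(tree, rm)
    length(unique(comp[ingroup_idx]))
  }
  current <- 1L
  for (e in ord) {
    if (current >= k) break
    trial <- c(removed, e)
    g <- n_groups(trial)
    if (g > current) {
      removed <- trial
      current <- g
    }
  }
  if (current != k) {
    stop("could not partition the ingroup into ", k, " clades")
  }
  comp <- .forest_components(tree, removed)
  tip_comp <- comp[ingroup_idx]
  clade <- match(tip_comp, unique(tip_comp))
  stats::setNames(clade, tree$tip.label[ingroup_idx])
}

#' Clade-to-chemotype concordance
#'
#' Purity of each clade with respect to chemotype labels:
#' `purity(clade)` is the frequency of the most common chemotype within
#' the clade, and the overall score is the tip-weighted mean purity.
#'
#' @param clades named vector of clade labels (accession id -> clade).
#' @param calls named vector of chemotype labels, or a `gsl_chemotypes`
#'   object / calls data.frame.
#' @return list with `per_clade` (data.frame: clade, n, top chemotype,
#'   purity) and `overall` (weighted purity in `[0, 1]`).
#' @export
clade_chemotype_concordance <- function(clades, calls) {
  if (inherits(calls, "gsl_chemotypes")) {
    calls <- calls$calls
  }
  if (is.data.frame(calls)) {
    calls <- stats::setNames(calls$chemotype, calls$accession_id)
  }
  shared <- intersect(names(clades), names(calls))
  if (length(shared) == 0) {
    stop("clade and chemotype labels share no accessions")
  }
  cl <- clades[shared]
  ch <- calls[shared]
  per <- lapply(split(ch, cl), function(x) {
    tab <- table(x)
    data.frame(n = length(x),
               top_chemotype = names(tab)[which.max(tab)],
               purity = max(tab) / length(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  out <- data.frame(clade = names(per), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(per_clade = out,
       overall = sum(out$n * out$purity) / sum(out$n))
}

#' Write a tree as Newick (supports kept as node labels)
#' @param tree a `phylo` tree.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
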