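# Fixture builders and independent oracles used across the suite.

# quick literal count matrix: genes x cells
make_counts <- function(values, n_genes = NULL, genes = NULL, cells = NULL,
                        sample = "S") {
  m <- if (is.matrix(values)) values else
    matrix(values, nrow = if (is.null(n_genes)) length(genes) else n_genes)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  sc_counts(m, sample = sample)
}

# two well-separated Gaussian blobs in gene space, rendered as counts
two_blob_counts <- function(n_per = 60, n_genes = 60, seed = 1,
                            labels = c("A", "B")) {
  spec <- population_spec(n_populations = 2, n_genes = n_genes,
                          n_markers = 10, separation = 12)
  a <- generate_population_data(spec, n_per, seed = seed, sample = labels[1],
                                populations = rep(1L, n_per))
  b <- generate_population_data(spec, n_per, seed = seed + 1000,
                                sample = labels[2],
                                populations = rep(2L, n_per))
  list(a = a, b = b, spec = spec)
}

# random rooted binary tree with positive branch lengths and tips
# relabeled cluster1..clusterK, wrapped for the package
random_cluster_tree <- function(k, seed) {
  set.seed(seed)
  phy <- ape::rtree(k, rooted = TRUE,
                    br = function(n) stats::runif(n, 0.1, 2))
  phy$tip.label <- paste0("cluster", seq_len(k))
  phy
}

# --- independent brute-force oracle for the UniFrac distance -------------
# Walks the phylo edge table directly: descendant tips by recursion, root
# paths by parent chasing. Shares no code with the package implementation.
oracle_unifrac <- function(phy, leaf_counts) {
  k <- length(phy$tip.label)
  at <- sum(leaf_counts[, 1])
  bt <- sum(leaf_counts[, 2])
  cl_of_tip <- match(phy$tip.label, paste0("cluster", seq_len(k)))
  tips_below <- function(node) {
    if (node <= k) return(node)
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  num <- 0
  for (e in seq_len(nrow(phy$edge))) {
    idx <- cl_of_tip[tips_below(phy$edge[e, 2])]
    num <- num + phy$edge.length[e] *
      abs(sum(leaf_counts[idx, 1]) / at - sum(leaf_counts[idx, 2]) / bt)
  }
  den <- 0
  root <- k + 1
  for (tip in seq_len(k)) {
    node <- tip
    dj <- 0
    while (node != root) {
      e <- which(phy$edge[, 2] == node)
      dj <- dj + phy$edge.length[e]
      node <- phy$edge[e, 1]
    }
    idx <- cl_of_tip[tip]
    den <- den + dj * (leaf_counts[idx, 1] / at + leaf_counts[idx, 2] / bt)
  }
  num / den
}

# distance via the package for a bare tree + leaf counts
pkg_unifrac <- function(phy, leaf_counts) {
  tree <- as_sc_tree(phy)
  rownames(leaf_counts) <- paste0("cluster", seq_len(nrow(leaf_counts)))
  colnames(leaf_counts) <- c("A", "B")
  unifrac_distance(tree, count_branches(tree, leaf_counts = leaf_counts))
}
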