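#' Cluster pooled cells in the embedding space
#'
#' Agglomerative clustering of cell coordinates (average linkage on
#' Euclidean distances by default) cut to exactly `k` flat clusters. The
#' cut defines the leaves of the UniFrac cluster tree; its purpose is to
#' discern structure in the pooled landscape, not to call cell types, so
#' moderate values of k (10–30) are recommended.
#'
#' @param emb an `sc_embedding` from [embed_cells()].
#' @param k number of clusters (default 10); must satisfy `1 <= k <= n_cells`.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param metric distance metric passed to [stats::dist()].
#' @return an object of class `sc_clusters`: named integer vector `cluster`
#'   (cell -> 1..k), `k`, and the per-cell `sample` labels.
#' @export
cluster_cells <- function(emb, k = 10, linkage = "average",
                          metric = "euclidean") {
  stopifnot(inherits(emb, "sc_embedding"))
  n <- nrow(emb$coords)
  if (k < 1 || k > n) stop_input("k = %d outside 1..%d cells", k, n)
  if (k == n) {
    cl <- seq_len(n)
  } else if (k == 1) {
    cl <- rep(1L, n)
  } else {
    hc <- stats::hclust(stats::dist(emb$coords, method = metric),
                        method = linkage)
    cl <- stats::cutree(hc, k = k)
  }
  names(cl) <- rownames(emb$coords)
  stopifnot(all(tabulate(cl, k) >= 1L))
  out <- list(cluster = cl, k = as.integer(k), sample = emb$sample,
              population = emb$population)
  class(out) <- "sc_clusters"
  out
}

# leaf labels used throughout exports
cluster_labels <- function(k) paste0("cluster", seq_len(k))

# edge x tip membership matrix: entry (i, j) is 1 when tip j descends from
# edge i's child node; tips ordered cluster1..clusterK
edge_membership <- function(phy) {
  k <- length(phy$tip.label)
  n_node <- k + phy$Nnode
  below <- matrix(0, n_node, k)
  below[cbind(seq_len(k), seq_len(k))] <- 1
  eo <- stats::reorder(phy, "postorder")$edge
  for (i in seq_len(nrow(eo))) {
    below[eo[i, 1], ] <- below[eo[i, 1], ] + below[eo[i, 2], ]
  }
  m <- below[phy$edge[, 2], , drop = FALSE]
  tip_idx <- match(cluster_labels(k), phy$tip.label)
  if (anyNA(tip_idx)) stop_input("tree tips must be labeled cluster1..clusterK")
  m[, tip_idx, drop = FALSE]
}

# assemble the internal tree structure from an ape phylo object
tree_from_phylo <- function(phy, centroids = NULL, eps = 1e-12) {
  stopifnot(inherits(phy, "phylo"), !is.null(phy$edge.length))
  k <- length(phy$tip.label)
  zero <- phy$edge.length <= 0
  if (any(zero)) {
    warn_code("zero_branch", "replaced %d nonpositive branch length(s) with %g",
              sum(zero), eps)
    phy$edge.length[zero] <- eps
  }
  depth <- ape::node.depth.edgelength(phy)
  rtl <- depth[match(cluster_labels(k), phy$tip.label)]
  names(rtl) <- cluster_labels(k)
  out <- list(phylo = phy, k = k, centroids = centroids,
              branch_length = phy$edge.length,
              membership = edge_membership(phy),
              root_to_leaf = rtl,
              n_branches = nrow(phy$edge))
  class(out) <- "sc_tree"
  out
}

#' Build the cluster tree over centroids
#'
#' Computes the centroid (mean embedding coordinate) of every cluster and
#' re-clusters the centroids by average linkage on Euclidean distances. The
#' resulting dendrogram, converted to a rooted ultrametric tree, supplies
#' the topology and branch lengths for the UniFrac distance: a node sits at
#' half its merge height, each branch length is the height difference to its
#' parent, and the root-to-leaf path length of leaf j is the normalizing
#' weight d_j. Branches of zero length (identical centroids) are replaced by
#' a tiny epsilon so every branch length stays positive.
#'
#' @param emb the `sc_embedding` the cells were clustered in.
#' @param clusters an `sc_clusters` object with `k >= 2`.
#' @return an object of class `sc_tree` wrapping an [ape] `phylo` tree with
#'   tips `cluster1..clusterK`, plus `centroids`, per-edge `branch_length`,
#'   the edge-by-leaf `membership` matrix, and `root_to_leaf` path lengths.
#' @export
build_tree <- function(emb, clusters) {
  stopifnot(inherits(emb, "sc_embedding"), inherits(clusters, "sc_clusters"))
  k <- clusters$k
  if (k < 2) {
    stop_input("tree undefined for k = 1; the UniFrac distance is 0 by definition")
  }
  cl <- clusters$cluster[rownames(emb$coords)]
  centroids <- rowsum(emb$coords, cl) / as.vector(table(cl))
  rownames(centroids) <- cluster_labels(k)
  hc <- stats::hclust(stats::dist(centroids), method = "average")
  phy <- ape::as.phylo(hc)
  tree_from_phylo(phy, centroids = centroids)
}

#' Wrap an existing rooted tree for UniFrac computation
#'
#' Accepts any rooted [ape] `phylo` tree with branch lengths whose tips are
#' labeled `cluster1..clusterK` (e.g. read from Newick), for use with
#' [count_branches()] and [unifrac_distance()] independently of the
#' clustering pipeline.
#'
#' @param phy a rooted `phylo` object with branch lengths.
#' @return an `sc_tree` object.
#' @export
as_sc_tree <- function(phy) tree_from_phylo(phy)

#' @export
print.sc_tree <- function(x, ...) {
  cat(sprintf("sc_tree: %d leaves, %d branches, max root-to-leaf %.4g\n",
              x$k, x$n_branches, max(x$root_to_leaf)))
  invisible(x)
}

#' Count cells per branch per sample
#'
#' For every branch (edge) of the cluster tree, counts the cells of each
#' sample in the leaves descending from it. Leaf counts are the per-cluster
#' per-sample cell tallies; internal branch counts are the sums over their
#' descendant leaves.
#'
#' @param tree an `sc_tree`.
#' @param clusters an `sc_clusters` assignment over the pooled cells
#'   (ignored when `leaf_counts` is given).
#' @param labels per-cell sample labels; defaults to the labels stored in
#'   `clusters`. Exactly the cells of the assignment, each labeled.
#' @param leaf_counts alternatively, a ready k x n_samples matrix of leaf
#'   counts (rows ordered cluster1..clusterK).
#' @return an object of class `sc_branch_counts`: `branch` (n_branches x
#'   n_samples), `leaf` (k x n_samples), and per-sample `totals`.
#' @export
count_branches <- function(tree, clusters = NULL, labels = NULL,
                           leaf_counts = NULL) {
  stopifnot(inherits(tree, "sc_tree"))
  if (is.null(leaf_counts)) {
    stopifnot(inherits(clusters, "sc_clusters"))
    if (is.null(labels)) labels <- clusters$sample
    if (length(labels) != length(clusters$cluster) || anyNA(labels)) {
      stop_input("every cell must carry a sample label")
    }
    tab <- table(factor(clusters$cluster, seq_len(tree$k)), labels)
    leaf_counts <- matrix(as.vector(tab), nrow(tab), ncol(tab),
                          dimnames = list(cluster_labels(tree$k),
                                          colnames(tab)))
  }
  leaf_counts <- as.matrix(leaf_counts)
  if (inherits(leaf_counts, "table")) leaf_counts <- unclass(leaf_counts)
  stopifnot(nrow(leaf_counts) == tree$k)
  totals <- colSums(leaf_counts)
  if (any(totals == 0)) {
    stop_input("sample(s) with zero cells: distance undefined (%s)",
               paste(colnames(leaf_counts)[totals == 0], collapse = ", "))
  }
  branch <- tree$membership %*% leaf_counts
  out <- list(branch = branch, leaf = leaf_counts, totals = totals,
              samples = colnames(leaf_counts))
  class(out) <- "sc_branch_counts"
  out
}

#' Export the cluster tree and feature table
#'
#' Writes the cluster tree in Newick format (leaf labels
#' `cluster1..clusterK`, branch lengths retained) and the leaf-by-sample
#' abundance table as a TSV feature table, the pair of inputs microbiome
#' tools such as QIIME consume for UniFrac analyses.
#'
#' @param tree an `sc_tree`.
#' @param counts an `sc_branch_counts` for the same tree.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix; writes `<prefix>.nwk` and
#'   `<prefix>_feature_table.tsv`.
#' @return named character vector of the two paths, invisibly.
#' @export
export_tree <- function(tree, counts, dir, prefix = "cluster_tree") {
  stopifnot(inherits(tree, "sc_tree"), inherits(counts, "sc_branch_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nwk <- file.path(dir, paste0(prefix, ".nwk"))
  ape::write.tree(tree$phylo, file = nwk)
  tab <- file.path(dir, paste0(prefix, "_feature_table.tsv"))
  df <- data.frame(cluster = rownames(counts$leaf), counts$leaf,
                   check.names = FALSE)
  utils::write.table(df, tab, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(tree = nwk, feature_table = tab))
}
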