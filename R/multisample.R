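#' Pairwise sc-UniFrac distances among n samples
#'
#' Runs [compare_pair()] independently for every unordered pair of samples:
#' each pair gets its own pooled preprocessing, embedding and tree, so
#' adding a sample later does not change existing entries. Per-pair seeds
#' are derived deterministically from the global seed and the sorted pair
#' labels, so results are independent of evaluation order.
#'
#' @param samples list of [sc_counts] objects with distinct sample labels.
#' @param params an [unifrac_params()] configuration.
#' @param seed global integer seed.
#' @param keep_pairs keep the full `sc_unifrac` object of every pair
#'   (default stores only D and p to save memory).
#' @return an object of class `sc_unifrac_matrix`: `labels`, symmetric
#'   distance matrix `D` (zero diagonal), symmetric p-value matrix `P`
#'   (unit diagonal), and optionally `pairs`.
#' @export
compare_all <- function(samples, params = unifrac_params(), seed,
                        keep_pairs = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  if (missing(seed)) stop_input("`seed` is required for reproducibility")
  labels <- vapply(samples, function(s) unique(s$sample)[1], character(1))
  if (anyDuplicated(labels)) stop_input("sample labels must be distinct")
  n <- length(samples)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  P <- matrix(1, n, n, dimnames = list(labels, labels))
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      pair_seed <- derive_seed(seed, sort(c(labels[i], labels[j])))
      res <- tryCatch(
        compare_pair(samples[[i]], samples[[j]], params = params,
                     seed = pair_seed),
        error = function(e) {
          stop_input("pair (%s, %s) failed: %s", labels[i], labels[j],
                     conditionMessage(e))
        })
      D[i, j] <- D[j, i] <- res$D
      P[i, j] <- P[j, i] <- res$p_value
      if (keep_pairs) pairs[[paste(labels[i], labels[j], sep = "|")]] <- res
    }
  }
  out <- list(labels = labels, D = D, P = P,
              pairs = if (keep_pairs) pairs else NULL)
  class(out) <- "sc_unifrac_matrix"
  out
}

#' @export
print.sc_unifrac_matrix <- function(x, ...) {
  cat(sprintf("sc-UniFrac distance matrix over %d samples\n", length(x$labels)))
  print(round(x$D, 4))
  invisible(x)
}

#' Hierarchical clustering of samples by sc-UniFrac distance
#'
#' Average-linkage clustering of the samples on their pairwise distance
#' matrix, e.g. to recover the expected similarity ordering (technical
#' replicates merge before biological replicates before a different organ).
#'
#' @param dm an `sc_unifrac_matrix` from [compare_all()], or a symmetric
#'   numeric distance matrix with sample names.
#' @return a rooted [ape] `phylo` tree over the samples, with the
#'   underlying `hclust` object attached as attribute `"hclust"`.
#' @export
sample_dendrogram <- function(dm) {
  D <- if (inherits(dm, "sc_unifrac_matrix")) dm$D else as.matrix(dm)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  phy <- ape::as.phylo(hc)
  attr(phy, "hclust") <- hc
  phy
}

#' Joint cluster-by-sample counts table
#'
#' Pools all samples, runs one joint preprocessing and clustering, and
#' tabulates cell counts per joint cluster per sample, so compositional
#' shifts can be read off a single shared structure.
#'
#' @param samples list of [sc_counts] objects with distinct labels.
#' @param params an [unifrac_params()] configuration.
#' @return integer matrix (k clusters x n samples); column sums equal each
#'   sample's cell count.
#' @export
joint_counts_table <- function(samples, params = unifrac_params()) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  merged <- merge_samples(samples)
  do_norm <- params$normalize && !isTRUE(merged$continuous)
  norm <- if (do_norm) {
    normalize_counts(merged, scale_factor = params$scale_factor,
                     pseudocount = params$pseudocount)
  } else {
    as_norm_passthrough(merged)
  }
  hvg <- select_hvg(norm, n_genes = min(params$hvg_count, nrow(norm$values)))
  emb <- embed_cells(norm, hvg = hvg,
                     d = min(params$n_components, length(hvg),
                             ncol(norm$values)))
  clusters <- cluster_cells(emb, k = params$k, linkage = params$linkage,
                            metric = params$metric)
  tab <- table(factor(clusters$cluster, seq_len(clusters$k)),
               clusters$sample)
  matrix(as.vector(tab), nrow(tab), ncol(tab),
         dimnames = list(cluster_labels(clusters$k), colnames(tab)))
}
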