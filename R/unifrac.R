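#' Pipeline parameters
#'
#' Bundles the tunable parameters of the comparison pipeline with the
#' method's defaults: 500 highly variable genes, 4 principal components,
#' k = 10 clusters, 1000 label permutations, alpha = 0.05.
#'
#' @param hvg_count number of highly variable genes.
#' @param n_components number of principal components.
#' @param k number of clusters (tree leaves).
#' @param n_perm number of label permutations for the null.
#' @param alpha significance level for the distance and per-branch tests.
#' @param scale_factor library-size target; `NULL` = median library size.
#' @param pseudocount offset for the log transform.
#' @param normalize set `FALSE` for already-continuous data (e.g. CyTOF
#'   intensities or pre-normalized matrices): normalization is skipped and
#'   the values are embedded directly.
#' @param conservative_p if `TRUE`, report (1 + #\{D* >= D\})/(1 + N) instead
#'   of the raw permutation fraction #\{D* >= D\}/N (which can be 0).
#' @param linkage,metric clustering linkage and distance metric.
#' @return an object of class `unifrac_params`.
#' @export
unifrac_params <- function(hvg_count = 500, n_components = 4, k = 10,
                           n_perm = 1000, alpha = 0.05, scale_factor = NULL,
                           pseudocount = 1, normalize = TRUE,
                           conservative_p = FALSE, linkage = "average",
                           metric = "euclidean") {
  stopifnot(hvg_count >= 1, n_components >= 1, k >= 1, n_perm >= 1,
            alpha > 0, alpha < 1, pseudocount > 0,
            is.null(scale_factor) || scale_factor > 0)
  out <- list(hvg_count = hvg_count, n_components = n_components, k = k,
              n_perm = n_perm, alpha = alpha, scale_factor = scale_factor,
              pseudocount = pseudocount, normalize = normalize,
              conservative_p = conservative_p, linkage = linkage,
              metric = metric)
  class(out) <- "unifrac_params"
  out
}

#' Normalized weighted UniFrac distance on a cluster tree
#'
#' Computes
#' \deqn{D = \frac{\sum_i b_i \, |A_i/A_T - B_i/B_T|}
#'             {\sum_j d_j \, (A_j/A_T + B_j/B_T)}}
#' where the numerator runs over all branches i of the rooted cluster tree
#' (b_i the branch length, A_i/B_i the cells of each sample descending from
#' the branch) and the denominator over the leaves j, weighting each leaf's
#' relative abundance by its root-to-leaf path length d_j. The denominator
#' is the abundance-weighted average root-to-cell distance and normalizes D
#' to \[0, 1\]: D = 0 when both samples have identical per-branch
#' proportions, and D = 1 exactly when no branch carries cells of both
#' samples (fully disjoint landscapes).
#'
#' @param tree an `sc_tree`.
#' @param counts an `sc_branch_counts` with exactly two samples.
#' @return the distance, a number in \[0, 1\].
#' @export
unifrac_distance <- function(tree, counts) {
  stopifnot(inherits(tree, "sc_tree"), inherits(counts, "sc_branch_counts"))
  if (ncol(counts$branch) != 2L) {
    stop_input("unifrac_distance() needs exactly two samples, got %d",
               ncol(counts$branch))
  }
  at <- counts$totals[1]
  bt <- counts$totals[2]
  num <- sum(tree$branch_length *
               abs(counts$branch[, 1] / at - counts$branch[, 2] / bt))
  den <- sum(tree$root_to_leaf *
               (counts$leaf[, 1] / at + counts$leaf[, 2] / bt))
  stopifnot(den > 0)
  num / den
}

# leaf counts for sample A over permuted labels: k x n_perm matrix
permute_leaf_counts <- function(cluster, labels, k, n_perm) {
  lev <- levels(labels)
  la <- matrix(0L, k, n_perm)
  for (p in seq_len(n_perm)) {
    perm <- sample(labels)
    la[, p] <- tabulate(cluster[perm == lev[1]], k)
  }
  la
}

#' Permutation test of the sc-UniFrac distance
#'
#' Builds the null distribution of the distance by shuffling the sample
#' labels of the pooled cells uniformly (preserving per-sample totals) while
#' holding the tree topology, branch lengths and cluster assignments fixed.
#' The p-value is the fraction of permuted distances D* at least as large as
#' the observed D (ties count). The same permutations supply a per-branch
#' null for the proportional shift ps_i = |A_i/A_T - B_i/B_T|, used to flag
#' the branches — i.e. cell populations — whose abundance shift cannot be
#' explained by chance alone.
#'
#' @param tree an `sc_tree`.
#' @param clusters the `sc_clusters` assignment of the pooled cells.
#' @param labels per-cell sample labels (two distinct values); defaults to
#'   the labels stored in `clusters`.
#' @param n_perm number of permutations N (default 1000).
#' @param seed integer seed; the test is fully reproducible given it.
#' @param alpha significance level for the per-branch shift threshold ps*.
#' @param conservative_p see [unifrac_params()].
#' @return an object of class `sc_unifrac` with elements `D`, `p_value`,
#'   `null_distances` (length N), `n_permutations`, `seed`, `alpha`,
#'   `branches` (per-branch table with `ps`, threshold `ps_star`,
#'   `significant` flag and empirical `p_branch`), and the inputs needed to
#'   re-derive branch significance at other levels.
#' @export
permutation_test <- function(tree, clusters, labels = NULL, n_perm = 1000,
                             seed, alpha = 0.05, conservative_p = FALSE) {
  stopifnot(inherits(tree, "sc_tree"), inherits(clusters, "sc_clusters"),
            n_perm >= 1)
  if (missing(seed)) stop_input("`seed` is required for reproducibility")
  if (is.null(labels)) labels <- clusters$sample
  labels <- factor(labels)
  if (nlevels(labels) != 2L) {
    stop_input("labels must take exactly two values, got %d", nlevels(labels))
  }
  if (length(labels) != length(clusters$cluster) || anyNA(labels)) {
    stop_input("every pooled cell must carry a sample label")
  }
  obs <- count_branches(tree, clusters, labels = as.character(labels))
  d_obs <- unifrac_distance(tree, obs)
  at <- obs$totals[1]
  bt <- obs$totals[2]
  leaf_tot <- rowSums(obs$leaf)

  set.seed(seed)
  la <- permute_leaf_counts(clusters$cluster, labels, tree$k, n_perm)
  lb <- leaf_tot - la
  ba <- tree$membership %*% la
  bb <- tree$membership %*% lb
  ps_perm <- abs(ba / at - bb / bt)             # n_branches x n_perm
  den <- as.vector(tree$root_to_leaf %*% (la / at + lb / bt))
  d_star <- as.vector(tree$branch_length %*% ps_perm) / den

  n_ge <- sum(d_star >= d_obs - 1e-12)
  p <- if (conservative_p) (1 + n_ge) / (1 + n_perm) else n_ge / n_perm

  ps_obs <- abs(obs$branch[, 1] / at - obs$branch[, 2] / bt)
  result <- structure(
    list(D = d_obs, p_value = p, null_distances = d_star,
         n_permutations = n_perm, seed = seed, alpha = alpha,
         conservative_p = conservative_p,
         ps_obs = ps_obs, ps_perm = ps_perm,
         counts = obs, tree = tree, clusters = clusters,
         labels = as.character(labels)),
    class = "sc_unifrac")
  result$branches <- significant_branches(result, alpha = alpha)
  result
}

#' Per-branch shift significance
#'
#' For every branch, compares the observed proportional shift ps_i against
#' ps*, the empirical (1 - alpha) quantile of the shifts observed under the
#' stored label permutations; a branch is flagged significant when
#' ps_i > ps*. A per-branch empirical p-value (1 + #\{ps* >= ps_i\})/(N + 1)
#' is also reported, optionally Benjamini-Hochberg adjusted across branches.
#'
#' @param result an `sc_unifrac` object from [permutation_test()].
#' @param alpha significance level (default the one stored in `result`).
#' @param adjust apply BH adjustment to the per-branch p-values and flag on
#'   the adjusted values instead (off by default).
#' @return data frame with one row per branch: `branch`, `node` (tip label
#'   for terminal branches), `length`, per-sample descendant counts, `ps`,
#'   `ps_star`, `p_branch` (and `p_adj` when `adjust`), `significant`.
#' @export
significant_branches <- function(result, alpha = NULL, adjust = FALSE) {
  stopifnot(inherits(result, "sc_unifrac"))
  alpha <- alpha %||% result$alpha
  stopifnot(alpha > 0, alpha < 1)
  tree <- result$tree
  n_perm <- ncol(result$ps_perm)
  ps_star <- apply(result$ps_perm, 1, stats::quantile, probs = 1 - alpha,
                   names = FALSE)
  p_branch <- (1 + rowSums(result$ps_perm >= result$ps_obs - 1e-12)) /
    (n_perm + 1)
  child <- tree$phylo$edge[, 2]
  node <- ifelse(child <= tree$k, tree$phylo$tip.label[child],
                 paste0("node", child))
  df <- data.frame(branch = seq_len(tree$n_branches), node = node,
                   length = tree$branch_length,
                   result$counts$branch, ps = result$ps_obs,
                   ps_star = ps_star, p_branch = p_branch,
                   check.names = FALSE)
  if (adjust) {
    df$p_adj <- stats::p.adjust(df$p_branch, method = "BH")
    df$significant <- df$p_adj <= alpha
  } else {
    df$significant <- df$ps > df$ps_star
  }
  rownames(df) <- NULL
  df
}

#' @export
print.sc_unifrac <- function(x, ...) {
  cat(sprintf("sc-UniFrac distance D = %.4f (p = %.4g, %d permutations)\n",
              x$D, x$p_value, x$n_permutations))
  if (!is.null(x$branches)) {
    cat(sprintf("%d of %d branches with significant proportional shift\n",
                sum(x$branches$significant), nrow(x$branches)))
  }
  invisible(x)
}

# one empty sc_unifrac result for the k = 1 short-circuit: a single cluster
# holds both samples fully, so the numerator is identically zero
trivial_result <- function(n_perm, seed, alpha) {
  structure(list(D = 0, p_value = 1, null_distances = rep(0, n_perm),
                 n_permutations = n_perm, seed = seed, alpha = alpha,
                 conservative_p = FALSE, branches = NULL),
            class = "sc_unifrac")
}

#' Compare two single-cell samples end to end
#'
#' Runs the full pipeline: pool the two samples on shared genes, normalize
#' and log-transform (unless `normalize = FALSE`), select highly variable
#' genes, embed by PCA, cluster the pooled cells, build the centroid tree,
#' count cells per branch, compute the normalized weighted UniFrac distance,
#' and assess overall and per-branch significance by label permutation. The
#' whole run is deterministic given `seed`.
#'
#' @param sample_a,sample_b [sc_counts] objects. If both carry the same
#'   sample label, the labels are suffixed to stay distinguishable.
#' @param params an [unifrac_params()] configuration.
#' @param seed integer seed driving the permutations.
#' @return an `sc_unifrac` object (see [permutation_test()]) with the
#'   intermediate `tree`, `clusters`, `norm`alized matrix, pooled `merged`
#'   counts and `params` attached for reporting and annotation.
#' @export
compare_pair <- function(sample_a, sample_b, params = unifrac_params(), seed) {
  stopifnot(inherits(sample_a, "sc_counts"), inherits(sample_b, "sc_counts"),
            inherits(params, "unifrac_params"))
  if (missing(seed)) stop_input("`seed` is required for reproducibility")
  la <- unique(sample_a$sample)
  lb <- unique(sample_b$sample)
  if (identical(la, lb)) {
    sample_a$sample <- rep(paste0(la, ".1"), length(sample_a$sample))
    sample_b$sample <- rep(paste0(lb, ".2"), length(sample_b$sample))
  }
  merged <- merge_samples(list(sample_a, sample_b))
  do_norm <- params$normalize && !isTRUE(merged$continuous)
  norm <- if (do_norm) {
    normalize_counts(merged, scale_factor = params$scale_factor,
                     pseudocount = params$pseudocount)
  } else {
    as_norm_passthrough(merged)
  }
  hvg <- select_hvg(norm, n_genes = min(params$hvg_count, nrow(norm$values)))
  d <- min(params$n_components, length(hvg), ncol(norm$values))
  emb <- embed_cells(norm, hvg = hvg, d = d)
  if (params$k == 1) {
    warn_code("k_one", "k = 1: both samples occupy the single cluster; D = 0")
    res <- trivial_result(params$n_perm, seed, params$alpha)
  } else {
    clusters <- cluster_cells(emb, k = params$k, linkage = params$linkage,
                              metric = params$metric)
    tree <- build_tree(emb, clusters)
    res <- permutation_test(tree, clusters, n_perm = params$n_perm,
                            seed = seed, alpha = params$alpha,
                            conservative_p = params$conservative_p)
  }
  res$norm <- norm
  res$merged <- merged
  res$embedding <- emb
  res$params <- params
  res
}
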