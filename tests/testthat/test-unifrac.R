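star_tree <- function() {
  as_sc_tree(ape::read.tree(text = "(cluster1:1,cluster2:1);"))
}

test_that("identical per-branch proportions give distance zero", {
  tree <- as_sc_tree(random_cluster_tree(5, 4))
  lc <- cbind(A = c(3, 1, 4, 1, 5), B = 2 * c(3, 1, 4, 1, 5))
  rownames(lc) <- paste0("cluster", 1:5)
  expect_equal(unifrac_distance(tree, count_branches(tree, leaf_counts = lc)),
               0)
})

test_that("hand-worked star-tree distances are reproduced", {
  tree <- star_tree()
  d1 <- unifrac_distance(tree, count_branches(tree,
          leaf_counts = cbind(A = c(10, 0), B = c(0, 10))))
  expect_equal(d1, 1, tolerance = 1e-12)
  d2 <- unifrac_distance(tree, count_branches(tree,
          leaf_counts = cbind(A = c(8, 2), B = c(2, 8))))
  expect_equal(d2, 0.6, tolerance = 1e-12)
})

test_that("distance matches the brute-force oracle on random instances", {
  cases <- 0
  for (k in 2:5) {
    for (seed in 1:5) {
      phy <- random_cluster_tree(k, seed * 10 + k)
      set.seed(seed * 100 + k)
      for (r in 1:8) {
        lc <- cbind(sample(0:5, k, replace = TRUE),
                    sample(0:5, k, replace = TRUE))
        if (any(colSums(lc) == 0)) next
        expect_equal(pkg_unifrac(phy, lc), oracle_unifrac(phy, lc),
                     tolerance = 1e-12)
        cases <- cases + 1
      }
    }
  }
  expect_gt(cases, 100)
})

test_that("distance lies in [0, 1] on randomized trees and counts", {
  set.seed(77)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    phy <- random_cluster_tree(k, i)
    lc <- cbind(rpois(k, 3), rpois(k, 3))
    if (any(colSums(lc) == 0)) next
    d <- pkg_unifrac(phy, lc)
    expect_gte(d, 0)
    expect_lte(d, 1 + 1e-9)
  }
})

test_that("fully disjoint samples reach the maximal distance exactly", {
  # every branch pure requires the root split to separate the samples:
  # assign all tips under the root's first child to A, the rest to B
  set.seed(31)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    phy <- random_cluster_tree(k, 1000 + i)
    tips_below <- function(node) {
      if (node <= k) return(node)
      kids <- phy$edge[phy$edge[, 1] == node, 2]
      unlist(lapply(kids, tips_below))
    }
    first_child <- phy$edge[phy$edge[, 1] == k + 1, 2][1]
    tips_a <- tips_below(first_child)
    in_a <- match(phy$tip.label, paste0("cluster", 1:k)) %in%
      match(phy$tip.label[tips_a], paste0("cluster", 1:k))
    lc <- cbind(ifelse(in_a, rpois(k, 3) + 1, 0),
                ifelse(in_a, 0, rpois(k, 3) + 1))
    expect_equal(pkg_unifrac(phy, lc), 1, tolerance = 1e-12)
  }
})

test_that("distance agrees with phyloseq's normalized weighted UniFrac", {
  for (i in 1:10) {
    k <- 4 + (i %% 3)
    phy <- random_cluster_tree(k, 500 + i)
    set.seed(600 + i)
    lc <- cbind(A = rpois(k, 5) + 1, B = rpois(k, 5) + 1)
    rownames(lc) <- paste0("cluster", 1:k)
    otu <- phyloseq::otu_table(lc, taxa_are_rows = TRUE)
    ps <- phyloseq::phyloseq(otu, phyloseq::phy_tree(phy))
    ref <- as.numeric(phyloseq::UniFrac(ps, weighted = TRUE,
                                        normalized = TRUE))
    expect_equal(pkg_unifrac(phy, lc), ref, tolerance = 1e-9)
  }
})

test_that("swapping the samples leaves the distance unchanged", {
  fix <- two_blob_counts(n_per = 30, n_genes = 40, seed = 6)
  par <- unifrac_params(k = 6, n_perm = 100)
  r_ab <- compare_pair(fix$a, fix$b, params = par, seed = 3)
  r_ba <- compare_pair(fix$b, fix$a, params = par, seed = 3)
  expect_equal(r_ab$D, r_ba$D, tolerance = 1e-12)
  expect_setequal(r_ab$branches$ps, r_ba$branches$ps)
})

test_that("permutation test is reproducible and p = 1 at distance zero", {
  fix <- two_blob_counts(n_per = 25, n_genes = 30, seed = 12)
  par <- unifrac_params(k = 4, n_perm = 200)
  r1 <- compare_pair(fix$a, fix$a, params = par, seed = 5)
  expect_identical(r1$D, 0)
  expect_identical(r1$p_value, 1)
  r2 <- compare_pair(fix$a, fix$b, params = par, seed = 9)
  r3 <- compare_pair(fix$a, fix$b, params = par, seed = 9)
  expect_identical(r2$null_distances, r3$null_distances)
  expect_identical(r2$p_value, r3$p_value)
})

test_that("conservative p-value never returns zero", {
  fix <- two_blob_counts(n_per = 25, n_genes = 30, seed = 13)
  par <- unifrac_params(k = 4, n_perm = 50, conservative_p = TRUE)
  r <- compare_pair(fix$a, fix$b, params = par, seed = 2)
  expect_gte(r$p_value, 1 / 51)
})

test_that("identical samples flag no branches; disjoint flag all pure ones", {
  fix <- two_blob_counts(n_per = 40, n_genes = 50, seed = 21)
  par <- unifrac_params(k = 6, n_perm = 200)
  same <- compare_pair(fix$a, fix$a, params = par, seed = 7)
  expect_equal(same$branches$ps, rep(0, nrow(same$branches)))
  expect_false(any(same$branches$significant))
  diff <- compare_pair(fix$a, fix$b, params = par, seed = 7)
  expect_equal(diff$D, 1, tolerance = 1e-9)
  # every branch is unshared (pure); all carrying a nontrivial share of
  # cells are flagged (leaves of one or two stray cells can sit inside the
  # permutation null and legitimately escape the flag)
  pure <- diff$branches[, "A"] == 0 | diff$branches[, "B"] == 0
  expect_true(all(pure))
  big <- rowSums(diff$branches[, c("A", "B")]) >= 10
  expect_true(all(diff$branches$significant[big]))
})

test_that("a planted abundance shift is detected on the right branch", {
  spec <- population_spec(n_populations = 2, n_genes = 60, n_markers = 10,
                          separation = 12)
  hits <- 0
  reps <- 10
  for (i in seq_len(reps)) {
    a <- generate_population_data(spec, 200, seed = 3000 + i, sample = "A",
                                  populations = rep(1:2, c(140, 60)))
    b <- generate_population_data(spec, 200, seed = 4000 + i, sample = "B",
                                  populations = rep(1L, 200))
    r <- compare_pair(a, b, params = unifrac_params(k = 4, n_perm = 200),
                      seed = i)
    # leaves holding the A-only population must be flagged for the bulk of
    # its cells (single stray cells may land in unflagged micro-leaves)
    leaf_of_cell <- r$clusters$cluster
    pop2_cells <- names(leaf_of_cell)[!is.na(r$merged$population) &
                                        r$merged$population == "pop2"]
    pop2_leaves <- paste0("cluster", leaf_of_cell[pop2_cells])
    flagged <- r$branches$node[r$branches$significant]
    if (mean(pop2_leaves %in% flagged) >= 0.8) hits <- hits + 1
  }
  expect_gte(hits, reps - 1)
})

test_that("k = 1 short-circuits to distance zero", {
  fix <- two_blob_counts(n_per = 15, n_genes = 20, seed = 17)
  expect_warning(
    r <- compare_pair(fix$a, fix$b, params = unifrac_params(k = 1, n_perm = 10),
                      seed = 1),
    "k_one")
  expect_identical(r$D, 0)
  expect_identical(r$p_value, 1)
})
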