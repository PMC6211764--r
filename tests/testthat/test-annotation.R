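norm_from_matrix <- function(values, sample = "S") {
  structure(list(values = values, sample = rep(sample, ncol(values))),
            class = "sc_norm")
}

clusters_from_vector <- function(cl, cells) {
  names(cl) <- cells
  structure(list(cluster = cl, k = max(cl), sample = rep("S", length(cl))),
            class = "sc_clusters")
}

test_that("a null cluster yields (almost) no signature genes", {
  set.seed(1)
  n_genes <- 1000
  m <- matrix(rnorm(n_genes * 60, 1, 0.5), n_genes,
              dimnames = list(sprintf("g%04d", 1:n_genes), paste0("c", 1:60)))
  norm <- norm_from_matrix(m)
  cl <- clusters_from_vector(rep(1:2, each = 30), colnames(m))
  sig <- cluster_signatures(norm, cl, fdr = 0.05)
  flagged <- sig$signature[sig$cluster == "cluster1"]
  expect_lte(mean(flagged), 0.05)
})

test_that("planted shifted genes are recovered as overexpressed", {
  set.seed(2)
  n_genes <- 200
  m <- matrix(rnorm(n_genes * 200, 0, 0.5), n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes), paste0("c", 1:200)))
  m[1:10, 1:100] <- m[1:10, 1:100] + 2
  norm <- norm_from_matrix(m)
  cl <- clusters_from_vector(rep(1:2, each = 100), colnames(m))
  sig <- cluster_signatures(norm, cl, fdr = 0.05, min_abs_lfc = 0.5)
  hits <- sig[sig$cluster == "cluster1" & sig$signature, ]
  expect_setequal(hits$gene, sprintf("g%03d", 1:10))
  expect_true(all(hits$direction == "over"))
})

test_that("signature direction flips when the complement is tested", {
  set.seed(3)
  m <- matrix(rnorm(50 * 40, 0, 0.3), 50,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:40)))
  m[1:5, 1:20] <- m[1:5, 1:20] + 3
  norm <- norm_from_matrix(m)
  cl <- clusters_from_vector(rep(1:2, each = 20), colnames(m))
  sig <- cluster_signatures(norm, cl)
  s1 <- sig[sig$cluster == "cluster1" & sig$gene %in% paste0("g", 1:5), ]
  s2 <- sig[sig$cluster == "cluster2" & sig$gene %in% paste0("g", 1:5), ]
  expect_true(all(s1$direction == "over"))
  expect_true(all(s2$direction == "under"))
  expect_equal(s1$lfc, -s2$lfc, tolerance = 1e-12)
})

test_that("tiny clusters are reported untested", {
  m <- matrix(rnorm(20 * 10), 20,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  norm <- norm_from_matrix(m)
  cl <- clusters_from_vector(c(rep(1L, 8), 2L, 2L), colnames(m))
  sig <- cluster_signatures(norm, cl, min_cells = 3)
  expect_true(all(!sig$tested[sig$cluster == "cluster2"]))
  expect_true(all(!sig$signature[sig$cluster == "cluster2"]))
})

test_that("Pearson matching reproduces hand-computed correlations", {
  q <- matrix(c(1, 2, 3), 3, 1,
              dimnames = list(c("g1", "g2", "g3"), "cell1"))
  atlas <- sc_atlas(matrix(c(2, 4, 6, 3, 2, 1), 3,
                           dimnames = list(c("g1", "g2", "g3"),
                                           c("typeUp", "typeDown"))))
  norm <- norm_from_matrix(q)
  res <- match_to_atlas(norm, atlas = atlas, min_overlap = 3)
  expect_equal(unname(res$correlations["cell1", c("typeUp", "typeDown")]),
               c(1, -1), tolerance = 1e-12)
  expect_equal(res$best$type, "typeUp")
})

test_that("correlations are affine-invariant and bounded", {
  set.seed(4)
  genes <- sprintf("g%03d", 1:300)
  ref <- matrix(rnorm(300 * 4), 300, dimnames = list(genes, paste0("t", 1:4)))
  atlas <- sc_atlas(ref)
  q <- matrix(rnorm(300 * 5), 300, dimnames = list(genes, paste0("c", 1:5)))
  r1 <- match_to_atlas(norm_from_matrix(q), atlas = atlas, min_overlap = 100)
  r2 <- match_to_atlas(norm_from_matrix(3 * q + 7), atlas = atlas,
                       min_overlap = 100)
  expect_equal(r1$correlations, r2$correlations, tolerance = 1e-9)
  expect_true(all(abs(r1$correlations) <= 1 + 1e-12))
})

test_that("a query equal to an atlas profile is its best match", {
  set.seed(5)
  genes <- sprintf("g%03d", 1:250)
  ref <- matrix(rexp(250 * 3), 250, dimnames = list(genes, c("tA", "tB", "tC")))
  atlas <- sc_atlas(ref)
  q <- matrix(ref[, "tB"], 250, 1, dimnames = list(genes, "q1"))
  res <- match_to_atlas(norm_from_matrix(q), atlas = atlas, min_overlap = 200)
  expect_equal(res$best$type, "tB")
  expect_equal(res$best$correlation, 1, tolerance = 1e-12)
  # several cells at once stay aligned with their own profiles
  q3 <- ref[, c("tC", "tA", "tB")] + matrix(rnorm(750, 0, 1e-3), 250)
  colnames(q3) <- c("q_c", "q_a", "q_b")
  res3 <- match_to_atlas(norm_from_matrix(q3), atlas = atlas,
                         min_overlap = 200)
  expect_equal(res3$best$type[match(c("q_a", "q_b", "q_c"), res3$best$cell)],
               c("tA", "tB", "tC"))
})

test_that("zero-variance query cells are unmatchable, not errors", {
  genes <- sprintf("g%03d", 1:250)
  ref <- matrix(rnorm(250 * 2), 250, dimnames = list(genes, c("t1", "t2")))
  q <- cbind(flat = rep(1, 250), ok = rnorm(250))
  rownames(q) <- genes
  expect_warning(
    res <- match_to_atlas(norm_from_matrix(q), atlas = sc_atlas(ref),
                          min_overlap = 200),
    "unmatchable")
  expect_true(is.na(res$best$type[res$best$cell == "flat"]))
  expect_false(is.na(res$best$type[res$best$cell == "ok"]))
})

test_that("match_to_atlas enforces the minimum gene overlap", {
  ref <- matrix(rnorm(20), 10,
                dimnames = list(paste0("g", 1:10), c("t1", "t2")))
  q <- matrix(rnorm(10), 10, 1, dimnames = list(paste0("g", 1:10), "c1"))
  expect_error(match_to_atlas(norm_from_matrix(q), atlas = sc_atlas(ref),
                              min_overlap = 50),
               "genes shared")
})

test_that("atlas files round-trip and duplicate genes collapse by mean", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tt1\tt2", "g1\t2\t1", "g2\t5\t0", "g1\t4\t3"), path)
  expect_warning(atlas <- read_atlas(path), "atlas_dup_genes")
  expect_equal(atlas$profiles["g1", c("t1", "t2")], c(t1 = 3, t2 = 2))
  expect_equal(atlas$profiles["g2", "t1"], 5)
  # clean round trip
  path2 <- withr::local_tempfile(fileext = ".csv")
  ref <- matrix(1:15, 5, dimnames = list(paste0("g", 1:5), paste0("t", 1:3)))
  write.csv(data.frame(gene = rownames(ref), ref), path2, row.names = FALSE)
  atlas2 <- read_atlas(path2)
  expect_equal(unname(atlas2$profiles), unname(ref), ignore_attr = TRUE)
  expect_equal(atlas2$type_names, c("t1", "t2", "t3"))
})
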