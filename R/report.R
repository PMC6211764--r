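# Report generation: machine-readable JSON/TSV artifacts for pairwise,
# multi-sample and simulation runs. Each stage is logged with its timing so
# runs are auditable; warnings carry stable bracketed codes.

log_stage <- function(stage, t0) {
  message(sprintf("[stage:%s] done in %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

resolve_input <- function(x, format = "auto") {
  if (inherits(x, "sc_counts")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_counts(x, format = format))
  stop_input("inputs must be sc_counts objects or file paths")
}

params_echo <- function(params, seed, inputs = NULL) {
  c(unclass(params), list(seed = seed, inputs = inputs))
}

write_tsv <- function(df, path, rowname_col = NULL) {
  if (!is.null(rowname_col)) {
    df <- data.frame(setNames(list(rownames(df)), rowname_col),
                     as.data.frame(df), check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Pairwise comparison report
#'
#' Runs [compare_pair()] and writes the full report to `outdir`:
#' `summary.json` (distance, p-value, seed, significant branches, config
#' echo), `branches.tsv`, the cluster tree (`cluster_tree.nwk`) with its
#' feature table, per-cluster gene signatures (`signatures.tsv`), the
#' cell-type match table (`matches.tsv`, when an atlas is given, for cells
#' in clusters with significant shifts), and `config.json` sufficient to
#' reproduce the run.
#'
#' @param sample_a,sample_b [sc_counts] objects or input paths.
#' @param outdir output directory (created).
#' @param params an [unifrac_params()] configuration.
#' @param seed integer seed.
#' @param atlas optional `sc_atlas` or atlas file path.
#' @param log_atlas see [match_to_atlas()].
#' @param format input format passed to [read_counts()] for path inputs.
#' @return the `sc_unifrac` result, invisibly.
#' @export
run_pairwise_report <- function(sample_a, sample_b, outdir,
                                params = unifrac_params(), seed,
                                atlas = NULL, log_atlas = FALSE,
                                format = "auto") {
  if (missing(seed)) stop_input("`seed` is required for reproducibility")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  a <- resolve_input(sample_a, format)
  b <- resolve_input(sample_b, format)
  log_stage("read", t0)

  t0 <- as.numeric(Sys.time())
  res <- compare_pair(a, b, params = params, seed = seed)
  log_stage("compare", t0)

  t0 <- as.numeric(Sys.time())
  if (!is.null(res$branches)) {
    write_tsv(res$branches, file.path(outdir, "branches.tsv"))
    export_tree(res$tree, res$counts, outdir)
  }
  summary <- list(
    distance = res$D, p_value = res$p_value,
    n_permutations = res$n_permutations, seed = seed,
    samples = unique(res$merged$sample),
    n_cells = as.list(table(res$merged$sample)),
    n_shared_genes = nrow(res$merged$counts),
    significant_branches = if (is.null(res$branches)) character(0) else
      res$branches$node[res$branches$significant],
    config = params_echo(params, seed))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(params_echo(params, seed),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("summary", t0)

  if (!is.null(res$branches)) {
    t0 <- as.numeric(Sys.time())
    sig <- cluster_signatures(res$norm, res$clusters, fdr = params$alpha)
    write_tsv(sig, file.path(outdir, "signatures.tsv"))
    log_stage("signatures", t0)

    if (!is.null(atlas)) {
      t0 <- as.numeric(Sys.time())
      if (is.character(atlas)) atlas <- read_atlas(atlas)
      leaf_sig <- res$branches$node[res$branches$significant &
                                      res$branches$node %in%
                                      cluster_labels(res$tree$k)]
      sig_clusters <- match(leaf_sig, cluster_labels(res$tree$k))
      cells <- names(res$clusters$cluster)[res$clusters$cluster %in%
                                             sig_clusters]
      if (length(cells)) {
        mt <- match_to_atlas(res$norm, cells, atlas, log_atlas = log_atlas)
        write_tsv(mt$best, file.path(outdir, "matches.tsv"))
      } else {
        message("[stage:atlas] no significant leaf clusters; no match table")
      }
      log_stage("atlas", t0)
    }
  }
  invisible(res)
}

#' Multi-sample comparison report
#'
#' Runs [compare_all()] and writes `distance_matrix.tsv`,
#' `pvalue_matrix.tsv`, the sample dendrogram (`sample_dendrogram.nwk`),
#' the joint cluster-by-sample counts table (`cluster_counts.tsv`) and the
#' config echo to `outdir`.
#'
#' @param samples list of [sc_counts] objects or input paths.
#' @param outdir output directory.
#' @param params an [unifrac_params()] configuration.
#' @param seed global integer seed.
#' @param format input format for path inputs.
#' @return the `sc_unifrac_matrix`, invisibly.
#' @export
run_multi_report <- function(samples, outdir, params = unifrac_params(),
                             seed, format = "auto") {
  if (missing(seed)) stop_input("`seed` is required for reproducibility")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  samples <- lapply(samples, resolve_input, format = format)

  t0 <- as.numeric(Sys.time())
  dm <- compare_all(samples, params = params, seed = seed)
  log_stage("pairwise", t0)

  t0 <- as.numeric(Sys.time())
  write_tsv(dm$D, file.path(outdir, "distance_matrix.tsv"), "sample")
  write_tsv(dm$P, file.path(outdir, "pvalue_matrix.tsv"), "sample")
  ape::write.tree(sample_dendrogram(dm),
                  file.path(outdir, "sample_dendrogram.nwk"))
  counts <- joint_counts_table(samples, params = params)
  write_tsv(counts, file.path(outdir, "cluster_counts.tsv"), "cluster")
  jsonlite::write_json(params_echo(params, seed),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("export", t0)
  invisible(dm)
}

#' Simulation report from a YAML design
#'
#' Reads a plain-text (YAML) design describing the population model and
#' the grids, runs [run_sensitivity()] (and [run_imbalance()] when an
#' `n2_grid` is present), and writes the tidy per-run table, the summary
#' table, and a config echo with all resolved seeds.
#'
#' Recognized keys (all optional, shown with defaults): `n_genes` (500),
#' `n_markers` (20), `spread` (0.5), `separation` (10), `mode` ("counts"),
#' `pool_size` (2000), `n1` (1000), `n2` (n1), `proportions`
#' (0, 0.02, 0.05, 0.1, 0.25, 0.5, 1), `k_grid` (10), `n2_grid`, `runs`
#' (50), `alpha` (0.05), `n_perm` (1000), `seed` (1).
#'
#' @param config path to the YAML design file, or an equivalent named list.
#' @param outdir output directory.
#' @return the tidy results data frame, invisibly.
#' @export
run_simulation_report <- function(config, outdir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  get <- function(key, default) cfg[[key]] %||% default
  seed <- get("seed", 1L)
  spec <- population_spec(n_populations = 2,
                          n_genes = get("n_genes", 500),
                          n_markers = get("n_markers", 20),
                          spread = get("spread", 0.5),
                          separation = get("separation", 10),
                          mode = get("mode", "counts"))
  pool_size <- get("pool_size", 2000)
  pool_a <- generate_population_data(spec, pool_size,
                                     seed = derive_seed(seed, "poolA"),
                                     sample = "poolA",
                                     populations = rep(1L, pool_size))
  pool_b <- generate_population_data(spec, pool_size,
                                     seed = derive_seed(seed, "poolB"),
                                     sample = "poolB",
                                     populations = rep(2L, pool_size))
  params <- unifrac_params(k = get("k", 10), n_perm = get("n_perm", 1000),
                           alpha = get("alpha", 0.05),
                           normalize = spec$mode == "counts")
  n1 <- get("n1", 1000)
  tidy <- run_sensitivity(pool_a, pool_b,
                          proportions = get("proportions",
                                            c(0, 0.02, 0.05, 0.1, 0.25, 0.5, 1)),
                          k_grid = get("k_grid", params$k),
                          n1 = n1, n2 = get("n2", n1),
                          runs = get("runs", 50), params = params,
                          seed = derive_seed(seed, "sensitivity"))
  if (!is.null(cfg$n2_grid)) {
    imb <- run_imbalance(pool_a, pool_b,
                         proportions = get("proportions", c(0, 0.02, 0.05, 0.1)),
                         n2_grid = cfg$n2_grid, n1 = n1,
                         runs = get("runs", 50), params = params,
                         seed = derive_seed(seed, "imbalance"))
    tidy <- rbind(tidy, imb)
  }
  write_tsv(tidy, file.path(outdir, "runs.tsv"))
  write_tsv(summarize_runs(tidy), file.path(outdir, "summary.tsv"))
  echo <- c(cfg, list(resolved_seed = seed,
                      pool_seed_a = derive_seed(seed, "poolA"),
                      pool_seed_b = derive_seed(seed, "poolB")))
  jsonlite::write_json(echo, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tidy)
}
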