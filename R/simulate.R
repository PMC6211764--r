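#' Specify a synthetic multi-population single-cell model
#'
#' Defines well-separated populations in latent (log-expression) space.
#' Each population elevates its own disjoint block of `n_markers` marker
#' genes above the shared baseline; cells scatter around their population
#' center with isotropic Gaussian noise of standard deviation `spread` per
#' gene. The geometry is controlled by the separation ratio — the Euclidean
#' distance between population centers divided by the per-gene spread —
#' which equals `marker_effect * sqrt(2 * n_markers) / spread`. Either the
#' ratio or the marker effect can be given; the other is solved for.
#'
#' In `"counts"` mode cells are rendered as UMI counts: the latent profile
#' is exponentiated to rates, scaled to a log-normally drawn library size,
#' and Poisson-sampled, emulating shallow droplet scRNA-seq. In
#' `"continuous"` mode the latent profiles are emitted directly (no count
#' sampling), emulating mass-cytometry-like continuous intensities to be
#' analyzed with `normalize = FALSE`.
#'
#' @param n_populations number of populations.
#' @param n_genes genes per cell (default 500).
#' @param n_markers marker genes per population (disjoint blocks).
#' @param spread per-gene latent standard deviation (log-units).
#' @param separation center separation as a multiple of `spread`
#'   (default 10: essentially non-overlapping clouds).
#' @param marker_effect alternatively, the latent elevation (log-units) of
#'   a population's markers; overrides `separation`.
#' @param base_level baseline latent log-expression.
#' @param lib_size_meanlog,lib_size_sdlog log-normal library-size law.
#' @param mode `"counts"` or `"continuous"` (see above).
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_populations = 2, n_genes = 500, n_markers = 20,
                            spread = 0.5, separation = 10,
                            marker_effect = NULL, base_level = 0,
                            lib_size_meanlog = log(2500),
                            lib_size_sdlog = 0.3,
                            mode = c("counts", "continuous")) {
  mode <- match.arg(mode)
  stopifnot(n_populations >= 1, n_markers >= 1, spread > 0,
            n_populations * n_markers <= n_genes)
  # Separation is promised in the space where cells are compared, not in the
  # latent space. Two corrections bridge the gap. (1) Readout: in counts
  # mode the log1p(count) readout compresses the latent marker contrast and
  # adds Poisson noise; a delta-method model of the readout gives the
  # realized per-gene contrast and variance (in continuous mode the latent
  # values are the readout). (2) Embedding: the PC directions a pooled PCA
  # finds are partly fit to sampling noise, which inflates the apparent
  # per-direction cloud spread by roughly the Marchenko-Pastur edge factor
  # 1 + sqrt(p/n); the yardstick uses n = 1000 pooled cells, the typical
  # analysis scale for this tool. The marker effect is solved so that the
  # center separation equals `separation` times the inflated spread.
  readout_ratio <- function(effect) {
    noise_inflation <- 1 + sqrt(n_genes / 1000)
    if (mode == "continuous") {
      return(effect * sqrt(2 * n_markers) / (spread * noise_inflation))
    }
    lib <- exp(lib_size_meanlog)
    r0 <- lib / (n_genes + n_markers * (exp(effect) - 1))
    r1 <- r0 * exp(effect)
    dv <- log((1 + r1) / (1 + r0))
    vr <- function(r) spread^2 * (r / (1 + r))^2 + r / (1 + r)^2
    dv * sqrt(2 * n_markers) / (sqrt((vr(r0) + vr(r1)) / 2) * noise_inflation)
  }
  if (is.null(marker_effect)) {
    stopifnot(separation > 0)
    marker_effect <- stats::uniroot(function(e) readout_ratio(e) - separation,
                                    c(1e-6, 50), tol = 1e-10)$root
  } else {
    separation <- readout_ratio(marker_effect)
  }
  centers <- matrix(base_level, n_genes, n_populations,
                    dimnames = list(sprintf("gene%04d", seq_len(n_genes)),
                                    sprintf("pop%d", seq_len(n_populations))))
  for (p in seq_len(n_populations)) {
    idx <- ((p - 1) * n_markers + 1):(p * n_markers)
    centers[idx, p] <- base_level + marker_effect
  }
  out <- list(n_populations = n_populations, n_genes = n_genes,
              n_markers = n_markers, spread = spread,
              separation = separation, marker_effect = marker_effect,
              base_level = base_level, centers = centers,
              lib_size_meanlog = lib_size_meanlog,
              lib_size_sdlog = lib_size_sdlog, mode = mode)
  class(out) <- "population_spec"
  out
}

#' Generate synthetic single-cell data
#'
#' Draws cells from the populations of a [population_spec()] and renders
#' them as counts or continuous values. Per-cell population memberships are
#' stored in the result's `population` field as ground truth.
#'
#' @param spec a `population_spec`.
#' @param n_cells number of cells.
#' @param seed integer seed; generation is fully reproducible.
#' @param sample sample label for the cells.
#' @param populations per-cell population indices; default cycles through
#'   the populations for a balanced draw (requires
#'   `n_cells >= n_populations`).
#' @return an [sc_counts] object (`continuous = TRUE` in continuous mode).
#' @export
generate_population_data <- function(spec, n_cells, seed, sample = "sim",
                                     populations = NULL) {
  stopifnot(inherits(spec, "population_spec"), n_cells >= 1)
  if (missing(seed)) stop_input("`seed` is required for reproducibility")
  if (is.null(populations)) {
    if (n_cells < spec$n_populations) {
      stop_input("n_cells = %d < %d populations for a balanced draw",
                 n_cells, spec$n_populations)
    }
    populations <- rep(seq_len(spec$n_populations), length.out = n_cells)
  }
  stopifnot(length(populations) == n_cells,
            all(populations %in% seq_len(spec$n_populations)))
  set.seed(seed)
  latent <- spec$centers[, populations, drop = FALSE] +
    matrix(stats::rnorm(spec$n_genes * n_cells, 0, spec$spread),
           spec$n_genes, n_cells)
  colnames(latent) <- sprintf("%s_cell%05d", sample, seq_len(n_cells))
  if (spec$mode == "continuous") {
    return(sc_counts(latent, sample = sample,
                     population = sprintf("pop%d", populations),
                     continuous = TRUE))
  }
  lib <- stats::rlnorm(n_cells, spec$lib_size_meanlog, spec$lib_size_sdlog)
  rates <- exp(latent)
  rates <- sweep(rates, 2, lib / colSums(rates), `*`)
  counts <- matrix(stats::rpois(length(rates), rates),
                   spec$n_genes, n_cells, dimnames = dimnames(latent))
  sc_counts(counts, sample = sample,
            population = sprintf("pop%d", populations))
}

#' Draw a mixture pair from two cell pools
#'
#' Emulates the mixture scheme used for sensitivity evaluation: sample N1
#' holds `n1` cells drawn from pool A only, while sample N2 holds
#' `round(proportion * n2)` cells from pool B (round-half-up) topped up to
#' `n2` with pool A cells. Sampling is without replacement within the draw.
#'
#' @param pool_a,pool_b [sc_counts] pools to draw from.
#' @param n1,n2 sample sizes.
#' @param proportion fraction of pool-B cells in N2, in \[0, 1\].
#' @param seed integer seed.
#' @return list with elements `N1` and `N2` ([sc_counts], labeled "N1" and
#'   "N2") and the realized `n_b` count of pool-B cells in N2.
#' @export
sample_mixture <- function(pool_a, pool_b, n1, n2, proportion, seed) {
  stopifnot(inherits(pool_a, "sc_counts"), inherits(pool_b, "sc_counts"),
            proportion >= 0, proportion <= 1, n1 >= 1, n2 >= 1)
  if (missing(seed)) stop_input("`seed` is required for reproducibility")
  n_b <- round_half_up(proportion * n2)
  n_a2 <- n2 - n_b
  if (n1 + n_a2 > ncol(pool_a$counts)) {
    stop_input("pool A has %d cells; %d needed", ncol(pool_a$counts), n1 + n_a2)
  }
  if (n_b > ncol(pool_b$counts)) {
    stop_input("pool B has %d cells; %d needed", ncol(pool_b$counts), n_b)
  }
  set.seed(seed)
  idx_a <- sample(ncol(pool_a$counts), n1 + n_a2)
  idx_b <- if (n_b > 0) sample(ncol(pool_b$counts), n_b) else integer(0)
  n1_cells <- subset_cells(pool_a, idx_a[seq_len(n1)], sample = "N1")
  n2_a <- subset_cells(pool_a, idx_a[n1 + seq_len(n_a2)])
  n2_b <- subset_cells(pool_b, idx_b)
  n2_counts <- cbind(n2_a$counts, n2_b$counts)
  colnames(n2_counts) <- paste0("N2_", seq_len(ncol(n2_counts)))
  n2_cells <- sc_counts(n2_counts, sample = "N2",
                        population = c(n2_a$population, n2_b$population),
                        continuous = isTRUE(pool_a$continuous))
  list(N1 = n1_cells, N2 = n2_cells, n_b = n_b)
}

run_grid <- function(pool_a, pool_b, grid, n1, runs, params, alpha, seed) {
  rows <- vector("list", nrow(grid) * runs)
  idx <- 0L
  for (g in seq_len(nrow(grid))) {
    p <- grid$proportion[g]
    k <- grid$k[g]
    n2 <- grid$n2[g]
    par_g <- params
    par_g$k <- k
    for (r in seq_len(runs)) {
      s <- derive_seed(seed, sprintf("%g|%d|%d|%d", p, k, n2, r))
      mix <- sample_mixture(pool_a, pool_b, n1 = n1, n2 = n2,
                            proportion = p, seed = s)
      res <- compare_pair(mix$N1, mix$N2, params = par_g,
                          seed = derive_seed(s, "perm"))
      idx <- idx + 1L
      rows[[idx]] <- data.frame(proportion = p, k = k, n1 = n1, n2 = n2,
                                run = r, n_b = mix$n_b, D = res$D,
                                p = res$p_value,
                                significant = res$p_value < alpha)
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity experiment over a mixture-proportion grid
#'
#' For every (proportion, k) grid point, repeatedly draws an (N1, N2)
#' mixture pair via [sample_mixture()], runs [compare_pair()], and records
#' the distance and its permutation p-value. The fraction of runs with
#' p < alpha at proportion 0 estimates the type-I error rate; at positive
#' proportions it estimates power.
#'
#' @param pool_a,pool_b cell pools ([sc_counts]).
#' @param proportions mixture fractions for N2.
#' @param k_grid cluster numbers to sweep (default just `params$k`).
#' @param n1,n2 sample sizes.
#' @param runs repetitions per grid point (default 50).
#' @param params an [unifrac_params()] configuration.
#' @param alpha significance level for the "significant" flag.
#' @param seed master seed; per-grid-point seeds are derived from it.
#' @return tidy data frame, one row per run: `proportion`, `k`, `n1`, `n2`,
#'   `run`, `n_b`, `D`, `p`, `significant`.
#' @export
run_sensitivity <- function(pool_a, pool_b, proportions = c(0, 0.02, 0.05,
                                                            0.1, 0.25, 0.5, 1),
                            k_grid = NULL, n1 = 1000, n2 = n1, runs = 50,
                            params = unifrac_params(), alpha = params$alpha,
                            seed) {
  if (missing(seed)) stop_input("`seed` is required for reproducibility")
  k_grid <- k_grid %||% params$k
  grid <- expand.grid(proportion = proportions, k = k_grid, n2 = n2)
  run_grid(pool_a, pool_b, grid, n1, runs, params, alpha, seed)
}

#' Dataset-size imbalance experiment
#'
#' As [run_sensitivity()] but sweeping the size of N2 while N1 stays fixed,
#' to measure how detection degrades under dataset-size imbalance.
#'
#' @inheritParams run_sensitivity
#' @param n2_grid N2 sizes to sweep.
#' @return tidy data frame as in [run_sensitivity()].
#' @export
run_imbalance <- function(pool_a, pool_b, proportions = c(0, 0.02, 0.05, 0.1),
                          n2_grid, n1 = 1000, runs = 50,
                          params = unifrac_params(), alpha = params$alpha,
                          seed) {
  if (missing(seed)) stop_input("`seed` is required for reproducibility")
  grid <- expand.grid(proportion = proportions, k = params$k, n2 = n2_grid)
  run_grid(pool_a, pool_b, grid, n1, runs, params, alpha, seed)
}

#' Summarize a sensitivity/imbalance run table
#'
#' @param tidy output of [run_sensitivity()] or [run_imbalance()].
#' @return data frame with one row per grid point: mean and quartiles of D
#'   and the fraction of significant runs.
#' @export
summarize_runs <- function(tidy) {
  key <- interaction(tidy$proportion, tidy$k, tidy$n2, drop = TRUE)
  parts <- split(tidy, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(proportion = d$proportion[1], k = d$k[1], n1 = d$n1[1],
               n2 = d$n2[1], runs = nrow(d), mean_D = mean(d$D),
               q1_D = unname(stats::quantile(d$D, 0.25)),
               median_D = stats::median(d$D),
               q3_D = unname(stats::quantile(d$D, 0.75)),
               frac_significant = mean(d$significant))
  }))
  out <- out[order(out$k, out$n2, out$proportion), ]
  rownames(out) <- NULL
  out
}
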