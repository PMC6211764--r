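#' Library-size normalize and log-transform counts
#'
#' Each cell's counts are scaled so that its total equals `scale_factor`
#' (default: the median library size of the pooled cells), then transformed
#' as `log(pseudocount + scaled)`. With the default pseudocount of 1 this is
#' the usual log1p of size-normalized counts; a zero count always maps to 0
#' and the result is invariant to multiplying a cell's counts by any
#' positive constant.
#'
#' @param x an [sc_counts] object.
#' @param scale_factor positive target library size; `NULL` uses the median
#'   library size across cells.
#' @param pseudocount positive offset added before taking the natural log.
#' @return an object of class `sc_norm`: list with `values` (genes x cells,
#'   log scale), `scale_factor`, `pseudocount`, and the per-cell `sample`
#'   labels.
#' @export
normalize_counts <- function(x, scale_factor = NULL, pseudocount = 1) {
  stopifnot(inherits(x, "sc_counts"))
  if (isTRUE(x$continuous)) {
    stop_input("continuous data should skip normalization (normalize = FALSE)")
  }
  lib <- colSums(x$counts)
  if (is.null(scale_factor)) scale_factor <- stats::median(lib)
  stopifnot(scale_factor > 0, pseudocount > 0)
  scaled <- sweep(x$counts, 2, scale_factor / lib, `*`)
  values <- log(pseudocount + scaled) - log(pseudocount)
  out <- list(values = values, scale_factor = scale_factor,
              pseudocount = pseudocount, sample = x$sample,
              population = x$population)
  class(out) <- "sc_norm"
  out
}

# wrap already-continuous values (CyTOF-like) in the sc_norm interface
# without transforming them, so the rest of the pipeline is unchanged
as_norm_passthrough <- function(x) {
  out <- list(values = x$counts, scale_factor = NA_real_,
              pseudocount = NA_real_, sample = x$sample,
              population = x$population)
  class(out) <- "sc_norm"
  out
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their normalized (log-scale) expression
#' across the pooled cells and returns the top `n_genes` IDs. Ties are broken
#' lexicographically by gene ID so the selection is deterministic.
#'
#' @param norm an `sc_norm` object from [normalize_counts()].
#' @param n_genes number of genes to keep (default 500). If the matrix has
#'   fewer genes, all are returned with a warning.
#' @return character vector of gene IDs, ordered by decreasing variance.
#' @export
select_hvg <- function(norm, n_genes = 500) {
  stopifnot(inherits(norm, "sc_norm"), n_genes >= 1)
  v <- row_vars(norm$values)
  ids <- rownames(norm$values)
  if (n_genes > length(ids)) {
    warn_code("hvg_short", "requested %d HVGs but only %d genes present",
              n_genes, length(ids))
    n_genes <- length(ids)
  }
  ord <- order(-v, ids)
  ids[ord][seq_len(n_genes)]
}

#' Embed cells by principal component analysis
#'
#' Computes PC scores of the pooled cells on the HVG submatrix. Genes are
#' mean-centered but not scaled to unit variance, keeping the magnitude
#' information that made them highly variable. Component signs are fixed by
#' requiring each component's largest-magnitude gene loading to be positive,
#' so repeated runs are bitwise identical.
#'
#' @param norm an `sc_norm` object.
#' @param hvg gene IDs to use; `NULL` uses all genes.
#' @param d number of components (default 4).
#' @return an object of class `sc_embedding`: `coords` (cells x d),
#'   `hvg`, `explained_variance` (nonincreasing), and `sample` labels.
#' @export
embed_cells <- function(norm, hvg = NULL, d = 4) {
  stopifnot(inherits(norm, "sc_norm"), d >= 1)
  if (is.null(hvg)) hvg <- rownames(norm$values)
  missing <- setdiff(hvg, rownames(norm$values))
  if (length(missing)) stop_input("unknown genes in `hvg`")
  x <- t(norm$values[hvg, , drop = FALSE])
  max_d <- min(nrow(x), ncol(x))
  if (d > max_d) {
    stop_input("d = %d exceeds the achievable rank %d (%d cells, %d genes)",
               d, max_d, nrow(x), ncol(x))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  d_eff <- min(d, ncol(pc$x))
  coords <- pc$x[, seq_len(d_eff), drop = FALSE]
  rot <- pc$rotation[, seq_len(d_eff), drop = FALSE]
  for (j in seq_len(d_eff)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) coords[, j] <- -coords[, j]
  }
  out <- list(coords = coords, d = d_eff, hvg = hvg,
              explained_variance = pc$sdev[seq_len(d_eff)]^2,
              sample = norm$sample, population = norm$population)
  class(out) <- "sc_embedding"
  out
}
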