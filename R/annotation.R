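#' Per-cluster gene expression signatures
#'
#' Tests every gene for differential expression between each cluster and
#' the rest of the pooled cells on the normalized (log-scale) values, using
#' a Welch two-sample t-test (optionally with variance moderation: gene
#' variances shrunk toward the mean variance of the comparison, which
#' stabilizes small clusters). Effect size is the difference of means, i.e.
#' a log fold-change. P-values are Benjamini-Hochberg adjusted within each
#' cluster; genes passing both the FDR and the effect-size cutoff form the
#' cluster's signature, split into over- and underexpressed sets. Clusters
#' with fewer than `min_cells` cells (or complements that small) are
#' reported untested.
#'
#' @param norm an `sc_norm` object over the pooled cells.
#' @param clusters an `sc_clusters` assignment with at least 2 clusters.
#' @param fdr FDR threshold for signature membership (default 0.05).
#' @param min_abs_lfc minimum absolute log fold-change (default 0.5).
#' @param moderated shrink per-gene variances toward the comparison mean
#'   with `prior_df` pseudo-degrees of freedom.
#' @param prior_df weight of the shrinkage target when `moderated`.
#' @param min_cells minimum cells per group for testing (default 3).
#' @return data frame of class `sc_signatures` with one row per
#'   (cluster, gene): `cluster`, `gene`, `lfc`, `t`, `p`, `p_adj`,
#'   `direction` ("over"/"under"), `signature` flag.
#' @export
cluster_signatures <- function(norm, clusters, fdr = 0.05, min_abs_lfc = 0.5,
                               moderated = FALSE, prior_df = 10,
                               min_cells = 3) {
  stopifnot(inherits(norm, "sc_norm"), inherits(clusters, "sc_clusters"))
  if (clusters$k < 2) stop_input("need at least 2 clusters to test signatures")
  x <- norm$values
  cl <- clusters$cluster[colnames(x)]
  genes <- rownames(x)
  out <- vector("list", clusters$k)
  for (c_i in seq_len(clusters$k)) {
    in_c <- cl == c_i
    n1 <- sum(in_c)
    n2 <- sum(!in_c)
    if (n1 < min_cells || n2 < min_cells) {
      out[[c_i]] <- data.frame(cluster = cluster_labels(clusters$k)[c_i],
                               gene = genes, lfc = NA_real_, t = NA_real_,
                               p = NA_real_, p_adj = NA_real_,
                               direction = NA_character_, signature = FALSE,
                               tested = FALSE)
      next
    }
    x1 <- x[, in_c, drop = FALSE]
    x2 <- x[, !in_c, drop = FALSE]
    m1 <- rowMeans(x1)
    m2 <- rowMeans(x2)
    v1 <- row_vars(x1)
    v2 <- row_vars(x2)
    if (moderated) {
      s0 <- mean(c(v1, v2))
      v1 <- (prior_df * s0 + (n1 - 1) * v1) / (prior_df + n1 - 1)
      v2 <- (prior_df * s0 + (n2 - 1) * v2) / (prior_df + n2 - 1)
    }
    se2 <- v1 / n1 + v2 / n2
    lfc <- m1 - m2
    tt <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, Inf * sign(lfc)))
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 1)
    p <- 2 * stats::pt(-abs(tt), df = df)
    p[se2 == 0 & lfc == 0] <- 1
    p[se2 == 0 & lfc != 0] <- 0
    p_adj <- stats::p.adjust(p, method = "BH")
    out[[c_i]] <- data.frame(cluster = cluster_labels(clusters$k)[c_i],
                             gene = genes, lfc = lfc, t = tt, p = p,
                             p_adj = p_adj,
                             direction = ifelse(lfc >= 0, "over", "under"),
                             signature = p_adj <= fdr & abs(lfc) >= min_abs_lfc,
                             tested = TRUE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sc_signatures", "data.frame")
  res
}

#' Read a reference cell-type atlas
#'
#' Reads a dense table of mean expression profiles (genes in rows, cell
#' types in columns). Duplicate gene rows are collapsed by their mean with
#' a warning.
#'
#' @param path CSV or TSV file; first column gene IDs, header cell types.
#' @param sep field separator; inferred from the extension by default.
#' @return an object of class `sc_atlas`: `profiles` (genes x types
#'   matrix), `type_names`, `gene_ids`.
#' @export
read_atlas <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) stop_input("empty atlas table")
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_input("atlas contains non-numeric entries")
  if (anyDuplicated(genes)) {
    warn_code("atlas_dup_genes", "collapsed %d duplicated gene row(s) by mean",
              sum(duplicated(genes)))
    m <- rowsum(m, genes) / as.vector(table(genes)[unique(sort(genes))])
    m <- m[order(rownames(m)), , drop = FALSE]
    genes <- rownames(m)
  } else {
    rownames(m) <- genes
  }
  if (anyDuplicated(colnames(m))) stop_input("duplicate cell-type names")
  sc_atlas(m)
}

#' Construct a reference atlas from a matrix
#'
#' @param profiles numeric matrix, genes x cell types, with dimnames.
#' @return an `sc_atlas` object.
#' @export
sc_atlas <- function(profiles) {
  stopifnot(is.matrix(profiles), is.numeric(profiles),
            !is.null(rownames(profiles)), !is.null(colnames(profiles)))
  if (any(!is.finite(profiles))) stop_input("atlas contains non-finite values")
  if (anyDuplicated(rownames(profiles))) stop_input("duplicate atlas gene IDs")
  if (anyDuplicated(colnames(profiles))) stop_input("duplicate cell-type names")
  out <- list(profiles = profiles, type_names = colnames(profiles),
              gene_ids = rownames(profiles))
  class(out) <- "sc_atlas"
  out
}

#' Match cells to reference cell types by correlation
#'
#' Correlates each query cell's normalized expression with every atlas
#' profile over the genes shared between query and atlas (Pearson). The
#' best match is the type with the highest correlation, ties broken by
#' type-name order. Cells with zero expression variance over the shared
#' genes cannot be correlated and are reported as unmatchable rather than
#' failing.
#'
#' @param norm an `sc_norm` object (log-scale values). The atlas is assumed
#'   to be on a comparable log scale; set `log_atlas = TRUE` to log1p raw
#'   atlas profiles first.
#' @param cells cell IDs to match; defaults to all cells.
#' @param atlas an `sc_atlas`.
#' @param min_overlap minimum number of shared genes (default 200).
#' @param log_atlas log1p-transform the atlas profiles before correlating.
#' @return list with `correlations` (cells x types matrix, NA rows for
#'   unmatchable cells) and `best` (data frame: `cell`, `type`,
#'   `correlation`).
#' @export
match_to_atlas <- function(norm, cells = NULL, atlas, min_overlap = 200,
                           log_atlas = FALSE) {
  stopifnot(inherits(norm, "sc_norm"), inherits(atlas, "sc_atlas"))
  if (is.null(cells)) cells <- colnames(norm$values)
  if (!all(cells %in% colnames(norm$values))) stop_input("unknown cell IDs")
  shared <- intersect(rownames(norm$values), atlas$gene_ids)
  if (length(shared) < min_overlap) {
    stop_input("only %d genes shared with the atlas (minimum %d)",
               length(shared), min_overlap)
  }
  q <- norm$values[shared, cells, drop = FALSE]
  ref <- atlas$profiles[shared, , drop = FALSE]
  ref <- ref[, order(colnames(ref)), drop = FALSE]  # tie-break by type name
  if (log_atlas) ref <- log1p(ref)
  qv <- row_vars(t(q))  # per-cell variance over shared genes
  ok <- qv > 0
  cors <- matrix(NA_real_, length(cells), ncol(ref),
                 dimnames = list(cells, colnames(ref)))
  if (any(ok)) {
    # cor() on genes-x-cells vs genes-x-types is already cells x types
    cors[ok, ] <- stats::cor(q[, ok, drop = FALSE], ref)
  }
  if (any(!ok)) {
    warn_code("unmatchable_cells",
              "%d cell(s) with zero variance over shared genes left unmatched",
              sum(!ok))
  }
  best_idx <- apply(cors, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)
  })
  best <- data.frame(cell = cells,
                     type = ifelse(is.na(best_idx), NA_character_,
                                   colnames(ref)[best_idx]),
                     correlation = ifelse(is.na(best_idx), NA_real_,
                                          cors[cbind(seq_along(cells),
                                                     best_idx)]))
  rownames(best) <- NULL
  list(correlations = cors, best = best)
}
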