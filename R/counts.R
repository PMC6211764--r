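#' Single-cell count matrix
#'
#' Container for a raw gene-by-cell count matrix with per-cell sample labels.
#' Validation enforces the invariants the downstream pipeline relies on:
#' unique gene identifiers, unique cell identifiers within a sample, finite
#' nonnegative values, and no zero-library cells (cells whose total count is
#' zero are dropped with a warning, since library-size normalization is
#' undefined for them).
#'
#' @param counts numeric matrix (genes in rows, cells in columns) with gene
#'   IDs as row names and cell IDs as column names. Sparse `Matrix` objects
#'   and data frames are densified.
#' @param sample sample label attached to every cell; either a single string
#'   or one string per cell.
#' @param population optional per-cell population labels (used by the
#'   synthetic-data generator to carry ground truth).
#' @param continuous set to `TRUE` for already-continuous measurements
#'   (e.g. mass-cytometry intensities): values may then be negative and the
#'   zero-library filter is skipped. Such data are meant to be analyzed with
#'   `normalize = FALSE` in [unifrac_params()].
#' @return an object of class `sc_counts` with elements `counts`, `sample`,
#'   and optionally `population`.
#' @export
sc_counts <- function(counts, sample = "sample1", population = NULL,
                      continuous = FALSE) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_input("`counts` must be a numeric matrix (genes x cells)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_input("`counts` must have gene IDs as rownames and cell IDs as colnames")
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop_input("count matrix contains missing or non-finite values")
  }
  if (!continuous && any(counts < 0)) {
    stop_input("count matrix contains negative values")
  }
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup)) {
    stop_input("duplicate gene IDs: %s",
               paste(utils::head(dup, 10), collapse = ", "))
  }
  n_cells <- ncol(counts)
  sample <- as.character(sample)
  if (length(sample) == 1L) sample <- rep(sample, n_cells)
  if (length(sample) != n_cells) {
    stop_input("`sample` must have length 1 or one label per cell")
  }
  for (s in unique(sample)) {
    ids <- colnames(counts)[sample == s]
    if (anyDuplicated(ids)) {
      stop_input("duplicate cell IDs within sample '%s'", s)
    }
  }
  if (!continuous) {
    lib <- colSums(counts)
    if (any(lib == 0)) {
      warn_code("zero_library", "dropped %d cell(s) with zero total count",
                sum(lib == 0))
      keep <- lib > 0
      counts <- counts[, keep, drop = FALSE]
      sample <- sample[keep]
      if (!is.null(population)) population <- population[keep]
    }
  }
  if (ncol(counts) == 0L) stop_input("no cells left after validation")
  out <- list(counts = counts, sample = sample,
              population = population, continuous = continuous)
  class(out) <- "sc_counts"
  out
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("sc_counts: %d genes x %d cells; samples: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$sample), collapse = ", ")))
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

#' Subset cells of a count matrix
#'
#' @param x an [sc_counts] object.
#' @param cells cell IDs or column indices to keep.
#' @param sample optional new sample label for the subset.
#' @return an `sc_counts` object restricted to the selected cells.
#' @export
subset_cells <- function(x, cells, sample = NULL) {
  stopifnot(inherits(x, "sc_counts"))
  if (is.character(cells)) cells <- match(cells, colnames(x$counts))
  if (anyNA(cells)) stop_input("unknown cell IDs in `cells`")
  out <- x
  out$counts <- x$counts[, cells, drop = FALSE]
  out$sample <- if (is.null(sample)) x$sample[cells] else
    rep(as.character(sample), length(cells))
  out$population <- x$population[cells]
  out
}

#' Read a count matrix from disk
#'
#' Supports the MatrixMarket triplet layout (`matrix.mtx` plus `genes.tsv`
#' and `barcodes.tsv` sidecars in one directory) and dense delimited tables
#' with gene IDs in the first column and cell IDs in the header.
#'
#' @param path for `format = "mtx"`, the directory holding the triplet (or
#'   the `.mtx` file itself); for `format = "dense"`, the table file.
#' @param format `"auto"` (directory or `.mtx` extension selects the triplet
#'   reader), `"mtx"`, or `"dense"`.
#' @param sample sample label for the cells.
#' @param genes_as_rows orientation of a dense table. The default `TRUE`
#'   (genes in rows) is the common convention; set to `FALSE` explicitly for
#'   transposed tables — orientation is never guessed silently.
#' @param sep field separator for dense tables; default is inferred from the
#'   extension (`","` for `.csv`, tab otherwise).
#' @return an [sc_counts] object.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "dense"),
                        sample = NULL, genes_as_rows = TRUE, sep = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx" else "dense"
  }
  if (is.null(sample)) {
    sample <- sub("\\.[^.]+$", "", basename(path))
  }
  if (format == "mtx") {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(dir, "matrix.mtx") else path
    genes_f <- file.path(dir, "genes.tsv")
    barcodes_f <- file.path(dir, "barcodes.tsv")
    for (f in c(mtx, genes_f, barcodes_f)) {
      if (!file.exists(f)) stop_input("missing sidecar file: %s", f)
    }
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- utils::read.delim(genes_f, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    barcodes <- utils::read.delim(barcodes_f, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
      stop_input("matrix dimensions (%d x %d) do not match sidecars (%d genes, %d barcodes)",
                 nrow(m), ncol(m), length(genes), length(barcodes))
    }
    dimnames(m) <- list(genes, barcodes)
  } else {
    if (!file.exists(path)) stop_input("file not found: %s", path)
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                             check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop_input("dense table contains non-numeric entries")
    if (!genes_as_rows) m <- t(m)
  }
  sc_counts(m, sample = sample)
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' Companion to [read_counts()]; writes `matrix.mtx`, `genes.tsv` and
#' `barcodes.tsv` into `dir`.
#'
#' @param x an [sc_counts] object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "sc_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Pool two or more samples on their shared genes
#'
#' Cells from all samples are combined into one matrix restricted to the
#' intersection of the gene panels. Cell IDs are made globally unique by
#' prefixing with the sample label, and the per-cell sample label is kept.
#' A warning is emitted when the shared panel covers less than half of any
#' input's genes, since dropping many genes can change the landscape.
#'
#' @param samples list of [sc_counts] objects, each carrying a single,
#'   distinct sample label.
#' @return a pooled [sc_counts] object.
#' @export
merge_samples <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  labels <- vapply(samples, function(s) {
    stopifnot(inherits(s, "sc_counts"))
    u <- unique(s$sample)
    if (length(u) != 1L) stop_input("each input to merge_samples() must carry one sample label")
    u
  }, character(1))
  if (anyDuplicated(labels)) {
    stop_input("duplicate sample labels: %s",
               paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  shared <- Reduce(intersect, lapply(samples, function(s) rownames(s$counts)))
  if (length(shared) == 0L) stop_input("empty gene intersection across samples")
  for (i in seq_along(samples)) {
    frac <- length(shared) / nrow(samples[[i]]$counts)
    if (frac < 0.5) {
      warn_code("gene_overlap",
                "shared genes cover only %.0f%% of sample '%s'",
                100 * frac, labels[i])
    }
  }
  mats <- lapply(seq_along(samples), function(i) {
    m <- samples[[i]]$counts[shared, , drop = FALSE]
    colnames(m) <- paste(labels[i], colnames(m), sep = ":")
    m
  })
  pooled <- do.call(cbind, mats)
  sample <- rep(labels, vapply(samples, function(s) ncol(s$counts), integer(1)))
  pop <- unlist(lapply(samples, function(s) {
    s$population %||% rep(NA_character_, ncol(s$counts))
  }), use.names = FALSE)
  if (all(is.na(pop))) pop <- NULL
  sc_counts(pooled, sample = sample, population = pop,
            continuous = any(vapply(samples, function(s) isTRUE(s$continuous),
                                    logical(1))))
}

#' Split a pooled matrix back into its samples
#'
#' Inverse of [merge_samples()] up to the gene intersection: returns one
#' [sc_counts] per sample label with the merge prefix stripped from cell IDs.
#'
#' @param x a pooled [sc_counts] object.
#' @return named list of `sc_counts` objects.
#' @export
split_samples <- function(x) {
  stopifnot(inherits(x, "sc_counts"))
  labels <- unique(x$sample)
  out <- lapply(labels, function(s) {
    y <- subset_cells(x, which(x$sample == s))
    ids <- colnames(y$counts)
    pre <- startsWith(ids, paste0(s, ":"))
    ids[pre] <- substring(ids[pre], nchar(s) + 2L)
    colnames(y$counts) <- ids
    y
  })
  names(out) <- labels
  out
}
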