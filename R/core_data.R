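## Container, file I/O, normalization and preprocessing shared by all stages.

#' Default post-symptom-onset time grid
#'
#' The ten sampling days (days since symptom onset) used throughout the
#' package as the default time grid.
#'
#' @return Strictly increasing integer vector of days.
#' @export
covid_time_grid <- function() c(3L, 7L, 9L, 10L, 13L, 15L, 16L, 22L, 25L, 28L)

required_meta_cols <- c("cell_id", "sample_id", "patient_id", "day",
                        "cell_type", "severity")

#' Annotated expression matrix
#'
#' Bundles a cells x genes raw count matrix with per-cell metadata, a
#' log-normalized layer and an optional low-dimensional embedding. Cells with
#' `severity == "control"` may carry `NA` day; all other cells must sit on
#' the declared time grid.
#'
#' @param counts sparse (or dense) non-negative integer matrix, cells in
#'   rows, genes in columns.
#' @param cell_meta data.frame with columns `cell_id`, `sample_id`,
#'   `patient_id`, `day`, `cell_type`, `severity`, one row per matrix row,
#'   in matrix row order.
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column.
#' @param normalized optional precomputed normalized layer (same shape as
#'   `counts`); computed lazily by [normalize_counts()] when `NULL`.
#' @param embedding optional cells x d numeric matrix.
#' @param time_grid strictly increasing integer vector of valid days.
#' @return An object of class `aem`.
#' @export
aem <- function(counts, cell_meta, gene_ids,
                normalized = NULL, embedding = NULL,
                time_grid = covid_time_grid()) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integral")
  if (!is.data.frame(cell_meta)) stop("cell_meta must be a data.frame")
  missing_cols <- setdiff(required_meta_cols, names(cell_meta))
  if (length(missing_cols))
    stop("cell_meta missing required columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(cell_meta) != nrow(counts))
    stop("cell_meta has ", nrow(cell_meta), " rows but counts has ",
         nrow(counts), " cells")
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids: ", paste(head(dup, 5), collapse = ", "))
  }
  if (length(gene_ids) != ncol(counts))
    stop("gene_ids length ", length(gene_ids), " != ", ncol(counts), " genes")
  if (any(diff(time_grid) <= 0)) stop("time_grid must be strictly increasing")
  day <- cell_meta$day
  noncontrol <- cell_meta$severity != "control"
  bad <- noncontrol & (is.na(day) | !(day %in% time_grid))
  if (any(bad))
    stop("cells with day outside the time grid: ",
         paste(head(cell_meta$cell_id[bad], 5), collapse = ", "))
  rownames(counts) <- cell_meta$cell_id
  colnames(counts) <- gene_ids
  structure(list(counts = counts, normalized = normalized,
                 cell_meta = cell_meta, gene_ids = gene_ids,
                 embedding = embedding, time_grid = as.integer(time_grid)),
            class = "aem")
}

#' @export
print.aem <- function(x, ...) {
  cat("aem: ", nrow(x$counts), " cells x ", ncol(x$counts), " genes\n", sep = "")
  cat("  days: ", paste(x$time_grid, collapse = ", "), "\n", sep = "")
  cat("  cell types: ", length(unique(x$cell_meta$cell_type)),
      "; normalized: ", !is.null(x$normalized),
      "; embedding: ", !is.null(x$embedding), "\n", sep = "")
  invisible(x)
}

#' @export
dim.aem <- function(x) dim(x$counts)

#' Subset an annotated matrix by cells
#'
#' @param x an `aem` object.
#' @param cells logical, integer or character (cell id) index.
#' @return An `aem` restricted to those cells (embedding and normalized
#'   layers subset consistently).
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "aem"))
  if (is.character(cells)) cells <- match(cells, x$cell_meta$cell_id)
  aem(x$counts[cells, , drop = FALSE],
      x$cell_meta[cells, , drop = FALSE],
      x$gene_ids,
      normalized = if (!is.null(x$normalized)) x$normalized[cells, , drop = FALSE],
      embedding  = if (!is.null(x$embedding))  x$embedding[cells, , drop = FALSE],
      time_grid  = x$time_grid)
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read an expression matrix from Matrix Market + TSV sidecars
#'
#' Reads a sparse count matrix (MTX), its feature and barcode lists, and a
#' cell metadata table keyed by `cell_id`, and assembles an [aem()]. Both
#' MTX dialects are accepted: `orientation = "genes_in_rows"` (the 10x /
#' CellRanger convention, default) or `"cells_in_rows"`.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param features_path path to a headerless TSV whose first column is the
#'   gene id.
#' @param barcodes_path path to a headerless TSV whose first column is the
#'   cell barcode.
#' @param meta_path path to a TSV/CSV with header containing the required
#'   metadata columns (see [aem()]); must cover every barcode.
#' @param orientation which MTX dialect the file uses.
#' @param time_grid passed through to [aem()].
#' @return An `aem` object.
#' @export
read_expression_matrix <- function(matrix_path, features_path, barcodes_path,
                                   meta_path,
                                   orientation = c("genes_in_rows", "cells_in_rows"),
                                   time_grid = covid_time_grid()) {
  orientation <- match.arg(orientation)
  m <- Matrix::readMM(matrix_path)
  if (orientation == "genes_in_rows") m <- Matrix::t(m)
  genes <- read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  barcodes <- read.delim(barcodes_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (length(genes) != ncol(m))
    stop("dimension mismatch: ", features_path, " lists ", length(genes),
         " features but ", matrix_path, " has ", ncol(m))
  if (length(barcodes) != nrow(m))
    stop("dimension mismatch: ", barcodes_path, " lists ", length(barcodes),
         " barcodes but ", matrix_path, " has ", nrow(m))
  meta <- read_table_auto(meta_path)
  if (!"cell_id" %in% names(meta)) stop(meta_path, " lacks a cell_id column")
  idx <- match(barcodes, meta$cell_id)
  if (anyNA(idx)) {
    miss <- barcodes[is.na(idx)]
    stop("barcodes absent from ", meta_path, ": ",
         paste(head(miss, 10), collapse = ", "))
  }
  aem(m, meta[idx, , drop = FALSE], genes, time_grid = time_grid)
}

#' Write an expression matrix as MTX + TSV sidecars
#'
#' Inverse of [read_expression_matrix()]; writes `matrix.mtx` (genes in
#' rows), `features.tsv`, `barcodes.tsv` and `cell_meta.tsv` into `dir`.
#'
#' @param x an `aem` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression_matrix <- function(x, dir) {
  stopifnot(inherits(x, "aem"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "features.tsv"))
  writeLines(x$cell_meta$cell_id, file.path(dir, "barcodes.tsv"))
  write.table(x$cell_meta, file.path(dir, "cell_meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Library-size log-normalize a count matrix
#'
#' Each cell's counts are divided by that cell's total, multiplied by
#' `scale_factor`, and natural-log transformed with a pseudocount of 1:
#' `normalized[c,g] = ln(1 + counts[c,g] / total[c] * scale_factor)`.
#'
#' @param counts non-negative matrix, cells in rows.
#' @param scale_factor library-size scale factor (default 10,000).
#' @return Sparse normalized matrix of the same shape.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) {
    zc <- which(totals == 0)
    nm <- if (!is.null(rownames(counts))) rownames(counts)[zc] else zc
    stop("cells with zero total counts: ", paste(head(nm, 10), collapse = ", "))
  }
  scaled <- Matrix::Diagonal(x = scale_factor / totals) %*% counts
  out <- scaled
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  methods::as(out, "CsparseMatrix")
}

#' Ensure the normalized layer is present
#'
#' @param x an `aem` object.
#' @param scale_factor passed to [normalize_counts()].
#' @return `x` with `$normalized` filled in.
#' @export
ensure_normalized <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "aem"))
  if (is.null(x$normalized)) x$normalized <- normalize_counts(x$counts, scale_factor)
  x
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their normalized expression, z-scored
#' within `n_bins` mean-expression bins so that highly expressed genes do
#' not dominate. Ties are broken by gene id (lexicographic), making the
#' ranking deterministic.
#'
#' @param x an `aem` with a normalized layer (computed if absent).
#' @param n_top number of genes to return; must not exceed the gene count.
#' @param n_bins number of mean-expression bins for the dispersion z-score.
#' @return Integer vector of `n_top` column indices, most variable first.
#' @export
select_hvgs <- function(x, n_top, n_bins = 20) {
  x <- ensure_normalized(x)
  n_genes <- ncol(x$normalized)
  if (n_top > n_genes)
    stop("n_top (", n_top, ") exceeds number of genes (", n_genes, ")")
  m <- x$normalized
  mu <- Matrix::colMeans(m)
  ex2 <- Matrix::colMeans(m^2)
  n <- nrow(m)
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  v[v < 0] <- 0
  # keep bins populated enough for a meaningful within-bin z-score
  n_bins_eff <- max(1, min(n_bins, floor(n_genes / 10)))
  bins <- if (n_bins_eff < 2) rep(1L, n_genes)
          else cut(rank(mu, ties.method = "first"), breaks = n_bins_eff,
                   labels = FALSE)
  z <- numeric(n_genes)
  for (b in unique(bins)) {
    i <- bins == b
    s <- sd(v[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (v[i] - mean(v[i])) / s
  }
  ord <- order(-z, x$gene_ids)
  ord[seq_len(n_top)]
}

#' PCA embedding of scaled HVG expression
#'
#' Centers and unit-scales the normalized expression of the selected genes,
#' clips the scaled values at `|z| = clip`, and runs PCA. Component signs
#' are fixed so the loading of largest absolute value in each component is
#' positive, making the embedding deterministic.
#'
#' @param x an `aem` with a normalized layer (computed if absent).
#' @param hvg integer vector of gene column indices (default: all genes).
#' @param n_components number of components (truncated to what the data
#'   supports).
#' @param clip clip scaled expression at this absolute z-score.
#' @return cells x n_components numeric matrix.
#' @export
compute_embedding <- function(x, hvg = NULL, n_components = 50, clip = 10) {
  x <- ensure_normalized(x)
  n_cells <- nrow(x$normalized)
  if (n_cells < 2) stop("embedding requires at least 2 cells")
  if (is.null(hvg)) hvg <- seq_len(ncol(x$normalized))
  m <- as.matrix(x$normalized[, hvg, drop = FALSE])
  mu <- colMeans(m)
  sdev <- apply(m, 2, sd)
  sdev[sdev == 0] <- 1
  z <- sweep(sweep(m, 2, mu, "-"), 2, sdev, "/")
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  k <- min(n_components, n_cells - 1, ncol(z))
  pc <- prcomp(z, center = FALSE, scale. = FALSE, rank. = k)
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    lj <- rot[, j]
    sign(lj[which.max(abs(lj))])
  }, numeric(1))
  flip[flip == 0] <- 1
  emb <- sweep(pc$x, 2, flip, "*")
  rownames(emb) <- x$cell_meta$cell_id
  emb
}
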