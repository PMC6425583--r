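#' Construct a count matrix
#'
#' Light container for a cells x genes expression matrix with cell and gene
#' identifiers. Values must be non-negative and finite for raw counts;
#' processed (log-scaled) values may be negative, in which case set
#' `processed = TRUE`.
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param cell_ids Character vector of unique cell identifiers
#'   (default: rownames or `cell_<i>`).
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: colnames or `gene_<j>`).
#' @param processed Logical; `TRUE` when values are on a processed
#'   (normalized/log/z) scale and may be negative.
#' @return An object of class `CountMatrix`: a numeric matrix with dimnames
#'   and a `processed` attribute.
#' @export
count_matrix <- function(values, cell_ids = NULL, gene_ids = NULL,
                         processed = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("count matrix must be numeric")
  if (any(!is.finite(values))) stop("count matrix contains non-finite values")
  if (!processed && any(values < 0)) stop("raw counts must be non-negative")
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(ncol(values)))
  }
  if (length(cell_ids) != nrow(values)) stop("cell_ids length != number of rows")
  if (length(gene_ids) != ncol(values)) stop("gene_ids length != number of columns")
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_ids))
  attr(values, "processed") <- processed
  class(values) <- c("CountMatrix", class(values))
  values
}

as_count_values <- function(x) {
  if (inherits(x, "CountMatrix")) return(unclass_count(x))
  as.matrix(x)
}

unclass_count <- function(x) {
  class(x) <- setdiff(class(x), "CountMatrix")
  attr(x, "processed") <- NULL
  x
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "processed"))) "processed" else "raw counts"))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Defaults follow the standard single-cell recipe: light filtering, total
#' count normalization to the median per-cell total, log1p, selection of
#' highly variable genes by normalized dispersion, and per-gene z-scaling
#' with clipping.
#'
#' @param min_genes Minimum number of detected genes to keep a cell.
#' @param min_cells Minimum number of cells expressing a gene to keep it.
#' @param target_sum Per-cell total after normalization; `NULL` uses the
#'   median of per-cell totals.
#' @param n_hvg Number of highly variable genes to retain; `NULL` disables
#'   HVG selection.
#' @param log1p Apply log(1 + x) after normalization.
#' @param scale Z-scale each gene after (optional) HVG selection.
#' @param clip Absolute cap applied to z-scores when `scale = TRUE`.
#' @param n_bins Number of gene-mean bins used to normalize dispersions.
#' @return A list of class `PreprocessConfig`.
#' @export
preprocess_config <- function(min_genes = 1, min_cells = 1, target_sum = NULL,
                              n_hvg = 1000, log1p = TRUE, scale = TRUE,
                              clip = 10, n_bins = 20) {
  structure(list(min_genes = min_genes, min_cells = min_cells,
                 target_sum = target_sum, n_hvg = n_hvg, log1p = log1p,
                 scale = scale, clip = clip, n_bins = n_bins),
            class = "PreprocessConfig")
}

#' Preprocess a raw count matrix
#'
#' Filters cells and genes, normalizes each cell's total to a common target,
#' applies log1p, restricts to highly variable genes (ranked by dispersion
#' normalized within gene-mean bins) and optionally z-scales genes with
#' clipping.
#'
#' @param counts A `CountMatrix` or numeric matrix of non-negative counts
#'   (cells x genes).
#' @param config A [preprocess_config()] object.
#' @return A processed `CountMatrix` restricted to retained cells/genes.
#' @export
preprocess_counts <- function(counts, config = preprocess_config()) {
  x <- as_count_values(counts)
  if (!is.numeric(x)) stop("format error: count matrix must be numeric")
  if (any(!is.finite(x))) stop("format error: non-finite entries in counts")
  if (any(x < 0)) stop("format error: negative entries in counts")

  keep_cells <- rowSums(x > 0) >= config$min_genes
  x <- x[keep_cells, , drop = FALSE]
  if (nrow(x) == 0) stop("empty after filtering: no cells retained")
  keep_genes <- colSums(x > 0) >= config$min_cells
  x <- x[, keep_genes, drop = FALSE]
  if (ncol(x) == 0) stop("empty after filtering: no genes retained")

  totals <- rowSums(x)
  if (any(totals == 0)) stop("empty after filtering: cells with zero total")
  target <- if (is.null(config$target_sum)) stats::median(totals) else config$target_sum
  x_norm <- x * (target / totals)

  if (!is.null(config$n_hvg) && config$n_hvg < ncol(x_norm)) {
    nd <- normalized_dispersion(x_norm, n_bins = config$n_bins)
    keep <- order(-nd, seq_along(nd))[seq_len(config$n_hvg)]
    x_norm <- x_norm[, sort(keep), drop = FALSE]
  }

  out <- if (config$log1p) log1p(x_norm) else x_norm

  if (config$scale) {
    mu <- colMeans(out)
    sd <- apply(out, 2, stats::sd)
    sd[sd == 0] <- 1
    out <- sweep(sweep(out, 2, mu, "-"), 2, sd, "/")
    out[out > config$clip] <- config$clip
    out[out < -config$clip] <- -config$clip
  }

  count_matrix(out, processed = TRUE)
}

#' Normalized dispersion of genes
#'
#' Per-gene dispersion (variance/mean) z-scored within quantile bins of the
#' gene mean; the ranking statistic used for highly-variable-gene selection.
#'
#' @param x Normalized (pre-log) cells x genes matrix.
#' @param n_bins Number of quantile bins of the gene mean.
#' @return Numeric vector of normalized dispersions, one per gene.
#' @export
normalized_dispersion <- function(x, n_bins = 20) {
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1, min(n_bins, length(unique(mu))))
  brk <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = brk, include.lowest = TRUE)
  nd <- numeric(length(disp))
  for (b in levels(bin)) {
    idx <- which(bin == b)
    m <- mean(disp[idx])
    s <- stats::sd(disp[idx])
    nd[idx] <- if (is.na(s) || s == 0) disp[idx] - m else (disp[idx] - m) / s
  }
  nd
}

#' Principal-component representation
#'
#' Centers the processed expression matrix and projects onto the top
#' principal components. Component signs are fixed (largest-magnitude
#' loading positive) so results are reproducible across platforms.
#'
#' @param counts Processed `CountMatrix` or numeric matrix (cells x genes).
#' @param n_comps Number of components; must be < min(cells, genes).
#' @param seed Unused by the exact decomposition; kept for interface
#'   stability with approximate backends.
#' @return An object of class `Representation` with elements `coords`
#'   (cells x n_comps score matrix), `basis_name`, `n_comps`.
#' @export
compute_representation <- function(counts, n_comps = 10, seed = 0) {
  x <- as_count_values(counts)
  if (n_comps >= min(dim(x))) {
    stop("parameter error: n_comps must be < min(cells, genes)")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_comps)
  rot <- p$rotation
  flip <- apply(rot, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  coords <- sweep(p$x[, seq_len(n_comps), drop = FALSE], 2, flip, "*")
  rownames(coords) <- rownames(x)
  structure(list(coords = coords, basis_name = "pca", n_comps = n_comps),
            class = "Representation")
}

#' @export
print.Representation <- function(x, ...) {
  cat(sprintf("Representation: %d cells x %d components (%s)\n",
              nrow(x$coords), x$n_comps, x$basis_name))
  invisible(x)
}

rep_coords <- function(rep) {
  if (inherits(rep, "Representation")) rep$coords else as.matrix(rep)
}

#' Read a MatrixMarket count matrix
#'
#' Reads the common triplet of files: a sparse `.mtx` matrix
#' (genes x cells or cells x genes), a barcode file (one cell id per line)
#' and a gene file (one gene id per line, first column used).
#'
#' @param mtx_file Path to the MatrixMarket file.
#' @param barcodes_file Path to the cell-id file.
#' @param genes_file Path to the gene-id file.
#' @param cells_in_rows `TRUE` when the matrix is stored cells x genes;
#'   the default `FALSE` matches the CellRanger genes x cells layout.
#' @return A `CountMatrix` (cells x genes).
#' @export
read_counts_mtx <- function(mtx_file, barcodes_file, genes_file,
                            cells_in_rows = FALSE) {
  m <- Matrix::readMM(mtx_file)
  cells <- readLines(barcodes_file)
  genes <- utils::read.table(genes_file, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  if (!cells_in_rows) m <- Matrix::t(m)
  m <- as.matrix(m)
  if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
    stop("format error: dimensions do not match barcode/gene files")
  }
  count_matrix(m, cell_ids = cells, gene_ids = genes,
               processed = any(m < 0))
}

#' Read a dense count table
#'
#' Expects a header row of gene ids and a first column of cell ids.
#'
#' @param file Path to a CSV or TSV file.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return A `CountMatrix`.
#' @export
read_counts_dense <- function(file, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$|\\.txt$", file)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("format error: non-numeric entries in count table")
  count_matrix(m, cell_ids = rownames(df), gene_ids = colnames(df),
               processed = any(m < 0))
}

#' Write a count matrix
#'
#' @param counts A `CountMatrix`.
#' @param file Output path; `.mtx` writes MatrixMarket plus `<file>.barcodes`
#'   and `<file>.genes`, anything else writes a dense CSV.
#' @return Invisibly, the file path.
#' @export
write_counts <- function(counts, file) {
  x <- as_count_values(counts)
  if (grepl("\\.mtx$", file)) {
    Matrix::writeMM(Matrix::Matrix(t(x), sparse = TRUE), file)
    writeLines(rownames(x), paste0(file, ".barcodes"))
    writeLines(colnames(x), paste0(file, ".genes"))
  } else {
    utils::write.csv(as.data.frame(x), file)
  }
  invisible(file)
}
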