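# Count-matrix container, 10x triplet IO, QC filtering, normalization.

#' Construct a count matrix with cell metadata
#'
#' Counts are stored genes x cells (10x convention) as a sparse Matrix.
#' Mitochondrial genes are detected by a case-insensitive `mt:` id prefix
#' unless an explicit gene list is supplied.
#'
#' @param counts Integer matrix or sparse Matrix, genes in rows, cells in
#'   columns, with dimnames.
#' @param cell_data data.frame with a `barcode` column matching the matrix
#'   columns; typically also `age`, `condition`, `batch`, and optionally
#'   `cluster` / `true_type`.
#' @param mito_genes Optional character vector overriding prefix detection.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_data, mito_genes = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (ncol(counts) == 0 && is.null(counts@Dimnames[[2]]))
    counts@Dimnames[[2]] <- character()
  .assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
          "counts must have gene and barcode dimnames")
  .assert(!anyDuplicated(rownames(counts)), "gene ids must be unique")
  .assert(!anyDuplicated(colnames(counts)), "cell barcodes must be unique")
  x <- counts@x
  .assert(all(x >= 0) && all(x == round(x)), "counts must be non-negative integers")
  .assert(is.data.frame(cell_data) && "barcode" %in% names(cell_data),
          "cell_data must be a data.frame with a barcode column")
  .assert(identical(as.character(cell_data$barcode), colnames(counts)),
          "cell_data barcodes must match matrix columns in order")
  if ("age" %in% names(cell_data))
    .assert(all(cell_data$age %in% AGES), "age must be 'young' or 'old'")
  if ("condition" %in% names(cell_data))
    .assert(all(cell_data$condition %in% CONDITIONS),
            "condition must be 'associated' or 'axenic'")
  is_mito <- if (is.null(mito_genes)) {
    grepl("^mt:", rownames(counts), ignore.case = TRUE)
  } else {
    rownames(counts) %in% mito_genes
  }
  structure(list(counts = counts, cell_data = cell_data,
                 gene_data = data.frame(gene = rownames(counts),
                                        is_mitochondrial = is_mito)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%d mitochondrial genes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$gene_data$is_mitochondrial)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write a count matrix as a 10x-style triplet
#'
#' Emits `matrix.mtx` (Matrix Market), `features.tsv`, `barcodes.tsv` and
#' `metadata.tsv` under `dir`.
#'
#' @param mat A `count_matrix`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_counts_10x <- function(mat, dir) {
  .assert(inherits(mat, "count_matrix"), "mat must be a count_matrix")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(mat$counts, mtx)
  feats <- file.path(dir, "features.tsv")
  utils::write.table(data.frame(id = rownames(mat$counts),
                                name = rownames(mat$counts),
                                type = "Gene Expression"),
                     feats, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bars <- file.path(dir, "barcodes.tsv")
  writeLines(colnames(mat$counts), bars)
  meta <- file.path(dir, "metadata.tsv")
  utils::write.table(mat$cell_data, meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(mtx, feats, bars, meta))
}

#' Read a 10x-style triplet directory
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and optionally `metadata.tsv`.
#' @param mito_genes Optional explicit mitochondrial gene list.
#' @return A `count_matrix`.
#' @export
read_counts_10x <- function(dir, mito_genes = NULL) {
  mtx <- file.path(dir, "matrix.mtx")
  feats <- file.path(dir, "features.tsv")
  bars <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feats, bars))
    .assert(file.exists(f), paste("missing file:", f))
  m <- Matrix::readMM(mtx)
  features <- utils::read.table(feats, sep = "\t", header = FALSE,
                                colClasses = "character")
  barcodes <- readLines(bars)
  if (nrow(features) != nrow(m))
    stop(sprintf("format error: %d features for a matrix with %d rows",
                 nrow(features), nrow(m)), call. = FALSE)
  if (length(barcodes) != ncol(m))
    stop(sprintf("format error: %d barcodes for a matrix with %d columns",
                 length(barcodes), ncol(m)), call. = FALSE)
  if (any(m@x != round(m@x)))
    stop("format error: non-integer entries in matrix.mtx", call. = FALSE)
  dimnames(m) <- list(features[[1]], barcodes)
  meta_path <- file.path(dir, "metadata.tsv")
  cell_data <- if (file.exists(meta_path)) {
    md <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            colClasses = "character")
    md[match(barcodes, md$barcode), , drop = FALSE]
  } else {
    data.frame(barcode = barcodes)
  }
  rownames(cell_data) <- NULL
  count_matrix(m, cell_data, mito_genes = mito_genes)
}

#' Cell-level quality filtering
#'
#' Retains cells whose detected-gene count lies in the closed interval
#' \[`min_features`, `max_features`\] and whose mitochondrial UMI fraction is
#' at most `max_mito_fraction` (cells strictly above are removed).
#'
#' @param mat A `count_matrix`.
#' @param min_features,max_features Inclusive bounds on genes detected.
#' @param max_mito_fraction Maximum tolerated mitochondrial UMI fraction.
#' @return List with `counts` (filtered `count_matrix`) and `report`
#'   (per-criterion removal counts).
#' @export
qc_filter <- function(mat, min_features = 200, max_features = 2500,
                      max_mito_fraction = 0.20) {
  .assert(inherits(mat, "count_matrix"), "mat must be a count_matrix")
  .assert(min_features > 0 && max_features > min_features,
          "need 0 < min_features < max_features")
  detected <- Matrix::colSums(mat$counts > 0)
  total <- Matrix::colSums(mat$counts)
  mito <- mat$gene_data$is_mitochondrial
  mito_frac <- if (any(mito)) {
    Matrix::colSums(mat$counts[mito, , drop = FALSE]) / pmax(total, 1)
  } else rep(0, ncol(mat$counts))
  low <- detected < min_features
  high <- detected > max_features
  mito_bad <- mito_frac > max_mito_fraction
  keep <- !(low | high | mito_bad)
  report <- list(n_input = ncol(mat$counts), n_retained = sum(keep),
                 n_low_features = sum(low), n_high_features = sum(high),
                 n_high_mito = sum(mito_bad),
                 thresholds = list(min_features = min_features,
                                   max_features = max_features,
                                   max_mito_fraction = max_mito_fraction))
  if (!any(keep)) warning("qc_filter removed every cell", call. = FALSE)
  out <- count_matrix(mat$counts[, keep, drop = FALSE],
                      mat$cell_data[keep, , drop = FALSE],
                      mito_genes = mat$gene_data$gene[mito])
  out$cell_data <- mat$cell_data[keep, , drop = FALSE]
  rownames(out$cell_data) <- NULL
  list(counts = out, report = report)
}

#' Library-size normalization with log transform
#'
#' value = log2(1 + scale * count / cell_total). Zero counts map exactly to
#' zero; cells with zero total are an error (QC should have removed them).
#'
#' @param mat A `count_matrix`.
#' @param scale Per-cell target library size (default 1e4).
#' @param log_base Base of the logarithm (default 2, consistent with log2
#'   fold changes downstream).
#' @return Object of class `normalized_matrix` with fields `values` (sparse,
#'   genes x cells), `cell_data`, `gene_data`, `scale`, `log_base`.
#' @export
normalize_log <- function(mat, scale = 1e4, log_base = 2) {
  .assert(inherits(mat, "count_matrix"), "mat must be a count_matrix")
  .assert(scale > 0, "scale must be positive")
  total <- Matrix::colSums(mat$counts)
  if (any(total == 0)) {
    stop(sprintf("cell(s) with zero total counts: %s",
                 paste(head(colnames(mat$counts)[total == 0], 5), collapse = ", ")),
         call. = FALSE)
  }
  v <- mat$counts
  percell <- rep.int(total, diff(v@p))
  v@x <- log(1 + scale * v@x / percell, base = log_base)
  structure(list(values = v, cell_data = mat$cell_data,
                 gene_data = mat$gene_data, scale = scale, log_base = log_base),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (scale %g, log base %g)\n",
              nrow(x$values), ncol(x$values), x$scale, x$log_base))
  invisible(x)
}
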