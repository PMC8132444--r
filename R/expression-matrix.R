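#' Expression matrix container
#'
#' A light wrapper around a genes x cells numeric matrix that carries the
#' gene and cell identifiers plus a `stage` flag recording where the matrix
#' sits in the preprocessing pipeline: `"raw_tpm"` (nonnegative TPM values),
#' `"log2_tpm1"` (after thresholding and `log2(x + 1)`), or `"normalized"`
#' (after per-gene centering and variance scaling).
#'
#' @param values numeric matrix, genes in rows and cells in columns. Row and
#'   column names, if present, seed `gene_ids` / `cell_ids`.
#' @param gene_ids character vector of unique gene identifiers (one per row).
#' @param cell_ids character vector of unique cell identifiers (one per column).
#' @param stage one of `"raw_tpm"`, `"log2_tpm1"`, `"normalized"`.
#'
#' @return An object of class `"expr_matrix"`: the numeric matrix with
#'   `dimnames` set and a `stage` attribute.
#' @examples
#' m <- matrix(c(0, 3, 7, 1, 2, 5), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("cellA", "cellB")))
#' expression_matrix(m, stage = "raw_tpm")
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              stage = c("raw_tpm", "log2_tpm1", "normalized")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x cells)")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)")
  if (length(cell_ids) != ncol(values))
    stop("length(cell_ids) must equal ncol(values)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_ids: ", paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyNA(values)) stop("expression values must not contain NA")
  if (stage == "raw_tpm" && any(values < 0))
    stop("stage 'raw_tpm' requires nonnegative values")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(values, stage = stage, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, stage: %s\n",
              nrow(x), ncol(x), expr_stage(x)))
  if (nrow(x) > 0 && ncol(x) > 0) {
    show <- unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x))), drop = FALSE]
    print(show, ...)
    if (nrow(x) > 5L || ncol(x) > 5L) cat("...\n")
  }
  invisible(x)
}

#' Pipeline stage of an expression matrix
#' @param x an `expr_matrix`.
#' @return `"raw_tpm"`, `"log2_tpm1"` or `"normalized"`.
#' @export
expr_stage <- function(x) {
  s <- attr(x, "stage")
  if (is.null(s)) stop("not an expr_matrix: missing stage attribute")
  s
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (!is.matrix(out)) return(out)
  expression_matrix(out, stage = expr_stage(x))
}

# coerce a plain matrix (or expr_matrix) to expr_matrix at a given stage
as_expr_matrix <- function(x, stage) {
  if (inherits(x, "expr_matrix")) return(x)
  expression_matrix(as.matrix(x), stage = stage)
}

#' Read an expression matrix from TSV/CSV or MatrixMarket files
#'
#' Tabular input has gene identifiers in the first column and a header of cell
#' identifiers; the delimiter is inferred from the extension (`.csv` = comma,
#' anything else = tab). MatrixMarket input (`.mtx`) stores genes as rows and
#' requires `genes.tsv` / `cells.tsv` sidecar files (one id per line) in the
#' same directory unless explicit paths are given. Gzipped files (`.gz`) are
#' read transparently.
#'
#' @param path path to the matrix file.
#' @param stage pipeline stage to stamp on the result (default `"raw_tpm"`).
#' @param genes,cells optional sidecar paths for `.mtx` input.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, stage = "raw_tpm", genes = NULL, cells = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  base <- sub("\\.gz$", "", path)
  if (grepl("\\.mtx$", base)) {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    if (is.null(genes)) genes <- file.path(dir, "genes.tsv")
    if (is.null(cells)) cells <- file.path(dir, "cells.tsv")
    gid <- readLines(genes)
    cid <- readLines(cells)
    return(expression_matrix(m, gene_ids = gid, cell_ids = cid, stage = stage))
  }
  sep <- if (grepl("\\.csv$", base)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  expression_matrix(as.matrix(df), stage = stage)
}

#' Write an expression matrix
#'
#' The tabular writer emits values with 12 significant digits so that a
#' read/write round trip preserves ids exactly and values to that precision.
#' A `.mtx` path writes MatrixMarket coordinate format with `genes.tsv` and
#' `cells.tsv` sidecars.
#'
#' @param x an `expr_matrix`.
#' @param path output path (`.tsv`, `.csv` or `.mtx`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  x <- as_expr_matrix(x, stage = "raw_tpm")
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(x), file.path(dir, "genes.tsv"))
    writeLines(colnames(x), file.path(dir, "cells.tsv"))
    return(invisible(path))
  }
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = sep), con)
  body <- apply(unclass(x), 1L, function(r)
    paste(formatC(r, digits = 12, format = "g"), collapse = sep))
  writeLines(paste(rownames(x), body, sep = sep), con)
  invisible(path)
}

#' Read a per-cell quality-control table
#'
#' Expects tab-separated columns `cell_id`, `total_reads`, `mapping_rate`,
#' `detected_genes`, `intergenic_fraction` as produced by sequencing QC tools.
#'
#' @param path path to the TSV file (optionally gzipped).
#' @return A data frame with one row per cell.
#' @export
read_qc_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "total_reads", "mapping_rate", "detected_genes",
            "intergenic_fraction")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("QC table lacks columns: ", paste(missing, collapse = ", "))
  df[need]
}

#' Read / write a cell label table
#'
#' Two tab-separated columns, `cell_id` and `label`. Used both for true
#' cell-type annotations and for writing predicted cluster assignments.
#'
#' @param path path to the TSV file (optionally gzipped).
#' @return `read_labels`: data frame with columns `cell_id`, `label`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("cell_id", "label") %in% names(df)))
    stop("label table must have columns 'cell_id' and 'label'")
  df$cell_id <- as.character(df$cell_id)
  df$label <- as.character(df$label)
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id in label table: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  if (any(!nzchar(df$label))) stop("empty labels are not allowed")
  df[c("cell_id", "label")]
}

#' @rdname read_labels
#' @param cell_ids character vector of cell identifiers.
#' @param labels vector of labels, parallel to `cell_ids`.
#' @export
write_labels <- function(cell_ids, labels, path) {
  utils::write.table(data.frame(cell_id = cell_ids, label = labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
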