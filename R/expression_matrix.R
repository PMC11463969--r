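#' Construct an ExpressionMatrix
#'
#' The package's format-neutral container for single-cell count data: a
#' sparse cells x genes matrix of non-negative integer counts, per-cell
#' metadata, and an optional log-normalized layer of the same shape.
#'
#' @param counts cells x genes matrix (dense or sparse); coerced to
#'   `dgCMatrix`. Row names are cell ids, column names gene ids; they can
#'   alternatively be supplied via `cell_ids`/`gene_ids`.
#' @param cell_meta data.frame of per-cell metadata, one row per cell.
#'   Matched to cells by a `cell_id` column or by row names; recycled columns
#'   such as `age`, `region`, `condition`, `library`, `cell_type` are kept
#'   as-is. Missing metadata is allowed (an empty frame is created).
#' @param lognorm optional log-normalized layer, same shape and dimnames.
#' @param cell_ids,gene_ids optional character vectors overriding dimnames.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `counts` (dgCMatrix), `cell_meta` (data.frame keyed by cell id) and
#'   `lognorm` (dgCMatrix or NULL).
#' @export
expression_matrix <- function(counts, cell_meta = NULL, lognorm = NULL,
                              cell_ids = NULL, gene_ids = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (!is.null(cell_ids)) rownames(counts) <- cell_ids
  if (!is.null(gene_ids)) colnames(counts) <- gene_ids
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("gene%d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene ids")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = rownames(counts))
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if ("cell_id" %in% names(cell_meta)) {
      rownames(cell_meta) <- cell_meta$cell_id
      cell_meta$cell_id <- NULL
    }
    default_rn <- identical(rownames(cell_meta),
                            as.character(seq_len(nrow(cell_meta))))
    if (default_rn && nrow(cell_meta) == nrow(counts))
      rownames(cell_meta) <- rownames(counts)
    cell_meta <- cell_meta[rownames(counts), , drop = FALSE]
    rownames(cell_meta) <- rownames(counts) # restore after [ with NAs
  }
  obj <- structure(list(counts = counts, cell_meta = cell_meta,
                        lognorm = lognorm),
                   class = "ExpressionMatrix")
  validate_expression_matrix(obj)
  obj
}

#' Validate an ExpressionMatrix
#'
#' Checks the class invariants: non-negative integral counts, unique cell and
#' gene ids, metadata covering every cell, and a lognorm layer (if present)
#' with identical shape and axis order.
#'
#' @param x ExpressionMatrix.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_expression_matrix <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  cts <- x$counts
  if (nrow(cts) == 0L) stop("ExpressionMatrix has zero cells")
  if (ncol(cts) == 0L) stop("ExpressionMatrix has zero genes")
  v <- cts@x
  if (length(v) && min(v) < 0) stop("counts contain negative entries")
  if (length(v) && max(abs(v - round(v))) > 1e-8)
    stop("counts contain non-integral entries")
  if (anyDuplicated(rownames(cts))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(cts))) stop("duplicate gene ids")
  if (!identical(rownames(x$cell_meta), rownames(cts)))
    stop("cell_meta does not cover every cell id in order")
  if (!is.null(x$lognorm)) {
    if (!identical(dim(x$lognorm), dim(cts)) ||
        !identical(dimnames(x$lognorm), dimnames(cts)))
      stop("lognorm layer shape/dimnames differ from counts")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$counts)

#' Cell ids of an ExpressionMatrix
#' @param x ExpressionMatrix.
#' @return character vector.
#' @export
cell_ids <- function(x) rownames(x$counts)

#' Gene ids of an ExpressionMatrix
#' @param x ExpressionMatrix.
#' @return character vector.
#' @export
gene_ids <- function(x) colnames(x$counts)

#' Subset an ExpressionMatrix
#'
#' `x[i, j]` subsets cells (`i`) and genes (`j`); metadata and the lognorm
#' layer follow.
#'
#' @param x ExpressionMatrix.
#' @param i,j cell / gene indices (integer, logical or character).
#' @param ... ignored.
#' @return ExpressionMatrix.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  out <- structure(list(
    counts = x$counts[i, j, drop = FALSE],
    cell_meta = x$cell_meta[i, , drop = FALSE],
    lognorm = if (is.null(x$lognorm)) NULL else x$lognorm[i, j, drop = FALSE]
  ), class = "ExpressionMatrix")
  validate_expression_matrix(out)
  out
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes (%.2f%% nonzero)%s\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts)),
              if (is.null(x$lognorm)) "" else ", with lognorm layer"))
  if (ncol(x$cell_meta))
    cat("cell_meta columns:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

# Dense lognorm layer (cells x genes), computing nothing: errors if absent.
.lognorm_dense <- function(x) {
  if (is.null(x$lognorm))
    stop("lognorm layer missing: run lognormalize() first")
  as.matrix(x$lognorm)
}
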