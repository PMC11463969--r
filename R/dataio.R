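# Reading/writing the on-disk exchange formats: Matrix Market counts with
# CSV sidecars (genes.csv: gene_id; cells.csv: cell_id + metadata columns).
# On disk the matrix is stored genes x cells (10x convention); in memory the
# package always works cells x genes.

#' Read a sparse count matrix with CSV sidecars
#'
#' Reads a Matrix Market coordinate file plus gene and cell sidecars. The
#' on-disk orientation is inferred from the sidecar lengths, so both
#' genes x cells (the 10x convention, and what [write_count_matrix()]
#' produces) and cells x genes files are accepted; the returned object is
#' always cells x genes.
#'
#' @param matrix_path path to the `.mtx` file (1-based coordinate format).
#' @param genes_path CSV with header and a `gene_id` column.
#' @param cells_path CSV with header, a `cell_id` column and any further
#'   metadata columns (age, region, condition, library, cell_type, ...).
#' @return [expression_matrix()] object.
#' @export
read_count_matrix <- function(matrix_path, genes_path, cells_path) {
  for (p in c(matrix_path, genes_path, cells_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.csv(genes_path, stringsAsFactors = FALSE)
  cells <- utils::read.csv(cells_path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(genes)) stop("genes sidecar lacks a gene_id column")
  if (!"cell_id" %in% names(cells)) stop("cells sidecar lacks a cell_id column")
  ng <- nrow(genes); nc <- nrow(cells)
  if (nrow(m) == ng && ncol(m) == nc) {
    m <- Matrix::t(m)                     # genes x cells on disk
  } else if (nrow(m) == nc && ncol(m) == ng) {
    # already cells x genes
  } else {
    stop(sprintf(paste0("dimension mismatch: matrix is %d x %d but sidecars ",
                        "declare %d genes and %d cells"),
                 nrow(m), ncol(m), ng, nc))
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in sidecar")
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell ids in sidecar")
  expression_matrix(m, cell_meta = cells,
                    cell_ids = cells$cell_id, gene_ids = genes$gene_id)
}

#' Write a count matrix as MTX + CSV sidecars
#'
#' Writes `matrix.mtx` (genes x cells, 1-based coordinate integers),
#' `genes.csv` and `cells.csv` (cell ids plus all metadata columns) into
#' `out_dir`. The result round-trips through [read_count_matrix()].
#'
#' @param matrix ExpressionMatrix.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_count_matrix <- function(matrix, out_dir) {
  validate_expression_matrix(matrix)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             genes = file.path(out_dir, "genes.csv"),
             cells = file.path(out_dir, "cells.csv"))
  Matrix::writeMM(Matrix::t(matrix$counts), paths[["matrix"]])
  utils::write.csv(data.frame(gene_id = gene_ids(matrix)),
                   paths[["genes"]], row.names = FALSE)
  meta <- cbind(data.frame(cell_id = cell_ids(matrix)),
                matrix$cell_meta)
  utils::write.csv(meta, paths[["cells"]], row.names = FALSE)
  invisible(paths)
}

#' Concatenate libraries over the union gene set
#'
#' Merges several libraries by simple concatenation: the output has the sum
#' of the input cell counts and the union of their gene sets, with absent
#' genes filled with zeros. Total count mass is conserved. No batch
#' correction is applied. Colliding cell ids across libraries are an error
#' unless `suffix_collisions = TRUE`, in which case ids are suffixed with
#' the library index.
#'
#' @param matrices list of ExpressionMatrix objects, each carrying a
#'   `library` column in `cell_meta` (added from `names(matrices)` or the
#'   list index when missing).
#' @param suffix_collisions suffix colliding cell ids instead of erroring.
#' @return ExpressionMatrix.
#' @export
merge_libraries <- function(matrices, suffix_collisions = FALSE) {
  if (!length(matrices)) stop("need at least one matrix")
  for (m in matrices) validate_expression_matrix(m)
  labs <- names(matrices)
  if (is.null(labs)) labs <- rep("", length(matrices))
  matrices <- lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    if (!"library" %in% names(m$cell_meta))
      m$cell_meta$library <- if (nzchar(labs[i])) labs[i] else
        sprintf("lib%d", i)
    m
  })
  all_ids <- unlist(lapply(matrices, cell_ids))
  if (anyDuplicated(all_ids)) {
    if (!suffix_collisions)
      stop("colliding cell_ids across libraries; set suffix_collisions=TRUE ",
           "to suffix them")
    matrices <- lapply(seq_along(matrices), function(i) {
      m <- matrices[[i]]
      ids <- paste0(cell_ids(m), "-", i)
      rownames(m$counts) <- ids
      rownames(m$cell_meta) <- ids
      if (!is.null(m$lognorm)) rownames(m$lognorm) <- ids
      m
    })
  }
  genes <- Reduce(union, lapply(matrices, gene_ids))
  blocks <- lapply(matrices, function(m) {
    out <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nrow(m$counts), length(genes)),
                                dimnames = list(cell_ids(m), genes))
    out[, gene_ids(m)] <- m$counts
    out
  })
  counts <- do.call(rbind, blocks)
  meta_cols <- Reduce(union, lapply(matrices, function(m) names(m$cell_meta)))
  meta <- do.call(rbind, lapply(matrices, function(m) {
    df <- m$cell_meta
    for (cn in setdiff(meta_cols, names(df))) df[[cn]] <- NA
    df[, meta_cols, drop = FALSE]
  }))
  expression_matrix(counts, cell_meta = meta)
}

#' Stage logger
#'
#' Writes a structured log line `<ISO timestamp> [stage] message` to
#' `con` (default stderr). Used by [run_stage()] but available anywhere.
#'
#' @param stage short stage name.
#' @param ... message parts, pasted.
#' @param con connection.
#' @return the line, invisibly.
#' @export
tm_log <- function(stage, ..., con = stderr()) {
  line <- sprintf("%s [%s] %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  stage, paste0(...))
  cat(line, "\n", file = con)
  invisible(line)
}
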