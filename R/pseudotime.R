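# Differentiation coordinate: a marker-anchored root cell, graph-geodesic
# pseudotime on the kNN graph, and selection of developmentally regulated
# genes along it.

#' Pick the root (most progenitor-like) cell
#'
#' Returns the cell maximizing the progenitor pseudogene score (mean
#' log-normalized expression of the progenitor markers, e.g. Btg2 / Pax6 /
#' Vim / Hes1 / Nes in mouse data). Ties go to the lexicographically
#' smallest cell id.
#'
#' @param matrix ExpressionMatrix with a lognorm layer.
#' @param progenitor_markers character vector of marker gene ids.
#' @return cell id.
#' @export
root_cell <- function(matrix, progenitor_markers) {
  sc <- score_pseudogene(matrix, progenitor_markers)
  top <- which(sc == max(sc))
  sort(names(sc)[top])[1]
}

#' Graph-geodesic pseudotime
#'
#' Pseudotime is the shortest-path distance from the root cell on the
#' symmetrized k-nearest-neighbor graph of the embedding (`k =
#' cfg$snn_neighbors`, Euclidean edge weights), min-max rescaled to
#' `[0, 1]`. Cells unreachable from the root inherit the pseudotime of
#' their nearest reachable neighbor, with a warning.
#'
#' @param embedding cells x dims matrix.
#' @param root_cell root cell id (see [root_cell()]).
#' @param cfg [pipeline_config()].
#' @return `PseudotimeField`: named numeric vector of t in `[0, 1]` with
#'   attributes `root_cell` and `method`.
#' @export
compute_pseudotime <- function(embedding, root_cell,
                               cfg = pipeline_config()) {
  ids <- rownames(embedding)
  if (!root_cell %in% ids) stop("root cell not in embedding: ", root_cell)
  n <- nrow(embedding)
  k <- min(cfg$snn_neighbors, n - 1)
  nn <- .knn_indices(embedding, k)
  ii <- rep(seq_len(n), k)
  jj <- as.vector(nn)
  w <- sqrt(rowSums((embedding[ii, , drop = FALSE] -
                       embedding[jj, , drop = FALSE])^2))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ii, to = jj, weight = w),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = "min")
  d <- igraph::distances(g, v = as.character(match(root_cell, ids)))[1, ]
  d <- d[as.character(seq_len(n))]
  if (any(!is.finite(d))) {
    warning(sum(!is.finite(d)),
            " cell(s) unreachable from root; assigned nearest reachable ",
            "neighbor's pseudotime")
    reach <- which(is.finite(d)); miss <- which(!is.finite(d))
    for (i in miss) {
      dd <- colSums((t(embedding[reach, , drop = FALSE]) - embedding[i, ])^2)
      d[i] <- d[reach[which.min(dd)]]
    }
  }
  rng <- range(d)
  t <- if (rng[2] > rng[1]) (d - rng[1]) / (rng[2] - rng[1]) else d * 0
  structure(stats::setNames(as.numeric(t), ids),
            root_cell = root_cell, method = "knn_geodesic",
            class = "PseudotimeField")
}

#' @export
print.PseudotimeField <- function(x, ...) {
  cat(sprintf("PseudotimeField over %d cells (root %s, method %s)\n",
              length(x), attr(x, "root_cell"), attr(x, "method")))
  print(summary(as.numeric(x)))
  invisible(x)
}

#' Developmentally regulated genes
#'
#' Genes whose expression changes along pseudotime: mean log-normalized
#' expression above `cfg$detect_threshold`, BH-adjusted p below
#' `cfg$de_alpha` for the Spearman correlation of expression with t
#' (large-sample t approximation), and |rho| at least `cfg$min_abs_rho`
#' (an effect-size floor: with thousands of cells, significance alone
#' admits arbitrarily weak library-composition trends). Output ordered by
#' decreasing |rho|.
#'
#' @param matrix ExpressionMatrix with a lognorm layer.
#' @param pt `PseudotimeField` over the same cells.
#' @param cfg [pipeline_config()].
#' @return data.frame (gene_id, rho, p, padj), ordered by |rho|.
#' @export
dev_regulated <- function(matrix, pt, cfg = pipeline_config()) {
  X <- .lognorm_dense(matrix)
  n <- nrow(X)
  if (n < 10) stop("need at least 10 cells")
  t_ <- as.numeric(pt)[match(cell_ids(matrix), names(pt))]
  if (anyNA(t_)) stop("pseudotime missing for some cells")
  expressed <- colMeans(X) > cfg$detect_threshold
  rt <- rank(t_)
  rho <- rep(NA_real_, ncol(X))
  sds <- apply(X, 2, stats::sd)
  ok <- which(expressed & sds > 0)
  if (length(ok)) {
    rX <- apply(X[, ok, drop = FALSE], 2, rank)
    rho[ok] <- as.numeric(stats::cor(rX, rt))
  }
  tstat <- rho * sqrt((n - 2) / pmax(1e-12, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  keep <- which(!is.na(rho))
  padj <- rep(NA_real_, ncol(X))
  padj[keep] <- stats::p.adjust(p[keep], method = "BH")
  sel <- which(!is.na(padj) & padj < cfg$de_alpha &
                 abs(rho) >= cfg$min_abs_rho)
  sel <- sel[order(abs(rho[sel]), decreasing = TRUE)]
  data.frame(gene_id = gene_ids(matrix)[sel], rho = rho[sel],
             p = p[sel], padj = padj[sel], stringsAsFactors = FALSE)
}
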