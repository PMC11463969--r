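# QC, normalization, feature selection, embedding and clustering.

#' Quality-control filter
#'
#' Removes cells with fewer than `cfg$min_genes_per_cell` detected genes,
#' then genes detected in fewer than `cfg$min_cells_per_gene` of the
#' remaining cells (cell filter strictly before gene filter). Because
#' removing genes can push a cell back below its threshold, the two
#' filters are applied in that order until a fixed point, so both
#' conditions hold in the output and the operation is idempotent.
#'
#' @param matrix ExpressionMatrix of raw counts.
#' @param cfg [pipeline_config()].
#' @return filtered ExpressionMatrix.
#' @export
qc_filter <- function(matrix, cfg = pipeline_config()) {
  validate_expression_matrix(matrix)
  m <- matrix
  repeat {
    detected <- Matrix::rowSums(m$counts > 0)
    keep_cells <- detected >= cfg$min_genes_per_cell
    if (!any(keep_cells))
      stop("qc_filter removed all cells (min_genes_per_cell = ",
           cfg$min_genes_per_cell, ")")
    m2 <- m[keep_cells, ]
    n_cells_per_gene <- Matrix::colSums(m2$counts > 0)
    keep_genes <- n_cells_per_gene >= cfg$min_cells_per_gene
    if (!any(keep_genes)) stop("qc_filter removed all genes")
    m2 <- m2[, keep_genes]
    if (all(keep_cells) && all(keep_genes)) return(m2)
    m <- m2
  }
}

#' Log-normalize counts
#'
#' Scales each cell's counts to `cfg$norm_scale` total and applies log1p,
#' storing the result as the `lognorm` layer (zeros stay zero, so the layer
#' stays sparse). Cells with zero total count are an error.
#'
#' @param matrix ExpressionMatrix (QC-filtered counts).
#' @param cfg [pipeline_config()].
#' @return ExpressionMatrix with a `lognorm` layer.
#' @export
lognormalize <- function(matrix, cfg = pipeline_config()) {
  totals <- Matrix::rowSums(matrix$counts)
  if (any(totals == 0)) stop("cell(s) with zero total count: ",
                             paste(utils::head(cell_ids(matrix)[totals == 0]),
                                   collapse = ", "))
  scaled <- Matrix::Diagonal(x = cfg$norm_scale / totals) %*% matrix$counts
  ln <- scaled
  ln@x <- log1p(ln@x)
  ln <- methods::as(ln, "CsparseMatrix")
  dimnames(ln) <- dimnames(matrix$counts)
  matrix$lognorm <- ln
  matrix
}

#' Select highly variable genes
#'
#' Variance-stabilizing selection: a degree-2 polynomial trend of log10
#' variance on log10 mean predicts each gene's expected standard deviation;
#' counts are standardized with that sd, clipped at `sqrt(N)`, and genes are
#' ranked by the variance of the clipped standardized values.
#'
#' @param matrix ExpressionMatrix (raw counts used).
#' @param cfg [pipeline_config()]; `n_hvg` genes returned.
#' @return character vector of gene ids, most variable first.
#' @export
select_hvg <- function(matrix, cfg = pipeline_config()) {
  cts <- matrix$counts
  G <- ncol(cts)
  if (cfg$n_hvg > G) stop("n_hvg exceeds the number of genes")
  N <- nrow(cts)
  mu <- Matrix::colSums(cts) / N
  ex2 <- Matrix::colSums(cts^2) / N
  v <- (ex2 - mu^2) * N / (N - 1)
  usable <- which(mu > 0 & v > 0)
  fit_df <- data.frame(lm = log10(mu[usable]), lv = log10(v[usable]))
  co <- stats::coef(stats::lm(lv ~ lm + I(lm^2), data = fit_df))
  pred_sd <- sqrt(10^(co[1] + co[2] * fit_df$lm + co[3] * fit_df$lm^2))
  clip <- sqrt(N)
  std_var <- numeric(G)
  dense <- as.matrix(cts[, usable, drop = FALSE])
  for (k in seq_along(usable)) {
    z <- (dense[, k] - mu[usable[k]]) / pred_sd[k]
    z <- pmin(pmax(z, -clip), clip)
    std_var[usable[k]] <- sum((z - mean(z))^2) / (N - 1)
  }
  ord <- order(std_var, decreasing = TRUE)
  gene_ids(matrix)[ord[seq_len(cfg$n_hvg)]]
}

#' PCA embedding of the log-normalized data
#'
#' Centers and unit-scales the lognorm layer over the HVGs and computes the
#' top `cfg$pca_dims` principal components. Component signs are fixed by
#' convention (largest-magnitude loading positive), so the embedding is
#' deterministic.
#'
#' @param matrix ExpressionMatrix with a lognorm layer.
#' @param hvg highly variable gene ids (from [select_hvg()]).
#' @param cfg [pipeline_config()].
#' @param scale. unit-scale genes before PCA (default TRUE).
#' @return cells x `pca_dims` matrix with attributes `sdev` (all singular
#'   sdevs), `explained` (variance share per kept PC) and `rotation`.
#' @export
embed_pca <- function(matrix, hvg, cfg = pipeline_config(), scale. = TRUE) {
  X <- .lognorm_dense(matrix)[, hvg, drop = FALSE]
  if (cfg$pca_dims > min(dim(X)))
    stop("pca_dims exceeds min(cells, genes)")
  X <- scale(X, center = TRUE, scale = FALSE)
  if (scale.) {
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2, sds, "/")
  }
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE,
                      rank. = cfg$pca_dims)
  rot <- pc$rotation
  for (k in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, k]))
    if (rot[i, k] < 0) {
      rot[, k] <- -rot[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  emb <- pc$x
  rownames(emb) <- cell_ids(matrix)
  attr(emb, "sdev") <- pc$sdev
  attr(emb, "explained") <- pc$sdev[seq_len(ncol(emb))]^2 / sum(pc$sdev^2)
  attr(emb, "rotation") <- rot
  emb
}

# Row-wise k nearest neighbours (indices), brute force on the Euclidean
# distance matrix; ties broken by index for determinism.
.knn_indices <- function(embedding, k) {
  n <- nrow(embedding)
  if (k >= n) stop("need more cells than neighbors")
  d <- as.matrix(stats::dist(embedding))
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    idx[i, ] <- ord[seq_len(k)]
  }
  idx
}

#' Shared-nearest-neighbor modularity clustering
#'
#' Builds a k-nearest-neighbor graph (`k = cfg$snn_neighbors`), weights
#' edges by the Jaccard overlap of the two cells' neighbor sets (pruning
#' overlaps below 1/15), and optimizes modularity by the Louvain algorithm
#' at `cfg$cluster_resolution`. Labels are contiguous integers from 0,
#' ordered by decreasing cluster size; the run is seeded by
#' `cfg$rng_seed`.
#'
#' @param embedding cells x dims matrix (from [embed_pca()]).
#' @param cfg [pipeline_config()].
#' @return integer vector of labels, named by cell id.
#' @export
cluster_snn <- function(embedding, cfg = pipeline_config()) {
  n <- nrow(embedding)
  if (n < cfg$snn_neighbors + 1)
    stop("too few cells for snn_neighbors = ", cfg$snn_neighbors)
  k <- cfg$snn_neighbors
  nn <- .knn_indices(embedding, k)
  # neighbor sets include the cell itself (standard SNN convention)
  sets <- cbind(seq_len(n), nn)
  memb <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1), j = as.vector(sets),
                               x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(memb)          # |A intersect B|
  shared <- methods::as(methods::as(shared, "generalMatrix"),
                        "CsparseMatrix")
  jac <- shared
  jac@x <- shared@x / (2 * (k + 1) - shared@x) # Jaccard
  jac@x[jac@x < 1 / 15] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(cfg$rng_seed)
  cl <- igraph::cluster_louvain(g, resolution = cfg$cluster_resolution)
  lab <- igraph::membership(cl)
  sizes <- table(lab)
  relab <- stats::setNames(seq_along(sizes) - 1L,
                           names(sort(sizes, decreasing = TRUE)))
  out <- as.integer(relab[as.character(lab)])
  names(out) <- rownames(embedding)
  out
}
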