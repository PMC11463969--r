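# Transcriptional waves: smoothed per-gene expression profiles along
# pseudotime, clustered into ordered waves.

#' Smooth per-gene expression profiles along pseudotime
#'
#' For each gene, local-mean smoothing of log-normalized expression over
#' pseudotime on an even grid (window `3 / n_grid`; empty windows fall back
#' to the nearest cell), then min-max scaling to `[0, 1]` per gene.
#' Constant genes map to all-zero profiles.
#'
#' @param matrix ExpressionMatrix with a lognorm layer.
#' @param pt `PseudotimeField`.
#' @param genes gene ids to profile (non-empty, subset of the matrix).
#' @param n_grid grid size (>= 10).
#' @return genes x grid matrix; grid positions as column names.
#' @export
smooth_profiles <- function(matrix, pt, genes, n_grid = 20L) {
  if (!length(genes)) stop("empty gene list")
  if (n_grid < 10) stop("n_grid must be at least 10")
  missing <- setdiff(genes, gene_ids(matrix))
  if (length(missing)) stop("genes absent from matrix: ",
                            paste(utils::head(missing), collapse = ", "))
  X <- .lognorm_dense(matrix)[, genes, drop = FALSE]
  t_ <- as.numeric(pt)[match(cell_ids(matrix), names(pt))]
  grid <- seq(0, 1, length.out = n_grid)
  half <- (3 / n_grid) / 2
  prof <- matrix(NA_real_, length(genes), n_grid,
                 dimnames = list(genes, sprintf("%.3f", grid)))
  for (gpt in seq_len(n_grid)) {
    sel <- which(abs(t_ - grid[gpt]) <= half)
    if (!length(sel)) sel <- which.min(abs(t_ - grid[gpt]))
    prof[, gpt] <- colMeans(X[sel, , drop = FALSE])
  }
  lo <- apply(prof, 1, min); hi <- apply(prof, 1, max)
  flat <- hi - lo <= 0
  prof <- (prof - lo) / ifelse(flat, 1, hi - lo)
  prof[flat, ] <- 0
  attr(prof, "grid") <- grid
  prof
}

#' Cluster smoothed profiles into ordered transcriptional waves
#'
#' K-means over the profile matrix with `k` chosen by maximum mean
#' silhouette width over `k_range` (10 restarts, fixed seed). Clusters are
#' relabeled 1..k by ascending mean peak position, so wave 1 is the
#' earliest. Degenerate inputs (all profiles identical) return
#' `k = min(k_range)` with a warning.
#'
#' @param profiles genes x grid matrix from [smooth_profiles()].
#' @param k_range candidate wave counts (default 2:8).
#' @param seed RNG seed for the k-means restarts.
#' @return `WaveAssignment`: list with `genes` (data.frame gene_id, wave,
#'   peak_t), `k`, `silhouette` (named by k), and `profiles` (per-wave mean
#'   profile matrix).
#' @export
cluster_waves <- function(profiles, k_range = 2:8, seed = 0L) {
  G <- nrow(profiles)
  if (max(k_range) > G) stop("k_range exceeds the number of genes")
  grid <- attr(profiles, "grid")
  if (is.null(grid)) grid <- seq(0, 1, length.out = ncol(profiles))
  d <- stats::dist(profiles)
  degenerate <- max(d) <= .Machine$double.eps^0.5
  sil <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  fits <- list()
  if (degenerate) {
    warning("all profiles identical; returning k = min(k_range)")
    best_k <- min(k_range)
    cl <- rep(1L, G)
  } else {
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      set.seed(seed)
      km <- try(stats::kmeans(profiles, centers = k, nstart = 10,
                              iter.max = 50), silent = TRUE)
      if (inherits(km, "try-error")) next
      fits[[as.character(k)]] <- km
      if (length(unique(km$cluster)) < 2) next
      sw <- cluster::silhouette(km$cluster, d)
      sil[i] <- mean(sw[, "sil_width"])
    }
    if (all(is.na(sil))) {
      warning("silhouette undefined for all k; returning k = min(k_range)")
      best_k <- min(k_range)
      cl <- if (!is.null(fits[[as.character(best_k)]]))
        fits[[as.character(best_k)]]$cluster else rep(1L, G)
    } else {
      best_k <- k_range[which.max(sil)]
      cl <- fits[[as.character(best_k)]]$cluster
    }
  }
  peak <- grid[apply(profiles, 1, which.max)]
  mean_peak <- tapply(peak, cl, mean)
  relab <- stats::setNames(seq_along(mean_peak),
                           names(sort(mean_peak)))
  wave <- as.integer(relab[as.character(cl)])
  wave_prof <- do.call(rbind, lapply(sort(unique(wave)), function(w)
    colMeans(profiles[wave == w, , drop = FALSE])))
  rownames(wave_prof) <- sprintf("wave%d", sort(unique(wave)))
  structure(list(
    genes = data.frame(gene_id = rownames(profiles), wave = wave,
                       peak_t = peak, stringsAsFactors = FALSE),
    k = length(unique(wave)),
    silhouette = sil,
    profiles = wave_prof,
    grid = grid
  ), class = "WaveAssignment")
}

#' @export
print.WaveAssignment <- function(x, ...) {
  cat(sprintf("WaveAssignment: %d genes in %d waves\n",
              nrow(x$genes), x$k))
  peaks <- tapply(x$genes$peak_t, x$genes$wave, mean)
  for (w in names(peaks))
    cat(sprintf("  wave %s: %3d genes, mean peak t = %.2f\n", w,
                sum(x$genes$wave == as.integer(w)), peaks[[w]]))
  invisible(x)
}

#' @export
plot.WaveAssignment <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "pseudotime", ylab = "scaled expression",
                 main = "Transcriptional waves", ...)
  cols <- grDevices::hcl.colors(nrow(x$profiles), "Dark 3")
  for (i in seq_len(nrow(x$profiles)))
    graphics::lines(x$grid, x$profiles[i, ], col = cols[i], lwd = 2)
  graphics::legend("topright", legend = rownames(x$profiles),
                   col = cols, lwd = 2, bty = "n")
  invisible(x)
}
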