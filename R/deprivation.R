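# Control-versus-deprived comparison: condition DE, overlap with the
# developmental program, pseudotime maturation lag, PCA centroid
# progression, and reference-to-query subcluster label transfer.

#' Condition differential expression within a region
#'
#' Per-gene Wilcoxon rank-sum test of deprived versus control cells
#' (glutamatergic cells of one region), BH-adjusted. Genes higher in the
#' deprived condition with adjusted p below `cfg$de_alpha` are "up",
#' symmetric for "down".
#'
#' @param matrix ExpressionMatrix with lognorm layer and `condition` +
#'   `region` metadata (`control` / `deprived`).
#' @param region region to test (e.g. `"LG"`); `NULL` uses all cells.
#' @param cfg [pipeline_config()].
#' @param cell_type metadata cell type retained (default glutamatergic).
#' @return list with `up` and `down` data.frames (gene_id, log2fc, padj)
#'   ordered by |log2fc|, plus `n_control`, `n_deprived`.
#' @export
condition_de <- function(matrix, region = NULL, cfg = pipeline_config(),
                         cell_type = "glut") {
  meta <- matrix$cell_meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(region)) {
    if (!"region" %in% names(meta)) stop("no region metadata")
    keep <- keep & meta$region == region
  }
  if (!is.null(cell_type) && "cell_type" %in% names(meta))
    keep <- keep & meta$cell_type == cell_type
  if (!any(keep)) stop("empty region: ", region)
  sub <- matrix[keep, ]
  cond <- sub$cell_meta$condition
  if (is.null(cond)) stop("no condition metadata")
  n_dep <- sum(cond == "deprived"); n_ctl <- sum(cond == "control")
  if (n_dep < 3 || n_ctl < 3)
    stop("need >= 3 cells per condition (control ", n_ctl,
         ", deprived ", n_dep, ")")
  X <- .lognorm_dense(sub)
  ing <- cond == "deprived"
  rs <- .rank_sum_cols(X, ing)
  fc <- .log2fc(X, ing)
  padj <- stats::p.adjust(rs$p, method = "BH")
  sig <- padj < cfg$de_alpha
  mk <- function(sel) {
    df <- data.frame(gene_id = colnames(X)[sel], log2fc = fc[sel],
                     padj = padj[sel], stringsAsFactors = FALSE)
    df[order(abs(df$log2fc), decreasing = TRUE), , drop = FALSE]
  }
  list(up = mk(which(sig & fc > 0)), down = mk(which(sig & fc < 0)),
       n_control = n_ctl, n_deprived = n_dep)
}

#' Activity-dependent gene overlap
#'
#' Of the developmentally regulated genes, how many are also condition-DE
#' ("activity-dependent"), as a percentage of the developmental set,
#' reported to one decimal.
#'
#' @param dev_genes developmentally regulated gene ids (non-empty).
#' @param de_genes condition-DE gene ids.
#' @return list `n_dev`, `n_overlap`, `percent` (one decimal).
#' @export
deprivation_overlap <- function(dev_genes, de_genes) {
  dev_genes <- unique(dev_genes)
  if (!length(dev_genes)) stop("empty developmental gene set")
  n_overlap <- length(intersect(dev_genes, de_genes))
  list(n_dev = length(dev_genes), n_overlap = n_overlap,
       percent = round(100 * n_overlap / length(dev_genes), 1))
}

#' Pseudotime maturation lag
#'
#' Difference in median pseudotime between control and deprived cells
#' (positive = deprived lags), with a two-sided permutation test of the
#' absolute difference. When per-cell strata (e.g. age cohorts) are given,
#' the statistic is the cell-count-weighted mean of the per-stratum median
#' differences and condition labels are permuted within strata — the
#' appropriate design when both conditions were sampled at the same ages,
#' since a pooled multimodal median is a needlessly noisy statistic.
#'
#' @param pt_control,pt_deprived pseudotime values of the two groups
#'   (each >= 20 cells).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed for the permutation draw.
#' @param strata_control,strata_deprived optional per-cell stratum labels
#'   (both or neither; strata present in only one condition are dropped).
#' @return list `delta` (median(control) - median(deprived), possibly
#'   stratum-averaged), `p`.
#' @export
pseudotime_lag <- function(pt_control, pt_deprived, n_perm = 1000L,
                           seed = 0L, strata_control = NULL,
                           strata_deprived = NULL) {
  x <- as.numeric(pt_control); y <- as.numeric(pt_deprived)
  if (length(x) < 20 || length(y) < 20)
    stop("need >= 20 cells per group")
  if (is.null(strata_control) != is.null(strata_deprived))
    stop("supply strata for both conditions or neither")
  set.seed(seed)
  if (is.null(strata_control)) {
    delta <- stats::median(x) - stats::median(y)
    pool <- c(x, y); n1 <- length(x)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(pool), n1)
      d <- stats::median(pool[idx]) - stats::median(pool[-idx])
      if (abs(d) >= abs(delta)) exceed <- exceed + 1L
    }
    return(list(delta = delta, p = (1 + exceed) / (1 + n_perm)))
  }
  sc <- as.character(strata_control); sd_ <- as.character(strata_deprived)
  stopifnot(length(sc) == length(x), length(sd_) == length(y))
  strata <- intersect(unique(sc), unique(sd_))
  if (!length(strata)) stop("no stratum present in both conditions")
  stat <- function(xs, ys) {
    num <- 0; den <- 0
    for (a in strata) {
      xa <- xs[[a]]; ya <- ys[[a]]
      w <- length(xa) + length(ya)
      num <- num + w * (stats::median(xa) - stats::median(ya))
      den <- den + w
    }
    num / den
  }
  xs <- split(x[sc %in% strata], sc[sc %in% strata])
  ys <- split(y[sd_ %in% strata], sd_[sd_ %in% strata])
  delta <- stat(xs, ys)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    xp <- list(); yp <- list()
    for (a in strata) {
      pool <- c(xs[[a]], ys[[a]])
      idx <- sample.int(length(pool), length(xs[[a]]))
      xp[[a]] <- pool[idx]; yp[[a]] <- pool[-idx]
    }
    if (abs(stat(xp, yp)) >= abs(delta)) exceed <- exceed + 1L
  }
  list(delta = delta, p = (1 + exceed) / (1 + n_perm))
}

#' Overlap of upregulated genes with an identity's markers
#'
#' Counts how many condition-upregulated genes are also markers of a given
#' category (e.g. LG-deprived up-genes that are LP markers, evidence of
#' partial identity shift).
#'
#' @param up_genes upregulated gene ids.
#' @param marker_set [marker_set()].
#' @param category marker category to intersect with.
#' @return list `n_up`, `n_markers`, `n_overlap`.
#' @export
marker_overlap_count <- function(up_genes, marker_set, category) {
  mk <- marker_genes(marker_set, category)
  list(n_up = length(unique(up_genes)), n_markers = length(mk),
       n_overlap = length(intersect(unique(up_genes), mk)))
}

#' Pairwise PCA centroid distances between groups
#'
#' Euclidean distances between group centroids in the PCA embedding;
#' groups are typically (age, condition) combinations. Singleton groups
#' are dropped with a warning.
#'
#' @param embedding cells x dims matrix.
#' @param group_labels per-cell labels (length = rows of embedding).
#' @param min_cells minimum group size kept (default 3).
#' @return symmetric distance matrix with zero diagonal.
#' @export
pca_group_distance <- function(embedding, group_labels, min_cells = 3L) {
  stopifnot(length(group_labels) == nrow(embedding))
  tab <- table(group_labels)
  small <- names(tab)[tab < min_cells]
  if (length(small))
    warning("groups dropped (fewer than ", min_cells, " cells): ",
            paste(small, collapse = ", "))
  keep <- !group_labels %in% small & !is.na(group_labels)
  groups <- sort(unique(group_labels[keep]))
  if (length(groups) < 2) stop("need at least 2 usable groups")
  cent <- do.call(rbind, lapply(groups, function(g)
    colMeans(embedding[keep & group_labels == g, , drop = FALSE])))
  rownames(cent) <- groups
  as.matrix(stats::dist(cent))
}

#' Transfer reference subcluster labels to a query dataset
#'
#' For each reference subcluster, its positive markers (one-vs-rest
#' rank-sum) define a pseudogene; query cells are scored with every
#' subcluster pseudogene, scores are z-normalized with the *reference*
#' cells' mean and sd (so a globally shifted query population shifts its
#' labels rather than being recentred away), and each query cell takes the
#' argmax subcluster (ties to the lowest subcluster index). Subclusters without positive markers are excluded
#' with a warning; fewer than 2 usable subclusters is an error.
#'
#' @param ref_matrix reference ExpressionMatrix with lognorm layer.
#' @param ref_labels per-cell subcluster labels of the reference.
#' @param query_matrix query ExpressionMatrix with lognorm layer (shared
#'   gene namespace).
#' @param cfg [pipeline_config()].
#' @return named vector of query labels (names = query cell ids), with the
#'   marker table as attribute `markers`.
#' @export
transfer_subcluster_labels <- function(ref_matrix, ref_labels, query_matrix,
                                       cfg = pipeline_config()) {
  ms <- find_markers(ref_matrix, ref_labels, cfg)
  subs <- sort(unique(as.character(ref_labels)))
  usable <- subs[subs %in% unique(ms$category)]
  dropped <- setdiff(subs, usable)
  if (length(dropped))
    warning("subclusters without positive markers excluded: ",
            paste(dropped, collapse = ", "))
  if (length(usable) < 2)
    stop("fewer than 2 subclusters with positive markers")
  sc <- vapply(usable, function(s)
    score_pseudogene(query_matrix, marker_genes(ms, s)),
    numeric(nrow(query_matrix$counts)))
  ref_sc <- vapply(usable, function(s)
    score_pseudogene(ref_matrix, marker_genes(ms, s)),
    numeric(nrow(ref_matrix$counts)))
  mu <- colMeans(ref_sc)
  sdv <- apply(ref_sc, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(sc, 2, mu), 2, sdv, "/")
  win <- apply(z, 1, which.max)   # usable is sorted: first max = lowest index
  out <- stats::setNames(usable[win], cell_ids(query_matrix))
  attr(out, "markers") <- ms
  out
}

# Two-pass maturation lag. Developmentally regulated genes are picked on
# the control cells with the dataset-wide pseudotime; both conditions are
# then re-embedded over those genes only and each cell gets a maturation
# score: its projection on the leading principal component of the
# developmental program, min-max scaled and oriented by the dataset-wide
# pseudotime. A projection is used rather than a graph geodesic on
# purpose: a geodesic measures position *along* the manifold and is
# insensitive to a condition sitting on a parallel, partially-lagged
# expression state, whereas the projection reflects the cell's aggregate
# maturational state.
.refined_lag <- function(matrix, mask_ctl, mask_dep, pt, cfg, seed) {
  dev <- dev_regulated(matrix[mask_ctl, ], pt, cfg)
  genes <- dev$gene_id
  if (length(genes) < 5) {
    warning("fewer than 5 developmentally regulated genes; measuring the ",
            "lag on the supplied pseudotime")
    tc <- as.numeric(pt)[match(cell_ids(matrix)[mask_ctl], names(pt))]
    td <- as.numeric(pt)[match(cell_ids(matrix)[mask_dep], names(pt))]
    return(list(dev = dev, lag = pseudotime_lag(tc, td, seed = seed),
                pt = NULL))
  }
  both <- mask_ctl | mask_dep
  sub <- matrix[both, genes]
  cfg2 <- cfg
  cfg2$pca_dims <- min(cfg$pca_dims, length(genes) - 1L, sum(both) - 1L)
  cfg2$n_hvg <- length(genes)
  emb <- embed_pca(sub, genes, cfg2)
  t0 <- as.numeric(pt)[match(cell_ids(sub), names(pt))]
  score <- emb[, 1]
  if (stats::cor(score, t0, method = "spearman") < 0) score <- -score
  score <- (score - min(score)) / (max(score) - min(score))
  names(score) <- cell_ids(sub)
  tc <- score[match(cell_ids(matrix)[mask_ctl], names(score))]
  td <- score[match(cell_ids(matrix)[mask_dep], names(score))]
  # pooled (unstratified) median test: when a lag shifts mass between age
  # cohorts, the pooled median in the inter-cohort gap moves with that
  # mass, making it the more sensitive statistic here
  list(dev = dev, lag = pseudotime_lag(tc, td, seed = seed), pt = score)
}

#' Full deprivation report
#'
#' Produces the region-level control-versus-deprived comparison: condition
#' DE up/down lists, developmentally regulated genes (control cells),
#' activity-dependent overlap, and the maturation lag, for each region's
#' glutamatergic cells and (optionally) for the interneurons pooled across
#' regions. The lag is measured on a refined trajectory: cells of both
#' conditions re-embedded over the group's developmentally regulated genes
#' (see Details in the package vignette); the overlap statistics use the
#' same developmental gene set.
#'
#' @param matrix merged control+deprived ExpressionMatrix with lognorm.
#' @param pt dataset-wide `PseudotimeField` (used to select developmental
#'   genes and to anchor/orient the refined trajectory).
#' @param regions regions to report (default the metadata's regions).
#' @param cfg [pipeline_config()].
#' @param lag_seed seed for the permutation tests.
#' @param interneurons also report the interneuron lag (requires
#'   `cell_type` metadata with `"IN"` cells in both conditions).
#' @return `DeprivationReport`: per-region list with `de`, `dev_genes`,
#'   `overlap`, `lag`; plus an `interneuron` element when requested.
#' @export
deprivation_report <- function(matrix, pt, regions = NULL,
                               cfg = pipeline_config(), lag_seed = 0L,
                               interneurons = FALSE) {
  meta <- matrix$cell_meta
  if (is.null(regions)) regions <- sort(unique(meta$region))
  out <- lapply(regions, function(rg) {
    glut <- meta$region == rg &
      (!"cell_type" %in% names(meta) | meta$cell_type %in% c("glut", NA))
    de <- condition_de(matrix, rg, cfg)
    ctl <- glut & meta$condition == "control"
    dep <- glut & meta$condition == "deprived"
    rl <- .refined_lag(matrix, ctl, dep, pt, cfg, lag_seed)
    ov <- deprivation_overlap(rl$dev$gene_id,
                              c(de$up$gene_id, de$down$gene_id))
    list(region = rg, de = de, dev_genes = rl$dev$gene_id, overlap = ov,
         lag = rl$lag)
  })
  names(out) <- regions
  if (interneurons) {
    if (!"cell_type" %in% names(meta)) stop("no cell_type metadata")
    ins <- meta$cell_type == "IN"
    rl <- .refined_lag(matrix, ins & meta$condition == "control",
                       ins & meta$condition == "deprived", pt, cfg,
                       lag_seed)
    out$interneuron <- list(region = "IN", de = NULL,
                            dev_genes = rl$dev$gene_id, overlap = NULL,
                            lag = rl$lag)
  }
  structure(out, class = "DeprivationReport")
}

#' @export
print.DeprivationReport <- function(x, ...) {
  for (rg in names(x)) {
    r <- x[[rg]]
    if (is.null(r$de)) {
      cat(sprintf("%s: median pseudotime lag %.3f (p = %.3g)\n",
                  rg, r$lag$delta, r$lag$p))
    } else {
      cat(sprintf(paste0("%s: %d up / %d down after deprivation; %d/%d ",
                         "developmental genes affected (%.1f%%); ",
                         "median pseudotime lag %.3f (p = %.3g)\n"),
                  rg, nrow(r$de$up), nrow(r$de$down), r$overlap$n_overlap,
                  r$overlap$n_dev, r$overlap$percent, r$lag$delta,
                  r$lag$p))
    }
  }
  invisible(x)
}
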