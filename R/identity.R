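# The core algorithm: iterative seed-cell marker bootstrapping. Mature
# markers score terminal-stage cells; top-quantile scorers become seed
# cells; differential expression between seed groups derives embryonic
# markers; every post-mitotic cell is assigned by the highest normalized
# derived pseudogene, retaining confident calls only.

#' Pseudogene score
#'
#' The per-cell mean log-normalized expression over a set of marker genes
#' (a "pseudogene" in the thalamus literature's sense: a score, not a
#' genomic pseudogene). Listed genes missing from the matrix are dropped
#' with a warning; none present is an error.
#'
#' @param matrix ExpressionMatrix with a lognorm layer.
#' @param genes marker gene ids.
#' @return named numeric vector (one score per cell).
#' @export
score_pseudogene <- function(matrix, genes) {
  present <- intersect(genes, gene_ids(matrix))
  if (!length(present)) stop("no listed gene present in matrix")
  if (length(present) < length(genes))
    warning(length(genes) - length(present), " marker gene(s) absent; ",
            "using the ", length(present), " present")
  sc <- Matrix::rowSums(matrix$lognorm[, present, drop = FALSE]) /
    length(present)
  stats::setNames(as.numeric(sc), cell_ids(matrix))
}

#' Select seed cells
#'
#' Terminal-stage cells whose pseudogene score reaches the
#' `cfg$seed_quantile` quantile of the scores within the stage (ties at the
#' threshold are all included; at least one cell is always returned).
#'
#' @param scores named per-cell scores (from [score_pseudogene()]).
#' @param stage_mask logical or character: the terminal-stage cells.
#' @param cfg [pipeline_config()].
#' @return character vector of seed cell ids.
#' @export
select_seed_cells <- function(scores, stage_mask, cfg = pipeline_config()) {
  if (is.logical(stage_mask)) {
    stopifnot(length(stage_mask) == length(scores))
    stage_ids <- names(scores)[stage_mask]
  } else stage_ids <- intersect(stage_mask, names(scores))
  if (!length(stage_ids)) stop("empty stage mask")
  s <- scores[stage_ids]
  thr <- stats::quantile(s, cfg$seed_quantile, names = FALSE, type = 7)
  seeds <- stage_ids[s >= thr]
  if (!length(seeds)) seeds <- stage_ids[which.max(s)]
  seeds
}

#' Derive embryonic markers from seed cells
#'
#' One-vs-rest differential expression restricted to the seed cells of all
#' categories; the top `cfg$n_round2_markers` genes per category by
#' fold-change become the second-round (embryonic) markers. Because seed
#' groups are tiny (a top-quantile sliver of one stage), ranking is by
#' fold-change without a significance gate. A gene passing for two
#' categories goes to the one with the larger fold-change; the other list
#' is backfilled from its next-ranked genes.
#'
#' @param matrix ExpressionMatrix with a lognorm layer.
#' @param seed_cells_by_category named list: category -> seed cell ids
#'   (>= 2 categories, each >= 3 cells after removing cells seeded for
#'   more than one category).
#' @param cfg [pipeline_config()].
#' @return [marker_set()] with provenance `"derived_round2"`.
#' @export
derive_embryonic_markers <- function(matrix, seed_cells_by_category,
                                     cfg = pipeline_config()) {
  cats <- names(seed_cells_by_category)
  if (length(cats) < 2) stop("need at least 2 categories")
  all_seeds <- unlist(seed_cells_by_category, use.names = FALSE)
  dup <- all_seeds[duplicated(all_seeds)]
  seed_cells_by_category <- lapply(seed_cells_by_category, setdiff, y = dup)
  sizes <- lengths(seed_cells_by_category)
  if (any(sizes < 3))
    stop("category with fewer than 3 exclusive seed cells: ",
         paste(cats[sizes < 3], collapse = ", "))
  labels <- rep(cats, sizes)
  cells <- unlist(seed_cells_by_category, use.names = FALSE)
  sub <- matrix[cells, ]
  ms <- find_markers(sub, labels, cfg, significant.only = FALSE)
  picked <- list()
  taken_fc <- list()
  for (cat in cats) {
    rows <- ms[ms$category == cat, , drop = FALSE]
    picked[[cat]] <- rows[order(rows$log2fc, decreasing = TRUE), ]
  }
  # resolve cross-category overlaps by larger fold-change, then backfill
  assigned <- list()
  for (cat in cats) assigned[[cat]] <- character(0)
  owner <- list()
  for (cat in cats) {
    rows <- picked[[cat]]
    for (i in seq_len(nrow(rows))) {
      g <- rows$gene_id[i]
      fc <- rows$log2fc[i]
      if (is.null(owner[[g]]) || owner[[g]]$fc < fc)
        owner[[g]] <- list(cat = cat, fc = fc)
    }
  }
  out <- lapply(cats, function(cat) {
    rows <- picked[[cat]]
    keep <- vapply(seq_len(nrow(rows)), function(i)
      owner[[rows$gene_id[i]]]$cat == cat, logical(1))
    utils::head(rows[keep, , drop = FALSE], cfg$n_round2_markers)
  })
  out <- do.call(rbind, out)
  marker_set(as.data.frame(out)[, c("category", "gene_id", "log2fc", "padj")],
             provenance = "derived_round2")
}

#' Assign identities from derived markers
#'
#' Scores each cell with one pseudogene per category (derived round-2
#' markers), z-normalizes each score across cells, and labels every cell
#' with the argmax category (exact ties break toward `ground_state`, the
#' developmental ground state, HO-side by default). A call is retained iff
#' the winning category's *raw* pseudogene reaches the
#' `cfg$retain_quantile` quantile of that pseudogene across cells;
#' unretained cells are labeled `"unassigned"`.
#'
#' @param matrix ExpressionMatrix with a lognorm layer.
#' @param derived_markers [marker_set()] with >= 2 categories.
#' @param cfg [pipeline_config()].
#' @param cells optional post-mitotic cell ids (neuron mask); default all.
#' @param ground_state tie-break category; defaults to the first of
#'   `HO`, `Po`, `LP` present, else the first category.
#' @return `IdentityCall`: list with `cells` (data.frame cell_id, label,
#'   retained), `scores` (raw pseudogenes), `z` (normalized), `categories`,
#'   `ground_state`.
#' @export
assign_identity <- function(matrix, derived_markers,
                            cfg = pipeline_config(), cells = NULL,
                            ground_state = NULL) {
  cats <- unique(derived_markers$category)
  if (length(cats) < 2) stop("need at least 2 marker categories")
  if (is.null(cells)) cells <- cell_ids(matrix)
  if (!length(cells)) stop("empty cell mask")
  sub <- matrix[cells, ]
  raw <- vapply(cats, function(cat)
    score_pseudogene(sub, marker_genes(derived_markers, cat)),
    numeric(nrow(sub$counts)))
  z <- scale(raw)
  z[, attr(z, "scaled:scale") == 0] <- 0
  if (is.null(ground_state))
    ground_state <- c(intersect(c("HO", "Po", "LP"), cats), cats[1])[1]
  pref <- order(match(cats, ground_state, nomatch = length(cats) + 1))
  zp <- z[, pref, drop = FALSE]
  win <- apply(zp, 1, which.max)              # first max wins -> ground state
  label <- cats[pref][win]
  thr <- apply(raw, 2, stats::quantile, probs = cfg$retain_quantile,
               names = FALSE)
  win_raw <- raw[cbind(seq_along(label), match(label, cats))]
  retained <- win_raw >= thr[match(label, cats)]
  label[!retained] <- "unassigned"
  structure(list(
    cells = data.frame(cell_id = cells, label = label, retained = retained,
                       stringsAsFactors = FALSE),
    scores = raw, z = z, categories = cats, ground_state = ground_state
  ), class = "IdentityCall")
}

#' @export
print.IdentityCall <- function(x, ...) {
  cat(sprintf("IdentityCall over %d cells (categories: %s; ground state %s)\n",
              nrow(x$cells), paste(x$categories, collapse = ", "),
              x$ground_state))
  print(table(x$cells$label))
  invisible(x)
}

#' FO/HO ratio score
#'
#' Contrast of two pseudogene scores: `r = (FO - HO) / (FO + HO + eps)`
#' after min-max scaling each score to `[0, 1]` across cells. `r > 0` is
#' FO-leaning, `r < 0` HO-leaning; `r` lies in `(-1, 1)`.
#'
#' @param fo_score,ho_score per-cell scores.
#' @param rescale min-max scale the inputs first (default TRUE; set FALSE
#'   if the inputs are already scaled).
#' @param eps guard against 0/0.
#' @return numeric vector of ratio scores.
#' @export
ratio_score <- function(fo_score, ho_score, rescale = TRUE, eps = 1e-9) {
  stopifnot(length(fo_score) == length(ho_score))
  mm <- function(v) {
    rng <- range(v)
    if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  }
  if (rescale) {
    fo_score <- mm(fo_score); ho_score <- mm(ho_score)
  }
  (fo_score - ho_score) / (fo_score + ho_score + eps)
}

#' Emergence curves and onsets along pseudotime
#'
#' Splits pseudotime into `cfg$n_bins` equal-width bins and reports, per
#' category: the mean normalized assignment score per bin and the
#' normalized cumulative count of labeled (retained) cells by bin. The
#' onset of a category is the smallest t at which its cumulative count
#' reaches 0.5, linearly interpolated between bin edges.
#'
#' @param pt `PseudotimeField`.
#' @param calls `IdentityCall` on the same cells.
#' @param cfg [pipeline_config()].
#' @return list with `bins` (long data.frame: bin, t_lo, t_hi, category,
#'   mean_score, n_labeled, cum_frac) and `onset` (named vector).
#' @export
emergence_curves <- function(pt, calls, cfg = pipeline_config()) {
  ids <- calls$cells$cell_id
  t_ <- as.numeric(pt)[match(ids, names(pt))]
  if (anyNA(t_)) stop("pseudotime missing for some called cells")
  nb <- cfg$n_bins
  edges <- seq(0, 1, length.out = nb + 1)
  bin <- pmin(pmax(findInterval(t_, edges, rightmost.closed = TRUE), 1), nb)
  cats <- calls$categories
  rows <- list(); onset <- stats::setNames(rep(NA_real_, length(cats)), cats)
  for (cat in cats) {
    zc <- calls$z[, match(cat, cats)]
    lab <- calls$cells$label == cat
    if (!any(lab)) stop("category with zero labeled cells: ", cat)
    n_lab <- tapply(lab, factor(bin, levels = seq_len(nb)), sum)
    n_lab[is.na(n_lab)] <- 0
    cum <- cumsum(n_lab) / sum(n_lab)
    msc <- tapply(zc, factor(bin, levels = seq_len(nb)), mean)
    rows[[cat]] <- data.frame(
      bin = seq_len(nb), t_lo = edges[-(nb + 1)], t_hi = edges[-1],
      category = cat, mean_score = as.numeric(msc),
      n_labeled = as.integer(n_lab), cum_frac = as.numeric(cum))
    prev <- c(0, cum[-nb])
    i <- which(cum >= 0.5)[1]
    onset[cat] <- if (cum[i] > prev[i])
      edges[i] + (0.5 - prev[i]) / (cum[i] - prev[i]) * (edges[i + 1] - edges[i])
    else edges[i]
  }
  list(bins = do.call(rbind, rows), onset = onset)
}

#' Identity dendrogram
#'
#' Average-linkage agglomeration on the correlation distance between group
#' mean log-normalized profiles over the highly variable genes. Typical
#' groups: the four nuclei (VB, Po, LG, LP) plus the progenitor classes
#' (AP, BP). Groups with fewer than 3 cells are dropped with a warning.
#'
#' @param matrix ExpressionMatrix with a lognorm layer.
#' @param groups named per-cell group labels (names = cell ids); NA cells
#'   are ignored.
#' @param hvg genes to profile over (default: all genes).
#' @return `hclust` object (deterministic leaf order).
#' @export
identity_dendrogram <- function(matrix, groups, hvg = NULL) {
  if (is.null(hvg)) hvg <- gene_ids(matrix)
  groups <- groups[!is.na(groups)]
  ids <- intersect(names(groups), cell_ids(matrix))
  groups <- groups[ids]
  tab <- table(groups)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("groups dropped (fewer than 3 cells): ",
            paste(small, collapse = ", "))
    groups <- groups[!groups %in% small]
  }
  if (length(unique(groups)) < 2) stop("need at least 2 usable groups")
  X <- .lognorm_dense(matrix[names(groups), hvg])
  means <- do.call(rbind, lapply(sort(unique(groups)), function(g)
    colMeans(X[groups == g, , drop = FALSE])))
  rownames(means) <- sort(unique(groups))
  keep <- apply(means, 2, stats::sd) > 0
  d <- stats::as.dist(1 - stats::cor(t(means[, keep, drop = FALSE])))
  stats::hclust(d, method = "average")
}

#' Fit the seed-cell marker-bootstrapping identity mapper
#'
#' The package's core fitting function. Starting from mature (reference)
#' markers for two or more categories, it: (1) scores every cell with each
#' category's mature pseudogene (top `cfg$n_seed_markers` reference genes);
#' (2) takes the terminal-stage cells at or above the `cfg$seed_quantile`
#' score quantile as seed cells; (3) re-derives stage-appropriate markers by
#' one-vs-rest differential expression between seed groups (top
#' `cfg$n_round2_markers` by fold-change); (4) assigns every post-mitotic
#' cell to the category with the highest z-normalized derived pseudogene,
#' retaining cells at or above the `cfg$retain_quantile` quantile of the
#' winning raw pseudogene. With exactly two categories a ratio score is
#' added, and if a pseudotime field is supplied, binned emergence curves
#' and category onsets are computed. The procedure is deterministic: no
#' step uses random numbers.
#'
#' @param matrix ExpressionMatrix with a lognorm layer.
#' @param reference_markers [marker_set()] of mature markers (provenance
#'   `"reference"`, e.g. [reference_marker_table()] or a published table).
#' @param terminal_mask logical/character mask of terminal-stage cells
#'   (e.g. the last age point) used for seeding.
#' @param cells optional post-mitotic (neuron) cell ids for assignment.
#' @param pt optional `PseudotimeField` for emergence statistics.
#' @param cfg [pipeline_config()].
#' @param categories categories to map (default: all in the reference).
#' @param ground_state tie-break category (see [assign_identity()]).
#' @return object of class `identity_fit`: list with `calls`
#'   (`IdentityCall`), `markers` (derived round-2 [marker_set()]),
#'   `seed_cells` (list per category), `reference` (input markers),
#'   `ratio` (named vector, two-category fits), `emergence`, `onset`,
#'   `cfg`.
#' @export
identity_bootstrap <- function(matrix, reference_markers, terminal_mask,
                               cells = NULL, pt = NULL,
                               cfg = pipeline_config(),
                               categories = NULL, ground_state = NULL) {
  if (is.null(categories)) categories <- unique(reference_markers$category)
  if (length(categories) < 2) stop("need at least 2 categories")
  seeds <- list()
  for (cat in categories) {
    genes <- marker_genes(reference_markers, cat, cfg$n_seed_markers)
    sc <- score_pseudogene(matrix, genes)
    seeds[[cat]] <- select_seed_cells(sc, terminal_mask, cfg)
  }
  derived <- derive_embryonic_markers(matrix, seeds, cfg)
  calls <- assign_identity(matrix, derived, cfg, cells = cells,
                           ground_state = ground_state)
  ratio <- NULL
  if (length(categories) == 2) {
    fo_like <- setdiff(categories, calls$ground_state)[1]
    ratio <- stats::setNames(
      ratio_score(calls$scores[, fo_like],
                  calls$scores[, calls$ground_state]),
      calls$cells$cell_id)
  }
  emergence <- NULL; onset <- NULL
  if (!is.null(pt)) {
    emergence <- emergence_curves(pt, calls, cfg)
    onset <- emergence$onset
  }
  structure(list(calls = calls, markers = derived, seed_cells = seeds,
                 reference = reference_markers, ratio = ratio,
                 emergence = emergence, onset = onset, cfg = cfg),
            class = "identity_fit")
}

#' @export
print.identity_fit <- function(x, ...) {
  cats <- x$calls$categories
  cat("Seed-cell bootstrapped identity fit\n")
  cat(sprintf("  categories : %s (ground state %s)\n",
              paste(cats, collapse = " vs "), x$calls$ground_state))
  cat(sprintf("  seed cells : %s\n",
              paste(sprintf("%s=%d", cats, lengths(x$seed_cells[cats])),
                    collapse = ", ")))
  tab <- table(x$calls$cells$label)
  cat(sprintf("  calls      : %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  if (!is.null(x$onset))
    cat(sprintf("  onset      : %s\n",
                paste(sprintf("%s=%.3f", names(x$onset), x$onset),
                      collapse = ", ")))
  invisible(x)
}

#' @export
summary.identity_fit <- function(object, ...) {
  out <- list(categories = object$calls$categories,
              n_cells = nrow(object$calls$cells),
              n_retained = sum(object$calls$cells$retained),
              labels = table(object$calls$cells$label),
              n_markers = table(object$markers$category),
              onset = object$onset)
  class(out) <- "summary.identity_fit"
  out
}

#' @export
print.summary.identity_fit <- function(x, ...) {
  cat(sprintf("identity fit: %d cells, %d retained (%.1f%%)\n",
              x$n_cells, x$n_retained, 100 * x$n_retained / x$n_cells))
  print(x$labels)
  if (!is.null(x$onset)) {
    cat("onsets (pseudotime at half cumulative count):\n")
    print(round(x$onset, 3))
  }
  invisible(x)
}

#' Derived marker table of an identity fit
#' @param object `identity_fit`.
#' @param ... ignored.
#' @return the derived round-2 [marker_set()].
#' @export
coef.identity_fit <- function(object, ...) object$markers

#' Plot emergence curves of an identity fit
#'
#' Per-category normalized cumulative labeled-cell counts across the
#' pseudotime bins, with onsets marked.
#'
#' @param x `identity_fit` fitted with a pseudotime field.
#' @param ... passed to `plot`.
#' @export
plot.identity_fit <- function(x, ...) {
  if (is.null(x$emergence)) stop("fit has no emergence curves (no pseudotime)")
  b <- x$emergence$bins
  cats <- unique(b$category)
  cols <- grDevices::hcl.colors(length(cats), "Dark 3")
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "pseudotime bin",
                 ylab = "cumulative labeled fraction", ...)
  for (i in seq_along(cats)) {
    bi <- b[b$category == cats[i], ]
    graphics::lines(c(bi$t_lo[1], bi$t_hi), c(0, bi$cum_frac),
                    col = cols[i], lwd = 2, type = "s")
    graphics::abline(v = x$onset[cats[i]], col = cols[i], lty = 3)
  }
  graphics::abline(h = 0.5, col = "grey60", lty = 2)
  graphics::legend("topleft", legend = cats, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
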