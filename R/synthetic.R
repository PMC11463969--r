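# Negative-binomial count simulator with full ground truth. The generated
# structure mirrors what the analysis assumes: a progenitor->neuron
# maturation continuum sampled at discrete ages, sequential gene-activation
# waves, an early-onset persistent HO identity program versus a late-onset
# transient FO program, nucleus programs (VB/LG under FO, Po/LP under HO)
# nested under order with weaker modality sharing, and a postnatal
# deprivation condition that lags FO glutamatergic maturation only.

#' Generator configuration
#'
#' All knobs of the synthetic dataset. Maturation `m` runs in `[0, 1]` from
#' apical progenitor to terminal neuron; each age cohort draws `m` from a
#' truncated normal centred at `(i - 0.5) / age_points`, so cohorts overlap.
#' Identity programs are smooth maturation windows: genes switch on at
#' `onset` and, past `offset`, decay to `retention_floor` of their plateau
#' (FO identity is transient, but mature FO cells retain partial marker
#' expression, which is what makes terminal-stage seeding possible).
#'
#' @param n_cells cells per age point.
#' @param age_points number of age cohorts (embryonic default 6, mimicking
#'   E11.5-E18.5 sampling; postnatal stage uses 2, P3/P7-like).
#' @param n_waves,genes_per_wave,wave_width sequential activation waves:
#'   Gaussian bumps in `m` with evenly spaced centres `(w - 0.5) / n_waves`.
#' @param order_windows named list of `c(onset, offset)` maturation windows
#'   for the order programs; HO switches on early and persists, FO late and
#'   transiently.
#' @param genes_per_order genes per order program.
#' @param nucleus_windows named list of windows for the nucleus programs
#'   (VB, LG nested under FO; Po, LP under HO).
#' @param genes_per_nucleus genes per nucleus program.
#' @param n_mature_markers genes flagged per category as mature markers
#'   (those with the largest terminal-stage effect).
#' @param order_weight,modality_weight expression weight of a nucleus
#'   program in its own nucleus vs the same-modality partner nucleus; order
#'   similarity must dominate modality similarity (1.0 vs 0.4 by default).
#' @param interneuron_fraction fraction of interneurons (postnatal only).
#' @param n_interneuron_genes interneuron marker program size.
#' @param n_housekeeping constant housekeeping genes.
#' @param dispersion shared negative-binomial dispersion (size = 1 /
#'   dispersion).
#' @param libsize_meanlog,libsize_sdlog log-normal per-cell library size.
#' @param deprivation list with `affected_fraction` (share of
#'   developmentally regulated FO-cell genes re-drawn under deprivation) and
#'   `lag` (maturation units lost).
#' @param seed RNG seed; a dataset is deterministic given the config.
#' @param stage `"embryonic"` (glutamatergic only, 6 ages) or `"postnatal"`
#'   (LG/LP dissections, interneurons present, 2 ages).
#' @param age_m_sd embryonic within-cohort maturation sd.
#' @param postnatal_m_centers,postnatal_m_sd postnatal cohort maturation.
#' @param baseline off-program relative expression floor.
#' @param amp_range per-gene activation amplitude range (uniform).
#' @param steepness sigmoid steepness of window edges (maturation units).
#' @param retention_floor fraction of plateau expression retained past a
#'   window's offset.
#' @param hk_sdlog spread of housekeeping expression levels.
#'
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_cells = 330L,
                             age_points = 6L,
                             n_waves = 4L,
                             genes_per_wave = 60L,
                             wave_width = 0.12,
                             order_windows = list(HO = c(0.35, 1.00),
                                                  FO = c(0.75, 0.95)),
                             genes_per_order = 80L,
                             nucleus_windows = list(Po = c(0.40, 1.00),
                                                    LP = c(0.40, 1.00),
                                                    VB = c(0.78, 0.95),
                                                    LG = c(0.78, 0.95)),
                             genes_per_nucleus = 40L,
                             n_mature_markers = 15L,
                             order_weight = 1.0,
                             modality_weight = 0.4,
                             interneuron_fraction = 0.15,
                             n_interneuron_genes = 40L,
                             n_housekeeping = 500L,
                             dispersion = 0.3,
                             libsize_meanlog = 9.2,
                             libsize_sdlog = 0.35,
                             deprivation = list(affected_fraction = 0.10,
                                                lag = 0.15),
                             seed = 1L,
                             stage = c("embryonic", "postnatal"),
                             age_m_sd = 0.10,
                             postnatal_m_centers = c(0.80, 0.95),
                             postnatal_m_sd = 0.08,
                             baseline = 0.02,
                             amp_range = c(1, 3),
                             steepness = 0.02,
                             retention_floor = 0.35,
                             hk_sdlog = 0.5) {
  stage <- match.arg(stage)
  if (stage == "postnatal") age_points <- length(postnatal_m_centers)
  gcfg <- as.list(environment())
  for (w in c(gcfg$order_windows, gcfg$nucleus_windows))
    if (w[1] >= w[2]) stop("window onset must precede offset")
  centers <- (seq_len(n_waves) - 0.5) / n_waves
  if (any(diff(centers) <= 0)) stop("wave centers must strictly increase")
  for (k in c("interneuron_fraction", "retention_floor"))
    if (gcfg[[k]] < 0 || gcfg[[k]] > 1) stop(k, " must lie in [0,1]")
  dep <- gcfg$deprivation
  if (dep$affected_fraction < 0 || dep$affected_fraction > 1)
    stop("deprivation$affected_fraction must lie in [0,1]")
  if (dep$lag < 0) stop("deprivation$lag must be non-negative")
  for (k in c("n_cells", "genes_per_wave", "genes_per_order",
              "genes_per_nucleus", "n_housekeeping", "n_interneuron_genes"))
    if (gcfg[[k]] < 1) stop(k, " must be positive")
  if (n_mature_markers > genes_per_order ||
      n_mature_markers > genes_per_nucleus)
    stop("n_mature_markers exceeds the per-program gene count")
  gcfg$wave_centers <- centers
  class(gcfg) <- "generator_config"
  gcfg
}

# Smooth activation window: sigmoid rise at onset; past offset, decay to
# `floor` of the plateau (transient programs leave a partial mature trace).
.window_activation <- function(m, onset, offset, steep, floor) {
  rise <- stats::plogis((m - onset) / steep)
  retain <- floor + (1 - floor) * stats::plogis((offset - m) / steep)
  rise * retain
}

.wave_activation <- function(m, center, width) {
  exp(-(m - center)^2 / (2 * width^2))
}

# Gene parameter table. Deterministic given the RNG state.
.make_gene_table <- function(gcfg) {
  rows <- list()
  idx <- 0L
  add <- function(n, program, prefix, ...) {
    extra <- list(...)
    df <- data.frame(gene_id = sprintf("%s_%03d", prefix, seq_len(n)),
                     program = program,
                     amplitude = stats::runif(n, gcfg$amp_range[1],
                                              gcfg$amp_range[2]),
                     stringsAsFactors = FALSE)
    for (k in names(extra)) df[[k]] <- extra[[k]]
    df
  }
  for (w in seq_len(gcfg$n_waves))
    rows[[length(rows) + 1L]] <-
      add(gcfg$genes_per_wave, sprintf("wave%d", w), sprintf("W%d", w),
          wave = w, center = gcfg$wave_centers[w], width = gcfg$wave_width)
  for (ord in names(gcfg$order_windows)) {
    win <- gcfg$order_windows[[ord]]
    rows[[length(rows) + 1L]] <-
      add(gcfg$genes_per_order, ord, ord, onset = win[1], offset = win[2])
  }
  modality <- c(VB = "somatosensory", Po = "somatosensory",
                LG = "visual", LP = "visual")
  nucleus_order <- c(VB = "FO", LG = "FO", Po = "HO", LP = "HO")
  for (nuc in names(gcfg$nucleus_windows)) {
    win <- gcfg$nucleus_windows[[nuc]]
    rows[[length(rows) + 1L]] <-
      add(gcfg$genes_per_nucleus, nuc, nuc, onset = win[1], offset = win[2],
          modality = modality[[nuc]], nucleus_order = nucleus_order[[nuc]])
  }
  rows[[length(rows) + 1L]] <-
    add(gcfg$n_interneuron_genes, "IN", "IN")
  hk <- data.frame(gene_id = sprintf("HK_%03d", seq_len(gcfg$n_housekeeping)),
                   program = "housekeeping",
                   amplitude = stats::rlnorm(gcfg$n_housekeeping, 0,
                                             gcfg$hk_sdlog),
                   stringsAsFactors = FALSE)
  cols <- c("gene_id", "program", "amplitude", "wave", "center", "width",
            "onset", "offset", "modality", "nucleus_order")
  rows <- lapply(c(rows, list(hk)), function(df) {
    for (cn in setdiff(cols, names(df)))
      df[[cn]] <- if (cn %in% c("modality", "nucleus_order")) NA_character_
                  else NA_real_
    df[, cols]
  })
  genes <- do.call(rbind, rows)
  # Mature-marker flags: per identity category, the genes with the largest
  # terminal-stage effect (amplitude x activation at m = 1).
  genes$terminal_effect <- 0
  idn <- genes$program %in% c(names(gcfg$order_windows),
                              names(gcfg$nucleus_windows))
  genes$terminal_effect[idn] <- genes$amplitude[idn] *
    .window_activation(1, genes$onset[idn], genes$offset[idn],
                       gcfg$steepness, gcfg$retention_floor)
  genes$mature_marker <- FALSE
  for (cat in c(names(gcfg$order_windows), names(gcfg$nucleus_windows))) {
    sel <- which(genes$program == cat)
    top <- sel[order(genes$terminal_effect[sel],
                     decreasing = TRUE)][seq_len(gcfg$n_mature_markers)]
    genes$mature_marker[top] <- TRUE
  }
  genes$affected <- FALSE
  genes
}

.truncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.make_cell_table <- function(gcfg) {
  n_ages <- gcfg$age_points
  if (gcfg$stage == "embryonic") {
    labels <- if (n_ages == 6L)
      c("E11.5", "E12.5", "E13.5", "E14.5", "E16.5", "E18.5") else
      sprintf("E%02d", seq_len(n_ages))
    centers <- (seq_len(n_ages) - 0.5) / n_ages
    sdm <- gcfg$age_m_sd
  } else {
    labels <- sprintf("P%d", c(3, 7))[seq_len(n_ages)]
    centers <- gcfg$postnatal_m_centers
    sdm <- gcfg$postnatal_m_sd
  }
  age <- rep(labels, each = gcfg$n_cells)
  n <- length(age)
  m <- .truncnorm(n, rep(centers, each = gcfg$n_cells), sdm)
  cls <- cut(m, c(-Inf, 0.25, 0.5, 0.75, Inf),
             labels = c("AP", "BP", "EN", "LN"))
  if (gcfg$stage == "embryonic") {
    nucleus <- sample(c("VB", "Po", "LG", "LP"), n, replace = TRUE)
    region <- rep("TH", n)
    cell_type <- rep("glut", n)
  } else {
    region <- sample(c("LG", "LP"), n, replace = TRUE)
    cell_type <- ifelse(stats::runif(n) < gcfg$interneuron_fraction,
                        "IN", "glut")
    nucleus <- ifelse(cell_type == "glut", region, "none")
  }
  ord <- c(VB = "FO", LG = "FO", Po = "HO", LP = "HO", none = "none")[nucleus]
  data.frame(cell_id = sprintf("C%05d", seq_len(n)),
             m = m, class = as.character(cls),
             order = unname(ord), nucleus = nucleus,
             cell_type = cell_type, condition = "control",
             age = age, region = region,
             library = paste0(labels[match(age, labels)], "_ctl"),
             stringsAsFactors = FALSE)
}

# Relative expression matrix (cells x genes): baseline + program activations.
.generating_relexpr <- function(cells, genes, gcfg, m = cells$m) {
  n <- nrow(cells); G <- nrow(genes)
  r <- matrix(gcfg$baseline, n, G,
              dimnames = list(cells$cell_id, genes$gene_id))
  hk <- genes$program == "housekeeping"
  r[, hk] <- rep(genes$amplitude[hk], each = n)
  for (w in seq_len(gcfg$n_waves)) {
    sel <- genes$program == sprintf("wave%d", w)
    act <- .wave_activation(m, gcfg$wave_centers[w], gcfg$wave_width)
    r[, sel] <- r[, sel] + act %o% genes$amplitude[sel]
  }
  for (ord in names(gcfg$order_windows)) {
    sel <- genes$program == ord
    win <- gcfg$order_windows[[ord]]
    act <- .window_activation(m, win[1], win[2], gcfg$steepness,
                              gcfg$retention_floor) *
      (cells$order == ord & cells$cell_type == "glut") * gcfg$order_weight
    r[, sel] <- r[, sel] + act %o% genes$amplitude[sel]
  }
  modality_of <- c(VB = "somatosensory", Po = "somatosensory",
                   LG = "visual", LP = "visual")
  cell_modality <- modality_of[cells$nucleus]
  for (nuc in names(gcfg$nucleus_windows)) {
    sel <- genes$program == nuc
    win <- gcfg$nucleus_windows[[nuc]]
    base <- .window_activation(m, win[1], win[2], gcfg$steepness,
                               gcfg$retention_floor)
    own <- cells$nucleus == nuc
    partner <- !own & !is.na(cell_modality) &
      cell_modality == modality_of[[nuc]] & cells$cell_type == "glut"
    weight <- ifelse(own, 1, ifelse(partner, gcfg$modality_weight, 0))
    r[, sel] <- r[, sel] + (base * weight) %o% genes$amplitude[sel]
  }
  sel <- genes$program == "IN"
  r[, sel] <- r[, sel] +
    (cells$cell_type == "IN") %o% genes$amplitude[sel]
  r
}

.draw_counts <- function(relexpr, libsize, dispersion) {
  p <- relexpr / rowSums(relexpr)
  mu <- p * libsize
  n <- length(mu)
  counts <- matrix(stats::rnbinom(n, mu = mu, size = 1 / dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
}

#' Simulate a ground-truth single-cell dataset
#'
#' Draws negative-binomial counts whose means follow the generator's program
#' structure: each gene's relative expression is a baseline plus the sum of
#' its program activations at the cell's maturation `m` (Gaussian bumps for
#' waves, smooth on/off windows for identity programs), scaled to a
#' log-normal per-cell library size. Deterministic given `gcfg$seed`.
#'
#' @param gcfg [generator_config()].
#' @return list with `matrix` (ExpressionMatrix) and `truth`
#'   (`SyntheticTruth`: `$cells` and `$genes` data frames).
#' @export
simulate_dataset <- function(gcfg) {
  stopifnot(inherits(gcfg, "generator_config"))
  set.seed(gcfg$seed)
  genes <- .make_gene_table(gcfg)
  cells <- .make_cell_table(gcfg)
  cells$libsize <- stats::rlnorm(nrow(cells), gcfg$libsize_meanlog,
                                 gcfg$libsize_sdlog)
  r <- .generating_relexpr(cells, genes, gcfg)
  counts <- .draw_counts(r, cells$libsize, gcfg$dispersion)
  meta <- cells[, c("cell_id", "age", "region", "condition", "library",
                    "cell_type")]
  mat <- expression_matrix(counts, cell_meta = meta)
  truth <- structure(list(cells = cells, genes = genes, gcfg = gcfg),
                     class = "SyntheticTruth")
  list(matrix = mat, truth = truth)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: %d cells, %d genes (%s stage)\n",
              nrow(x$cells), nrow(x$genes), x$gcfg$stage))
  print(table(x$cells$class))
  invisible(x)
}

#' Simulate an input-deprived twin cohort
#'
#' Builds a deprived cohort matched to a (postnatal) control dataset: every
#' cell is re-drawn from the same generating means, except that in FO
#' glutamatergic cells a fraction of the developmentally regulated genes
#' (waves, FO order program, FO-side nucleus programs) are drawn at the
#' lagged effective maturation `m' = max(0, m - lag)`. HO cells and
#' interneurons keep identical generating means. Returns the merged
#' control + deprived dataset with affected-gene flags recorded in the
#' truth.
#'
#' @param matrix control ExpressionMatrix from [simulate_dataset()].
#' @param truth matching `SyntheticTruth`.
#' @param gcfg the generator config (uses `deprivation$affected_fraction`,
#'   `deprivation$lag`).
#' @return list with merged `matrix` and `truth`.
#' @export
simulate_deprivation <- function(matrix, truth, gcfg) {
  stopifnot(inherits(gcfg, "generator_config"),
            inherits(truth, "SyntheticTruth"))
  dep <- gcfg$deprivation
  if (dep$lag < 0) stop("lag must be non-negative")
  cells <- truth$cells; genes <- truth$genes
  fo_cells <- cells$order == "FO" & cells$cell_type == "glut"
  if (!any(fo_cells)) stop("no FO glutamatergic cells present")
  set.seed(gcfg$seed + 1L)
  # Eligible genes: wave or FO-side program genes that are actually
  # developmentally regulated over the maturation range of the FO cells in
  # THIS dataset (activation sd >= 0.05); lagging a flat gene is a no-op.
  cand <- which(genes$program %in%
                  c(sprintf("wave%d", seq_len(gcfg$n_waves)), "FO",
                    "VB", "LG"))
  r_fo <- .generating_relexpr(cells[fo_cells, , drop = FALSE], genes, gcfg)
  act_sd <- apply(r_fo[, cand, drop = FALSE], 2, stats::sd) /
    pmax(genes$amplitude[cand], 1e-9)
  eligible <- cand[act_sd >= 0.05]
  if (!length(eligible)) stop("no developmentally regulated FO genes ",
                              "in this dataset's maturation range")
  n_aff <- round(dep$affected_fraction * length(eligible))
  affected <- if (n_aff > 0) sample(eligible, n_aff) else integer(0)
  genes$affected <- FALSE
  genes$affected[affected] <- TRUE

  r <- .generating_relexpr(cells, genes, gcfg)
  if (length(affected) && any(fo_cells)) {
    m_lag <- pmax(0, cells$m - dep$lag)
    r_lag <- .generating_relexpr(cells[fo_cells, , drop = FALSE],
                                 genes, gcfg, m = m_lag[fo_cells])
    r[fo_cells, affected] <- r_lag[, affected]
  }
  counts_dep <- .draw_counts(r, cells$libsize, gcfg$dispersion)
  dep_cells <- cells
  dep_cells$cell_id <- paste0(cells$cell_id, "-enu")
  dep_cells$condition <- "deprived"
  dep_cells$library <- sub("_ctl$", "_enu", cells$library)
  rownames(counts_dep) <- dep_cells$cell_id
  meta_dep <- dep_cells[, c("cell_id", "age", "region", "condition",
                            "library", "cell_type")]
  dep_mat <- expression_matrix(counts_dep, cell_meta = meta_dep)
  merged <- merge_libraries(list(matrix, dep_mat))
  truth_out <- structure(list(cells = rbind(cells, dep_cells),
                              genes = genes, gcfg = gcfg),
                         class = "SyntheticTruth")
  list(matrix = merged, truth = truth_out)
}

#' Reference marker table from ground truth
#'
#' Stand-in for a published mature-marker table: returns, per identity
#' category, the top `n_per_category` mature-marker-flagged genes ranked by
#' terminal-stage effect size.
#'
#' @param truth `SyntheticTruth`.
#' @param n_per_category markers per category.
#' @param categories categories to include (default: all flagged ones).
#' @return [marker_set()] with provenance `"reference"`; the effect column
#'   is the log2 terminal-stage fold over baseline.
#' @export
reference_marker_table <- function(truth, n_per_category = 15L,
                                   categories = NULL) {
  genes <- truth$genes
  flagged <- genes[genes$mature_marker, , drop = FALSE]
  if (is.null(categories)) categories <- unique(flagged$program)
  out <- lapply(categories, function(cat) {
    g <- flagged[flagged$program == cat, , drop = FALSE]
    if (nrow(g) < n_per_category)
      stop(sprintf("only %d flagged genes available for %s (requested %d)",
                   nrow(g), cat, n_per_category))
    g <- g[order(g$terminal_effect, decreasing = TRUE), ][
      seq_len(n_per_category), ]
    data.frame(category = cat, gene_id = g$gene_id,
               log2fc = log2((truth$gcfg$baseline + g$terminal_effect + 1) /
                               (truth$gcfg$baseline + 1)),
               padj = NA_real_, stringsAsFactors = FALSE)
  })
  marker_set(do.call(rbind, out), provenance = "reference")
}

#' Write ground truth tables as CSV
#'
#' @param truth `SyntheticTruth`.
#' @param out_dir directory for `truth_cells.csv` / `truth_genes.csv`.
#' @return file paths, invisibly.
#' @export
write_truth <- function(truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cells = file.path(out_dir, "truth_cells.csv"),
             genes = file.path(out_dir, "truth_genes.csv"))
  utils::write.csv(truth$cells, paths[["cells"]], row.names = FALSE)
  utils::write.csv(truth$genes, paths[["genes"]], row.names = FALSE)
  invisible(paths)
}
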