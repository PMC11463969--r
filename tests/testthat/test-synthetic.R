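test_that("same seed reproduces the dataset exactly", {
  g <- tiny_gcfg(seed = 3L)
  a <- simulate_dataset(g)
  b <- simulate_dataset(g)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$truth$genes, b$truth$genes)
})

test_that("activation windows are closed at m = 0", {
  # generating means, not draws: wave 2..4 and identity programs must sit
  # at baseline for a cell at the very start of the trajectory
  g <- tiny_gcfg()
  genes <- thalamap:::.make_gene_table(g)
  cells <- data.frame(cell_id = "c1", m = 0, class = "AP", order = "FO",
                      nucleus = "VB", cell_type = "glut",
                      condition = "control", stringsAsFactors = FALSE)
  r <- thalamap:::.generating_relexpr(cells, genes, g)
  late <- genes$program %in% c("wave2", "wave3", "wave4", "FO", "HO",
                               "VB", "Po", "LG", "LP")
  excess <- r[1, late] - g$baseline
  expect_true(all(excess < 0.03 * genes$amplitude[late]))
  # wave 1 is open near m = 0
  w1 <- genes$program == "wave1"
  expect_true(all(r[1, w1] - g$baseline > 0.3 * genes$amplitude[w1]))
})

test_that("HO windows open before FO windows under defaults", {
  g <- generator_config()
  expect_lt(g$order_windows$HO[1], g$order_windows$FO[1])
  expect_gt(diff(g$order_windows$HO), diff(g$order_windows$FO))
  expect_lt(g$nucleus_windows$Po[1], g$nucleus_windows$VB[1])
  expect_lt(g$nucleus_windows$LP[1], g$nucleus_windows$LG[1])
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config(order_windows = list(HO = c(0.9, 0.2),
                                                     FO = c(0.75, 0.95))),
               "onset must precede offset")
  expect_error(generator_config(n_mature_markers = 100L,
                                genes_per_nucleus = 40L),
               "exceeds")
  expect_error(generator_config(deprivation = list(affected_fraction = 0.1,
                                                   lag = -1)),
               "lag")
})

test_that("wave means peak in the right maturation bin (Monte Carlo)", {
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    g <- tiny_gcfg(seed = seed)
    sim <- simulate_dataset(g)
    m <- sim$truth$cells$m
    bins <- cut(m, seq(0, 1, 0.1), include.lowest = TRUE, labels = FALSE)
    X <- as.matrix(sim$matrix$counts)
    # library-size normalize so bin means compare expression, not depth
    X <- X / rowSums(X)
    for (w in 1:4) {
      sel <- sim$truth$genes$program == sprintf("wave%d", w)
      prof <- tapply(rowMeans(X[, sel]), bins, mean)
      peak_bin <- as.integer(names(prof)[which.max(prof)])
      center_bin <- findInterval(g$wave_centers[w], seq(0, 1, 0.1),
                                 rightmost.closed = TRUE)
      total <- total + 1L
      if (peak_bin == center_bin) hits <- hits + 1L
    }
  }
  # >= 3 of 4 waves on average across seeds
  expect_gte(hits, 0.75 * total)
})

test_that("library sizes are conserved within sampling error", {
  g <- tiny_gcfg(seed = 5L)
  sim <- simulate_dataset(g)
  tot <- sum(sim$matrix$counts)
  expected <- sum(sim$truth$cells$libsize)
  expect_lt(abs(tot - expected) / expected, 0.05)
})

test_that("reference marker table returns flagged, disjoint, ranked genes", {
  g <- tiny_gcfg(seed = 2L)
  sim <- simulate_dataset(g)
  ref <- reference_marker_table(sim$truth, 15)
  genes <- sim$truth$genes
  for (cat in unique(ref$category)) {
    ids <- marker_genes(ref, cat)
    rows <- genes[match(ids, genes$gene_id), ]
    expect_true(all(rows$mature_marker))
    expect_true(all(rows$program == cat))
  }
  expect_length(intersect(marker_genes(ref, "FO"), marker_genes(ref, "HO")),
                0)
  one <- reference_marker_table(sim$truth, 1, categories = "FO")
  best <- genes[genes$program == "FO" & genes$mature_marker, ]
  expect_identical(one$gene_id,
                   best$gene_id[which.max(best$terminal_effect)])
  expect_error(reference_marker_table(sim$truth, 999), "available")
})

test_that("deprivation is the identity when lag = 0 and flags none at fraction 0", {
  g <- tiny_gcfg(seed = 4L, stage = "postnatal",
                 deprivation = list(affected_fraction = 0.1, lag = 0))
  sim <- simulate_dataset(g)
  dep <- simulate_deprivation(sim$matrix, sim$truth, g)
  cells <- dep$truth$cells
  genes <- dep$truth$genes
  # lag 0: generating means of the deprived cohort equal the control means,
  # so per-gene mean counts agree within Monte Carlo error
  ctl <- dep$matrix[cells$cell_id[cells$condition == "control"], ]
  enu <- dep$matrix[cells$cell_id[cells$condition == "deprived"], ]
  aff <- genes$gene_id[genes$affected]
  expect_gt(length(aff), 0)
  mc <- Matrix::colSums(ctl$counts[, aff]) / nrow(ctl$counts)
  md <- Matrix::colSums(enu$counts[, aff]) / nrow(enu$counts)
  expect_gt(cor(mc, md), 0.98)
  expect_lt(abs(mean(md - mc)) / mean(mc), 0.1)

  g0 <- tiny_gcfg(seed = 4L, stage = "postnatal",
                  deprivation = list(affected_fraction = 0, lag = 0.15))
  dep0 <- simulate_deprivation(sim$matrix, sim$truth, g0)
  expect_equal(sum(dep0$truth$genes$affected), 0)
})

test_that("affected late-wave genes drop in deprived FO cells (20 seeds)", {
  lower <- 0L
  for (seed in 1:20) {
    g <- tiny_gcfg(seed = seed, stage = "postnatal")
    sim <- simulate_dataset(g)
    dep <- simulate_deprivation(sim$matrix, sim$truth, g)
    cells <- dep$truth$cells; genes <- dep$truth$genes
    # late-wave affected genes: the final wave rises through the postnatal
    # window, so a maturation lag lowers it
    aff <- genes$gene_id[genes$affected & !is.na(genes$wave) &
                           genes$wave == g$n_waves]
    if (!length(aff)) next
    fo_ctl <- cells$condition == "control" & cells$order == "FO" &
      cells$cell_type == "glut"
    fo_dep <- cells$condition == "deprived" & cells$order == "FO" &
      cells$cell_type == "glut"
    X <- dep$matrix$counts
    X <- X / Matrix::rowSums(X)
    d <- mean(as.matrix(X[cells$cell_id[fo_dep], aff, drop = FALSE]))
    c_ <- mean(as.matrix(X[cells$cell_id[fo_ctl], aff, drop = FALSE]))
    if (d < c_) lower <- lower + 1L
  }
  expect_gte(lower, 16L)
})

test_that("interneurons are distributionally unaffected by deprivation", {
  g <- generator_config(n_cells = 400L, stage = "postnatal", seed = 11L)
  sim <- simulate_dataset(g)
  dep <- simulate_deprivation(sim$matrix, sim$truth, g)
  cells <- dep$truth$cells
  ins <- cells$cell_type == "IN"
  Xc <- as.matrix(dep$matrix$counts[
    cells$cell_id[ins & cells$condition == "control"], ])
  Xd <- as.matrix(dep$matrix$counts[
    cells$cell_id[ins & cells$condition == "deprived"], ])
  ps <- vapply(seq_len(ncol(Xc)), function(j)
    suppressWarnings(stats::ks.test(Xc[, j], Xd[, j])$p.value), numeric(1))
  expect_equal(sum(p.adjust(ps, "BH") < 0.05), 0)
})

test_that("deprivation requires FO cells and a non-negative lag", {
  g <- tiny_gcfg(seed = 6L)
  sim <- simulate_dataset(g)
  truth2 <- sim$truth
  truth2$cells$order <- "HO"
  expect_error(simulate_deprivation(sim$matrix, truth2, g),
               "no FO glutamatergic cells")
})
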