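postnatal_fixture <- function(seed = 31L, n_cells = 150L) {
  g <- generator_config(n_cells = n_cells, stage = "postnatal",
                        genes_per_wave = 30L, genes_per_order = 40L,
                        genes_per_nucleus = 20L, n_housekeeping = 150L,
                        n_interneuron_genes = 20L, seed = seed)
  sim <- simulate_dataset(g)
  dep <- simulate_deprivation(sim$matrix, sim$truth, g)
  cfg <- pipeline_config(min_genes_per_cell = 50L)
  list(mat = lognormalize(qc_filter(dep$matrix, cfg), cfg),
       truth = dep$truth, cfg = cfg, gcfg = g)
}

test_that("condition_de finds nothing between identical groups (null)", {
  counts <- sapply(1:40, function(i) rpois(120, 4))
  n_sig <- vapply(1:20, function(seed) {
    set.seed(seed)
    meta <- data.frame(region = "LG", cell_type = "glut",
                       condition = sample(rep(c("control", "deprived"),
                                              each = 60)))
    em <- em_from_dense(counts, meta = meta, lognormed = TRUE)
    de <- condition_de(em, "LG")
    nrow(de$up) + nrow(de$down)
  }, numeric(1))
  expect_equal(median(n_sig), 0)
})

test_that("condition_de detects a planted 4-fold shift at n = 200 per side", {
  set.seed(5)
  counts <- sapply(1:30, function(i) rpois(400, 5))
  counts[201:400, 30] <- rpois(200, 20)
  colnames(counts) <- c(sprintf("G%02d", 1:29), "shifted")
  meta <- data.frame(region = "LG", cell_type = "glut",
                     condition = rep(c("control", "deprived"), each = 200))
  em <- em_from_dense(counts, meta = meta, lognormed = TRUE)
  de <- condition_de(em, "LG")
  expect_true("shifted" %in% de$up$gene_id)
  expect_error(condition_de(em, "LP"), "empty region")
})

test_that("deprivation_overlap reproduces exact percentages and properties", {
  dev <- sprintf("d%03d", 1:489)
  de <- c(dev[1:52], sprintf("x%03d", 1:40))
  got <- deprivation_overlap(dev, de)
  expect_equal(got$percent, 10.6)
  expect_equal(got$n_overlap, 52)
  got2 <- deprivation_overlap(sprintf("d%03d", 1:328),
                              sprintf("d%03d", 1:15))
  expect_equal(got2$percent, 4.6)
  expect_equal(deprivation_overlap(dev, "zz")$percent, 0)
  # order-invariance and monotonicity in the intersection
  expect_equal(deprivation_overlap(dev, rev(de)), got)
  more <- deprivation_overlap(dev, c(de, dev[53:60]))
  expect_gte(more$n_overlap, got$n_overlap)
  expect_error(deprivation_overlap(character(0), de), "empty")
})

test_that("pseudotime_lag recovers a constructed shift and respects the null", {
  set.seed(7)
  tc <- runif(300)
  same <- pseudotime_lag(tc, tc, seed = 1)
  expect_equal(same$delta, 0)
  expect_gt(same$p, 0.9)
  shifted <- pmax(0, tc - 0.15)
  lag <- pseudotime_lag(tc, shifted, seed = 1)
  expect_equal(lag$delta, 0.15, tolerance = 0.03)
  expect_lt(lag$p, 0.01)
  expect_error(pseudotime_lag(tc[1:5], tc), "20 cells")
  # stratified variant agrees on a shared shift
  strat <- rep(c("P3", "P7"), 150)
  lag_s <- pseudotime_lag(tc, shifted, seed = 1, strata_control = strat,
                          strata_deprived = strat)
  expect_equal(lag_s$delta, 0.15, tolerance = 0.03)
  expect_lt(lag_s$p, 0.01)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(11)
  ps <- vapply(1:50, function(i) {
    x <- rnorm(40); y <- rnorm(40)
    pseudotime_lag(x, y, n_perm = 200L, seed = i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("marker overlap counting is exact set intersection", {
  ms <- marker_set(data.frame(category = "LP",
                              gene_id = sprintf("m%02d", 1:20),
                              log2fc = 20:1, padj = 0.01), "reference")
  up <- c(sprintf("m%02d", 3:7), "other1", "other2")
  got <- marker_overlap_count(up, ms, "LP")
  expect_equal(got$n_overlap, 5)
  expect_equal(got$n_up, 7)
  expect_equal(marker_overlap_count(sprintf("m%02d", 1:4), ms,
                                    "LP")$n_overlap, 4)
  expect_equal(marker_overlap_count(c("a", "b"), ms, "LP")$n_overlap, 0)
  expect_error(marker_overlap_count(up, ms, "XX"), "unknown category")
  # random fixture vs brute force
  set.seed(3)
  for (i in 1:5) {
    up_r <- sample(sprintf("m%02d", 1:40), 10)
    expect_equal(marker_overlap_count(up_r, ms, "LP")$n_overlap,
                 length(intersect(unique(up_r), sprintf("m%02d", 1:20))))
  }
})

test_that("pca_group_distance returns exact centroid geometry", {
  emb <- rbind(matrix(rep(c(0, 0), each = 30), 30),
               matrix(rep(c(7, 0), each = 30), 30),
               matrix(rep(c(0, 0), each = 30), 30))
  labs <- rep(c("a", "b", "a2"), each = 30)
  d <- pca_group_distance(emb, labs)
  expect_equal(d["a", "a2"], 0)
  expect_equal(d["a", "b"], 7)
  expect_equal(diag(d), setNames(rep(0, 3), rownames(d)))
  expect_equal(d, t(d))
  expect_warning(pca_group_distance(emb, c(labs[-1], "single")),
                 "dropped")
})

test_that("FO-like identity drifts more across ages than HO-like in PCA space", {
  fx <- postnatal_fixture(seed = 33L, n_cells = 200L)
  mat <- fx$mat
  cfg2 <- thalamap:::pipeline_config_clamped(fx$cfg, mat)
  emb <- embed_pca(mat, select_hvg(mat, cfg2), cfg2)
  meta <- mat$cell_meta
  ctl_glut <- meta$condition == "control" & meta$cell_type == "glut"
  grp <- ifelse(ctl_glut, paste(meta$region, meta$age, sep = "_"), NA)
  d <- pca_group_distance(emb, grp)
  expect_gt(d["LG_P3", "LG_P7"], d["LP_P3", "LP_P7"])
})

test_that("label transfer reproduces reference labels on self-transfer", {
  set.seed(9)
  n <- 120
  m <- matrix(rpois(n * 30, 3), n, 30)
  sub <- rep(c("0", "1", "2"), each = 40)
  m[sub == "0", 1:5] <- m[sub == "0", 1:5] + 20
  m[sub == "1", 6:10] <- m[sub == "1", 6:10] + 20
  m[sub == "2", 11:15] <- m[sub == "2", 11:15] + 20
  em <- em_from_dense(m, lognormed = TRUE)
  got <- transfer_subcluster_labels(em, sub, em)
  expect_gte(mean(got == sub), 0.95)
  # degenerate: a single usable subcluster errors
  flat <- em_from_dense(matrix(rpois(60 * 20, 3), 60, 20),
                        lognormed = TRUE)
  expect_error(
    suppressWarnings(transfer_subcluster_labels(
      flat, rep(c("0", "1"), each = 30), flat)),
    "fewer than 2 subclusters")
})

test_that("deprived FO cells shift toward immature subclusters", {
  fx <- postnatal_fixture(seed = 35L, n_cells = 250L)
  mat <- fx$mat; truth <- fx$truth
  meta <- mat$cell_meta
  lg <- meta$region == "LG" & meta$cell_type == "glut"
  ref <- mat[lg & meta$condition == "control", ]
  qry <- mat[lg & meta$condition == "deprived", ]
  # reference subclusters: immature vs mature halves by true maturation
  m_ref <- truth$cells$m[match(cell_ids(ref), truth$cells$cell_id)]
  sub <- ifelse(m_ref < stats::median(m_ref), "immature", "mature")
  # baseline: the classifier's own immature fraction on the control cells
  self <- transfer_subcluster_labels(ref, sub, ref, fx$cfg)
  got <- transfer_subcluster_labels(ref, sub, qry, fx$cfg)
  ctl_frac <- mean(self == "immature")
  dep_frac <- mean(got == "immature")
  expect_gt(dep_frac, ctl_frac)
})

test_that("the deprivation report shows the FO-specific asymmetry", {
  fx <- postnatal_fixture(seed = 37L, n_cells = 300L)
  mat <- fx$mat; truth <- fx$truth
  cfg2 <- thalamap:::pipeline_config_clamped(fx$cfg, mat)
  emb <- embed_pca(mat, select_hvg(mat, cfg2), cfg2)
  prog <- truth$genes$gene_id[!is.na(truth$genes$wave) &
                                truth$genes$wave == 3]
  pt <- suppressWarnings(
    compute_pseudotime(emb, root_cell(mat, prog), fx$cfg))
  rep <- deprivation_report(mat, pt, regions = c("LG", "LP"),
                            cfg = fx$cfg, lag_seed = 1,
                            interneurons = TRUE)
  expect_gte(rep$LG$overlap$percent, rep$LP$overlap$percent)
  expect_gt(rep$LG$lag$delta, rep$LP$lag$delta)
  expect_output(print(rep), "developmental genes affected")
  expect_named(rep, c("LG", "LP", "interneuron"))
})
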