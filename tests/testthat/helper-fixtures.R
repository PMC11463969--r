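# Shared fixture builders and independent oracles.

# Random sparse count ExpressionMatrix with optional metadata columns.
random_matrix <- function(n_cells = 20, n_genes = 10, density = 0.3,
                          max_count = 20, seed = 1, meta = NULL,
                          prefix = "C") {
  set.seed(seed)
  counts <- matrix(0L, n_cells, n_genes)
  nnz <- max(1, round(density * n_cells * n_genes))
  idx <- sample.int(n_cells * n_genes, nnz)
  counts[idx] <- sample.int(max_count, nnz, replace = TRUE)
  dimnames(counts) <- list(sprintf("%s%03d", prefix, seq_len(n_cells)),
                           sprintf("G%03d", seq_len(n_genes)))
  expression_matrix(counts, cell_meta = meta)
}

# ExpressionMatrix straight from a dense matrix (rows = cells).
em_from_dense <- function(m, meta = NULL, lognormed = FALSE,
                          cfg = pipeline_config()) {
  out <- expression_matrix(m, cell_meta = meta)
  if (lognormed) out <- lognormalize(out, cfg)
  out
}

# Brute-force two-sided Wilcoxon p by full enumeration over all splits.
enum_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pool), n1)
  us <- apply(combos, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  # two-sided: as extreme or more, measured by |U - mu|
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Adjusted Rand index (independent of any clustering package).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sij <- comb2(as.vector(tab))
  si <- comb2(rowSums(tab)); sj <- comb2(colSums(tab))
  n2 <- comb2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# Gaussian blob embedding fixture.
blob_embedding <- function(centers, n_per = 50, sd = 1, seed = 1,
                           dims = NULL) {
  set.seed(seed)
  if (is.null(dims)) dims <- ncol(centers)
  out <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * dims, mean = rep(centers[i, ], each = n_per),
                 sd = sd), n_per, dims)))
  rownames(out) <- sprintf("B%04d", seq_len(nrow(out)))
  out
}

# Small, fast generator config for unit tests.
tiny_gcfg <- function(seed = 1L, ...) {
  generator_config(n_cells = 80L, genes_per_wave = 30L,
                   genes_per_order = 40L, genes_per_nucleus = 20L,
                   n_housekeeping = 150L, n_interneuron_genes = 20L,
                   seed = seed, ...)
}

# Relaxed pipeline config for small fixtures; named args override defaults.
tiny_cfg <- function(...) {
  args <- list(min_genes_per_cell = 1L, min_cells_per_gene = 1L,
               n_hvg = 50L, pca_dims = 5L, snn_neighbors = 10L)
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}
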