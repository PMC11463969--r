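#' Pipeline configuration
#'
#' Collects every numeric parameter of the analysis pipeline with the
#' defaults used throughout: cells with fewer than 200 detected genes and
#' genes detected in fewer than 3 cells are removed at QC; counts are scaled
#' to 10,000 per cell before log1p; 2000 variable genes feed a 20-dimensional
#' PCA; neighborhood graphs use 30 neighbors; seed cells are the terminal-
#' stage cells at or above the 0.99 score quantile; identity calls are
#' retained at or above the 0.70 quantile of the winning pseudogene; 10
#' reference markers seed the bootstrap and 15 derived markers are kept per
#' category; emergence statistics use 5 consecutive pseudotime bins;
#' developmentally regulated genes need mean log-normalized expression above
#' 0.5; differential expression is Benjamini-Hochberg corrected at 0.05.
#'
#' @param min_genes_per_cell minimum detected genes for a cell to pass QC.
#' @param min_cells_per_gene minimum cells a gene must be detected in.
#' @param norm_scale per-cell count scale before log1p.
#' @param n_hvg number of highly variable genes.
#' @param pca_dims number of principal components kept.
#' @param snn_neighbors neighbors for SNN/kNN graphs.
#' @param cluster_resolution modularity resolution for SNN clustering.
#' @param seed_quantile within-stage score quantile defining seed cells.
#' @param retain_quantile quantile of the winning pseudogene above which an
#'   identity call is retained ("top 70th quantile" = top 30% of cells).
#' @param n_seed_markers reference (mature) markers used per category.
#' @param n_round2_markers derived embryonic markers kept per category.
#' @param n_bins consecutive pseudotime bins for emergence curves.
#' @param detect_threshold mean log-normalized expression required of a
#'   developmentally regulated gene.
#' @param min_abs_rho effect-size floor for developmental regulation: the
#'   minimum absolute Spearman correlation with pseudotime. At thousands of
#'   cells the BH-adjusted p-value alone admits arbitrarily small
#'   library-composition trends, so a floor is applied on top of it.
#' @param logfc_filter log2 fold-change threshold for "specific" markers.
#' @param de_alpha BH-adjusted significance level.
#' @param rng_seed seed for the stochastic steps (clustering restarts,
#'   permutation tests).
#'
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_genes_per_cell = 200L,
                            min_cells_per_gene = 3L,
                            norm_scale = 10000,
                            n_hvg = 2000L,
                            pca_dims = 20L,
                            snn_neighbors = 30L,
                            cluster_resolution = 0.8,
                            seed_quantile = 0.99,
                            retain_quantile = 0.70,
                            n_seed_markers = 10L,
                            n_round2_markers = 15L,
                            n_bins = 5L,
                            detect_threshold = 0.5,
                            min_abs_rho = 0.25,
                            logfc_filter = 1.0,
                            de_alpha = 0.05,
                            rng_seed = 0L) {
  cfg <- list(min_genes_per_cell = as.integer(min_genes_per_cell),
              min_cells_per_gene = as.integer(min_cells_per_gene),
              norm_scale = norm_scale,
              n_hvg = as.integer(n_hvg),
              pca_dims = as.integer(pca_dims),
              snn_neighbors = as.integer(snn_neighbors),
              cluster_resolution = cluster_resolution,
              seed_quantile = seed_quantile,
              retain_quantile = retain_quantile,
              n_seed_markers = as.integer(n_seed_markers),
              n_round2_markers = as.integer(n_round2_markers),
              n_bins = as.integer(n_bins),
              detect_threshold = detect_threshold,
              min_abs_rho = min_abs_rho,
              logfc_filter = logfc_filter,
              de_alpha = de_alpha,
              rng_seed = as.integer(rng_seed))
  for (q in c("seed_quantile", "retain_quantile"))
    if (cfg[[q]] < 0 || cfg[[q]] >= 1)
      stop(sprintf("%s must lie in [0, 1)", q))
  for (k in c("min_genes_per_cell", "min_cells_per_gene", "n_hvg",
              "pca_dims", "snn_neighbors", "n_seed_markers",
              "n_round2_markers", "n_bins"))
    if (cfg[[k]] < 1L) stop(sprintf("%s must be a positive integer", k))
  for (k in c("norm_scale", "detect_threshold", "logfc_filter", "de_alpha",
              "cluster_resolution", "min_abs_rho"))
    if (cfg[[k]] < 0) stop(sprintf("%s must be non-negative", k))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline/run configuration from YAML
#'
#' The file may contain top-level keys `pipeline:` (fields of
#' [pipeline_config()]), `generator:` (fields of [generator_config()]) and
#' free-form extras (e.g. `progenitor_markers`). Unknown pipeline/generator
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return list with elements `pipeline` (`pipeline_config`), `generator`
#'   (`generator_config` or NULL) and `extra` (remaining keys).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  pl <- raw$pipeline
  if (!is.null(pl)) {
    bad <- setdiff(names(pl), names(formals(pipeline_config)))
    if (length(bad)) stop("unknown pipeline config keys: ",
                          paste(bad, collapse = ", "))
  }
  gen <- raw$generator
  if (!is.null(gen)) {
    bad <- setdiff(names(gen), names(formals(generator_config)))
    if (length(bad)) stop("unknown generator config keys: ",
                          paste(bad, collapse = ", "))
  }
  list(pipeline = do.call(pipeline_config, if (is.null(pl)) list() else pl),
       generator = if (is.null(gen)) NULL else do.call(generator_config, gen),
       extra = raw[setdiff(names(raw), c("pipeline", "generator"))],
       raw = raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
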