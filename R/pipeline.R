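# File-based stage orchestration. Stages communicate through CSV/MTX/JSON
# files only, so each stage is independently testable and re-runnable.

.stage_names <- c("simulate", "deprive", "preprocess", "pseudotime",
                  "waves", "identity", "deprivation-report", "all")

.require_upstream <- function(paths, needed_by) {
  for (p in paths)
    if (!file.exists(p))
      stop("missing upstream output: ", p,
           " (required by stage '", needed_by, "')", call. = FALSE)
}

.read_matrix_dir <- function(dir) {
  read_count_matrix(file.path(dir, "matrix.mtx"),
                    file.path(dir, "genes.csv"),
                    file.path(dir, "cells.csv"))
}

# Recompute the lognorm layer for a matrix read back from disk.
.with_lognorm <- function(mat, cfg) lognormalize(mat, cfg)

.terminal_age <- function(meta, extra) {
  if (!is.null(extra$terminal_age)) return(extra$terminal_age)
  ages <- sort(unique(as.character(meta$age)))
  ages[length(ages)]
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (synthetic dataset + truth + reference markers),
#' `deprive` (adds the deprived cohort), `preprocess` (QC, normalization,
#' HVG, PCA, SNN clusters), `pseudotime` (root, geodesic pseudotime,
#' developmentally regulated genes), `waves`, `identity` (seed-cell
#' bootstrap for every category pair present in the reference table),
#' `deprivation-report`, and `all` (an embryonic chain through identity
#' plus a postnatal chain through the deprivation report, in
#' subdirectories). Each stage reads its inputs from `in_dir`, writes its
#' outputs and a `manifest_<stage>.json` (config snapshot, seed, file
#' lists, timestamps) to `out_dir`, and fails with the missing file named
#' if an upstream output is absent. Deterministic stages are byte-stable
#' given the same config and seed.
#'
#' @param stage_name one of the stages above.
#' @param config_path YAML config (see [read_run_config()]).
#' @param in_dir directory with upstream outputs (defaults to `out_dir`).
#' @param out_dir output directory.
#' @param seed optional override of the config seeds.
#' @return the manifest, invisibly.
#' @export
run_stage <- function(stage_name, config_path, in_dir = out_dir, out_dir,
                      seed = NULL) {
  if (!stage_name %in% .stage_names)
    stop("unknown stage '", stage_name, "'; expected one of: ",
         paste(.stage_names, collapse = ", "))
  rc <- read_run_config(config_path)
  cfg <- rc$pipeline
  gcfg <- rc$generator
  if (!is.null(seed)) {
    cfg$rng_seed <- as.integer(seed)
    if (!is.null(gcfg)) gcfg$seed <- as.integer(seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  tm_log(stage_name, "start")
  outputs <- character(0)
  emit <- function(...) outputs <<- c(outputs, ...)

  if (stage_name == "all") {
    emb_dir <- file.path(out_dir, "embryonic")
    pn_dir <- file.path(out_dir, "postnatal")
    for (st in c("simulate", "preprocess", "pseudotime", "waves",
                 "identity"))
      run_stage(st, config_path, in_dir = emb_dir, out_dir = emb_dir,
                seed = seed)
    # postnatal chain: rewrite the generator stage, keep everything else
    raw <- rc$raw
    raw$generator$stage <- "postnatal"
    pn_cfg <- file.path(out_dir, "config_postnatal.yaml")
    yaml::write_yaml(raw, pn_cfg)
    for (st in c("simulate", "deprive", "preprocess", "pseudotime",
                 "deprivation-report"))
      run_stage(st, pn_cfg, in_dir = pn_dir, out_dir = pn_dir, seed = seed)
    emit(emb_dir, pn_dir)
  } else if (stage_name == "simulate") {
    if (is.null(gcfg)) stop("config lacks a generator: section")
    sim <- simulate_dataset(gcfg)
    emit(write_count_matrix(sim$matrix, out_dir))
    emit(write_truth(sim$truth, out_dir))
    ref <- reference_marker_table(sim$truth,
                                  n_per_category = gcfg$n_mature_markers)
    rp <- file.path(out_dir, "reference_markers.csv")
    utils::write.csv(as.data.frame(ref), rp, row.names = FALSE)
    emit(rp)
  } else if (stage_name == "deprive") {
    if (is.null(gcfg)) stop("config lacks a generator: section")
    need <- file.path(in_dir, c("matrix.mtx", "genes.csv", "cells.csv",
                                "truth_cells.csv", "truth_genes.csv"))
    .require_upstream(need, "deprive")
    mat <- .read_matrix_dir(in_dir)
    truth <- structure(list(
      cells = utils::read.csv(file.path(in_dir, "truth_cells.csv"),
                              stringsAsFactors = FALSE),
      genes = utils::read.csv(file.path(in_dir, "truth_genes.csv"),
                              stringsAsFactors = FALSE),
      gcfg = gcfg), class = "SyntheticTruth")
    dep <- simulate_deprivation(mat, truth, gcfg)
    emit(write_count_matrix(dep$matrix, out_dir))
    emit(write_truth(dep$truth, out_dir))
  } else if (stage_name == "preprocess") {
    need <- file.path(in_dir, c("matrix.mtx", "genes.csv", "cells.csv"))
    .require_upstream(need, "preprocess")
    mat <- .read_matrix_dir(in_dir)
    mat <- qc_filter(mat, cfg)
    mat <- lognormalize(mat, cfg)
    hvg <- select_hvg(mat, pipeline_config_clamped(cfg, mat))
    emb <- embed_pca(mat, hvg, pipeline_config_clamped(cfg, mat))
    cl <- cluster_snn(emb, cfg)
    fdir <- file.path(out_dir, "filtered")
    emit(write_count_matrix(mat, fdir))
    hp <- file.path(out_dir, "hvg.csv")
    utils::write.csv(data.frame(gene_id = hvg), hp, row.names = FALSE)
    ep <- file.path(out_dir, "embedding.csv")
    utils::write.csv(data.frame(cell_id = rownames(emb), emb), ep,
                     row.names = FALSE)
    cp <- file.path(out_dir, "clusters.csv")
    utils::write.csv(data.frame(cell_id = names(cl), cluster = cl), cp,
                     row.names = FALSE)
    emit(hp, ep, cp)
  } else if (stage_name == "pseudotime") {
    need <- c(file.path(in_dir, "filtered", c("matrix.mtx", "genes.csv",
                                              "cells.csv")),
              file.path(in_dir, "embedding.csv"))
    .require_upstream(need, "pseudotime")
    mat <- .with_lognorm(.read_matrix_dir(file.path(in_dir, "filtered")),
                         cfg)
    ed <- utils::read.csv(file.path(in_dir, "embedding.csv"))
    emb <- as.matrix(ed[, -1, drop = FALSE])
    rownames(emb) <- ed$cell_id
    markers <- rc$extra$progenitor_markers
    if (is.null(markers)) {
      tg <- file.path(in_dir, "truth_genes.csv")
      .require_upstream(tg, "pseudotime")
      gt <- utils::read.csv(tg, stringsAsFactors = FALSE)
      markers <- gt$gene_id[!is.na(gt$wave) & gt$wave == 1]
    }
    root <- root_cell(mat, markers)
    pt <- compute_pseudotime(emb, root, cfg)
    pp <- file.path(out_dir, "pseudotime.csv")
    utils::write.csv(data.frame(cell_id = names(pt), t = as.numeric(pt),
                                root = names(pt) == attr(pt, "root_cell")),
                     pp, row.names = FALSE)
    dev <- dev_regulated(mat, pt, cfg)
    dp <- file.path(out_dir, "dev_genes.csv")
    utils::write.csv(dev, dp, row.names = FALSE)
    emit(pp, dp)
  } else if (stage_name == "waves") {
    need <- c(file.path(in_dir, "filtered", c("matrix.mtx", "genes.csv",
                                              "cells.csv")),
              file.path(in_dir, "pseudotime.csv"),
              file.path(in_dir, "dev_genes.csv"))
    .require_upstream(need, "waves")
    mat <- .with_lognorm(.read_matrix_dir(file.path(in_dir, "filtered")),
                         cfg)
    pt <- .read_pt(file.path(in_dir, "pseudotime.csv"))
    dev <- utils::read.csv(file.path(in_dir, "dev_genes.csv"),
                           stringsAsFactors = FALSE)
    prof <- smooth_profiles(mat, pt, dev$gene_id)
    wa <- cluster_waves(prof, seed = cfg$rng_seed)
    wp <- file.path(out_dir, "waves.csv")
    utils::write.csv(wa$genes, wp, row.names = FALSE)
    pp <- file.path(out_dir, "wave_profiles.csv")
    utils::write.csv(data.frame(wave = rownames(wa$profiles), wa$profiles,
                                check.names = FALSE), pp, row.names = FALSE)
    emit(wp, pp)
  } else if (stage_name == "identity") {
    need <- c(file.path(in_dir, "filtered", c("matrix.mtx", "genes.csv",
                                              "cells.csv")),
              file.path(in_dir, "pseudotime.csv"),
              file.path(in_dir, "reference_markers.csv"))
    .require_upstream(need, "identity")
    mat <- .with_lognorm(.read_matrix_dir(file.path(in_dir, "filtered")),
                         cfg)
    pt <- .read_pt(file.path(in_dir, "pseudotime.csv"))
    ref <- marker_set(utils::read.csv(file.path(in_dir,
                                                "reference_markers.csv"),
                                      stringsAsFactors = FALSE),
                      provenance = "reference")
    terminal <- mat$cell_meta$age == .terminal_age(mat$cell_meta, rc$extra)
    neurons <- cell_ids(mat)[as.numeric(pt)[
      match(cell_ids(mat), names(pt))] >= 0.5]
    pairs <- list(c("FO", "HO"), c("VB", "Po"), c("LG", "LP"))
    pairs <- Filter(function(p) all(p %in% unique(ref$category)), pairs)
    if (!length(pairs)) stop("reference table has no usable category pair")
    calls_all <- list(); onsets <- list(); derived_all <- list()
    for (p in pairs) {
      fit <- identity_bootstrap(mat, ref, terminal, cells = neurons,
                                pt = pt, cfg = cfg, categories = p)
      key <- paste(p, collapse = "_")
      df <- fit$calls$cells
      df$pair <- key
      if (!is.null(fit$ratio)) df$ratio <- as.numeric(fit$ratio)
      calls_all[[key]] <- df
      onsets[[key]] <- as.list(fit$onset)
      dm <- as.data.frame(fit$markers); dm$pair <- key
      derived_all[[key]] <- dm
    }
    ip <- file.path(out_dir, "identity_calls.csv")
    utils::write.csv(do.call(rbind, calls_all), ip, row.names = FALSE)
    mp <- file.path(out_dir, "derived_markers.csv")
    utils::write.csv(do.call(rbind, derived_all), mp, row.names = FALSE)
    op <- file.path(out_dir, "onsets.json")
    jsonlite::write_json(onsets, op, auto_unbox = TRUE, digits = NA)
    emit(ip, mp, op)
  } else if (stage_name == "deprivation-report") {
    need <- c(file.path(in_dir, "filtered", c("matrix.mtx", "genes.csv",
                                              "cells.csv")),
              file.path(in_dir, "pseudotime.csv"))
    .require_upstream(need, "deprivation-report")
    mat <- .with_lognorm(.read_matrix_dir(file.path(in_dir, "filtered")),
                         cfg)
    pt <- .read_pt(file.path(in_dir, "pseudotime.csv"))
    has_in <- "cell_type" %in% names(mat$cell_meta) &&
      any(mat$cell_meta$cell_type == "IN", na.rm = TRUE)
    rep <- deprivation_report(mat, pt, cfg = cfg, lag_seed = cfg$rng_seed,
                              interneurons = has_in)
    rp <- file.path(out_dir, "deprivation_report.json")
    jsonlite::write_json(lapply(unclass(rep), function(r) {
      o <- list(region = r$region,
                lag_delta = r$lag$delta, lag_p = r$lag$p)
      if (!is.null(r$de)) {
        o$n_up <- nrow(r$de$up); o$n_down <- nrow(r$de$down)
        o$n_dev <- r$overlap$n_dev
        o$n_overlap <- r$overlap$n_overlap
        o$percent_affected <- r$overlap$percent
      }
      o
    }), rp, auto_unbox = TRUE, digits = NA)
    emit(rp)
    for (rg in names(rep)) {
      if (is.null(rep[[rg]]$de)) next
      gp <- file.path(out_dir, sprintf("de_genes_%s.csv", rg))
      tag <- function(dir, df)
        cbind(direction = rep(dir, nrow(df)), df)
      utils::write.csv(rbind(tag("up", rep[[rg]]$de$up),
                             tag("down", rep[[rg]]$de$down)),
                       gp, row.names = FALSE)
      emit(gp)
    }
  }

  manifest <- list(stage = stage_name,
                   package_version = as.character(utils::packageVersion(
                     "thalamap")),
                   config_path = normalizePath(config_path),
                   config_snapshot = paste(readLines(config_path,
                                                     warn = FALSE),
                                           collapse = "\n"),
                   rng_seed = cfg$rng_seed,
                   generator_seed = if (is.null(gcfg)) NULL else gcfg$seed,
                   in_dir = in_dir, out_dir = out_dir,
                   outputs = as.character(outputs),
                   started = started,
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mf <- file.path(out_dir, sprintf("manifest_%s.json", stage_name))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, null = "null")
  tm_log(stage_name, "done: ", length(outputs), " output(s)")
  invisible(manifest)
}

.read_pt <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(stats::setNames(df$t, df$cell_id),
            root_cell = df$cell_id[which(df$root)[1]],
            method = "knn_geodesic", class = "PseudotimeField")
}

# Small datasets can have fewer genes/cells than the default n_hvg and
# pca_dims; clamp those to the data without touching the user's config.
pipeline_config_clamped <- function(cfg, mat) {
  cfg$n_hvg <- min(cfg$n_hvg, ncol(mat$counts))
  cfg$pca_dims <- min(cfg$pca_dims, nrow(mat$counts) - 1L,
                      ncol(mat$counts) - 1L, cfg$n_hvg)
  cfg
}
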