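# Rank-sum differential expression: the scalar two-sample primitive, a
# vectorised all-genes version backing the marker finders, and the
# MarkerSet container used to pass gene lists between stages.

#' Construct a MarkerSet
#'
#' A marker table: per category, an ordered gene list with effect sizes.
#' Within each category genes are unique and ordered by descending log2
#' fold-change; a `rank` column records that order.
#'
#' @param df data.frame with columns `category`, `gene_id`, `log2fc`,
#'   `padj` (NA allowed for reference tables).
#' @param provenance one of `"reference"`, `"derived_round2"`,
#'   `"cluster_markers"`.
#' @return data.frame of class `MarkerSet` with a `provenance` attribute.
#' @export
marker_set <- function(df, provenance = c("reference", "derived_round2",
                                          "cluster_markers")) {
  provenance <- match.arg(provenance)
  need <- c("category", "gene_id", "log2fc", "padj")
  if (!all(need %in% names(df)))
    stop("marker set needs columns: ", paste(need, collapse = ", "))
  df <- df[order(df$category, -df$log2fc), , drop = FALSE]
  if (any(tapply(df$gene_id, df$category, anyDuplicated) > 0))
    stop("duplicate genes within a category")
  pv <- df$padj[!is.na(df$padj)]
  if (length(pv) && (min(pv) < 0 || max(pv) > 1))
    stop("adjusted p-values outside [0,1]")
  df$rank <- as.integer(stats::ave(seq_len(nrow(df)), df$category,
                                   FUN = seq_along))
  rownames(df) <- NULL
  structure(df, class = c("MarkerSet", "data.frame"),
            provenance = provenance)
}

#' Genes of one marker category
#' @param ms MarkerSet.
#' @param category category name.
#' @param n optionally keep only the top `n` by fold-change.
#' @return character vector in rank order.
#' @export
marker_genes <- function(ms, category, n = Inf) {
  g <- ms$gene_id[ms$category == category]
  if (!length(g)) stop("unknown category: ", category)
  utils::head(g, n)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test. With 10 or fewer total observations and no
#' ties the p-value is exact (the full enumeration distribution); otherwise
#' a normal approximation with tie-corrected variance and no continuity
#' correction is used, so identical samples give p = 1.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with `U` (statistic for `x`), `p` (two-sided) and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n1 + n2 <= 10 && !ties) {
    # exact enumeration distribution of U
    p <- if (U > n1 * n2 / 2)
      2 * (1 - stats::pwilcox(U - 1, n1, n2)) else
      2 * stats::pwilcox(U, n1, n2)
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

# Vectorised tie-corrected rank-sum over the columns of a dense matrix.
# Returns U and the two-sided normal-approximation p per gene, matching
# wilcoxon_rank_sum()'s large-sample branch.
.rank_sum_cols <- function(X, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  stopifnot(n1 > 0, n2 > 0, n == nrow(X))
  U <- numeric(ncol(X)); sigma2 <- numeric(ncol(X))
  mu <- n1 * n2 / 2
  for (j in seq_len(ncol(X))) {
    r <- rank(X[, j])
    U[j] <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    rl <- rle(sort.int(X[, j], method = "radix"))$lengths
    tie_term <- sum(rl^3 - rl) / (n * (n - 1))
    sigma2[j] <- n1 * n2 / 12 * ((n + 1) - tie_term)
  }
  z <- ifelse(sigma2 > 0, (U - mu) / sqrt(sigma2), 0)
  p <- ifelse(sigma2 > 0, 2 * stats::pnorm(-abs(z)), 1)
  list(U = U, p = p)
}

# log2 fold-change on the natural scale with pseudocount 1, from lognorm.
.log2fc <- function(X, in_group) {
  a <- colMeans(expm1(X[in_group, , drop = FALSE]))
  b <- colMeans(expm1(X[!in_group, , drop = FALSE]))
  log2((a + 1) / (b + 1))
}

#' One-vs-rest cluster markers by Wilcoxon rank-sum
#'
#' For every label, tests each gene in the labelled cells against all other
#' cells on the log-normalized layer, BH-adjusts within the label, and
#' keeps genes with positive log2 fold-change (natural-scale means with
#' pseudocount 1), ordered by fold-change. Labels with fewer than 3 cells
#' are skipped with a warning.
#'
#' @param matrix ExpressionMatrix with a lognorm layer.
#' @param labels per-cell label vector (length = number of cells).
#' @param cfg [pipeline_config()].
#' @param significant.only if TRUE (default), keep only genes with
#'   BH-adjusted p below `cfg$de_alpha`; FALSE ranks purely by fold-change
#'   (used by the seed-cell marker derivation, where group sizes are tiny).
#' @param min_detect_frac minimum detection fraction in the in-group.
#' @return [marker_set()] with provenance `"cluster_markers"`.
#' @export
find_markers <- function(matrix, labels, cfg = pipeline_config(),
                         significant.only = TRUE, min_detect_frac = 0.1) {
  X <- .lognorm_dense(matrix)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(X))
  tab <- table(labels)
  usable <- names(tab)[tab >= 3]
  skipped <- setdiff(names(tab), usable)
  if (length(skipped))
    warning("labels skipped (fewer than 3 cells): ",
            paste(skipped, collapse = ", "))
  if (length(usable) < 2) stop("need at least 2 labels with >= 3 cells")
  res <- lapply(usable, function(lb) {
    ing <- labels == lb
    rs <- .rank_sum_cols(X, ing)
    fc <- .log2fc(X, ing)
    detect <- colMeans(X[ing, , drop = FALSE] > 0)
    padj <- stats::p.adjust(rs$p, method = "BH")
    keep <- fc > 0 & detect >= min_detect_frac
    if (significant.only) keep <- keep & padj < cfg$de_alpha
    data.frame(category = rep(lb, sum(keep)),
               gene_id = colnames(X)[keep],
               log2fc = fc[keep], padj = padj[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!nrow(out))
    out <- data.frame(category = character(0), gene_id = character(0),
                      log2fc = numeric(0), padj = numeric(0))
  marker_set(out, provenance = "cluster_markers")
}
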