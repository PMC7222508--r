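#' Presence filter on an expression matrix
#'
#' A feature is considered expressed when there is at least one
#' generation in which every replicate exceeds the threshold (strict
#' `>`); the conventional gene-level cut-off is FPKM > 5.  miRNA
#' matrices typically use a lower threshold.  The filter is idempotent.
#'
#' @param e An [expression_matrix()].
#' @param threshold Abundance threshold (default 5).
#' @return The filtered [expression_matrix()].
#' @export
presence_filter <- function(e, threshold = 5) {
  gens <- generations_of(e$sheet)
  keep <- rep(FALSE, nrow(e$values))
  for (g in gens) {
    cols <- e$sheet$sample_id[e$sheet$generation == g]
    keep <- keep | apply(e$values[, cols, drop = FALSE] > threshold, 1, all)
  }
  expression_matrix(e$values[keep, , drop = FALSE], e$sheet, e$kind)
}

#' One-way fixed-effects ANOVA across generations
#'
#' Classical F test of equal group means: F = (SSB/df_between) /
#' (SSW/df_within) with the p value from the upper tail of the F
#' distribution.  For the full 5 x 3 design df_between = 4 and
#' df_within = 10.  By default the test is run on log2(value + 1), which
#' stabilizes the variance of FPKM-like abundances; raw-scale mode is
#' available for sensitivity checks.
#'
#' Degenerate inputs: all values identical gives F undefined and p = 1
#' by convention; zero within-group variance with unequal means gives
#' F = Inf and p = 0, flagged `degenerate`.
#'
#' @param values Numeric vector of abundances (one per sample).
#' @param generations Integer vector of generation labels, same length.
#' @param transform `"log2"` (default, log2(x+1)) or `"raw"`.
#' @return A list with `f_stat`, `p_value`, `group_means` (on the
#'   analysis scale, named by generation), `df_between`, `df_within`,
#'   `degenerate`.
#' @export
one_way_anova <- function(values, generations,
                          transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  y <- if (transform == "log2") log2(values + 1) else values
  fg <- factor(generations)
  if (nlevels(fg) < 2L || any(table(fg) < 2L))
    stop("one_way_anova: need >= 2 groups with >= 2 observations each",
         call. = FALSE)
  gm <- tapply(y, fg, mean)
  dfb <- nlevels(fg) - 1L
  dfw <- length(y) - nlevels(fg)
  base <- list(group_means = gm, df_between = dfb, df_within = dfw)
  ssw <- sum((y - gm[as.integer(fg)])^2)
  if (ssw <= .Machine$double.eps * sum(y^2)) {
    if (max(gm) - min(gm) <= .Machine$double.eps * max(abs(y), 1))
      return(c(base, list(f_stat = NA_real_, p_value = 1,
                          degenerate = TRUE)))
    return(c(base, list(f_stat = Inf, p_value = 0, degenerate = TRUE)))
  }
  fit <- stats::oneway.test(y ~ fg, var.equal = TRUE)
  c(base, list(f_stat = unname(fit$statistic),
               p_value = unname(fit$p.value), degenerate = FALSE))
}

#' ANOVA table over all features of an expression matrix
#'
#' Runs [one_way_anova()] per feature and returns a tidy table.
#'
#' @param e An [expression_matrix()].
#' @param transform Passed to [one_way_anova()].
#' @return A `data.frame` with `feature_id`, `f_stat`, `p_value`,
#'   per-generation mean columns `mean_g<g>`, and `degenerate`.
#' @export
anova_table <- function(e, transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  gens <- e$sheet$generation
  res <- lapply(seq_len(nrow(e$values)), function(i)
    one_way_anova(e$values[i, ], gens, transform))
  means <- t(vapply(res, `[[`, numeric(length(unique(gens))),
                    "group_means"))
  colnames(means) <- paste0("mean_g", sort(unique(gens)))
  data.frame(feature_id = rownames(e$values),
             f_stat = vapply(res, `[[`, numeric(1), "f_stat"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             means,
             degenerate = vapply(res, `[[`, logical(1), "degenerate"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select differentially expressed features at a p-value threshold
#'
#' Features with unadjusted ANOVA p strictly below `alpha`, sorted by p
#' ascending with feature id as tie-break.  No multiple-testing
#' correction is applied (raw-threshold convention; see the vignette for
#' the caveat).
#'
#' @param results An [anova_table()] `data.frame`.
#' @param alpha Significance threshold (strict `<`).
#' @return Character vector of feature ids.
#' @export
select_degs <- function(results, alpha) {
  hit <- results[results$p_value < alpha, , drop = FALSE]
  hit$feature_id[order(hit$p_value, hit$feature_id)]
}

#' Hierarchically cluster samples on selected features
#'
#' Average-linkage hierarchical clustering of samples using Euclidean
#' distance on row-standardized log2(value + 1) (rows with zero variance
#' are left centred at zero), cut into `k` groups.  The partition is
#' invariant to feature and sample order.
#'
#' @param e An [expression_matrix()].
#' @param features Feature ids to cluster on (>= 2).
#' @param k Number of groups to cut the dendrogram into (default 2).
#' @return A list with `assignment` (named integer vector; labels follow
#'   sample-sheet order of first appearance), `hclust` (the tree) and
#'   `degenerate` (TRUE when all pairwise sample distances are zero, in
#'   which case the cut is arbitrary but deterministic).
#' @export
cluster_samples <- function(e, features, k = 2L) {
  if (length(features) < 2L)
    stop("cluster_samples: need >= 2 features", call. = FALSE)
  if (k > ncol(e$values))
    stop("cluster_samples: k exceeds the number of samples", call. = FALSE)
  missing_feat <- setdiff(features, rownames(e$values))
  if (length(missing_feat))
    stop("cluster_samples: unknown feature: ", missing_feat[1L],
         call. = FALSE)
  x <- log2(e$values[sort(features), , drop = FALSE] + 1)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  x <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  d <- stats::dist(t(x))
  hc <- stats::hclust(d, method = "average")
  assignment <- stats::cutree(hc, k = k)
  list(assignment = assignment, hclust = hc,
       degenerate = all(d == 0))
}

#' Temporal trend of a feature across generations
#'
#' Spearman rank correlation between per-sample abundance and the
#' generation index.  The trend is `"up"`/`"down"` by the sign of the
#' correlation when the correlation-test p value is below `alpha`,
#' otherwise `"none"`; constant features are `"none"`.
#'
#' @param values Numeric vector of abundances (one per sample).
#' @param generations Integer generation labels, same length.
#' @param alpha Trend-significance threshold (default 0.05).
#' @return A list with `trend`, `statistic` (Spearman rho) and
#'   `p_value`.
#' @export
trend_classify <- function(values, generations, alpha = 0.05) {
  if (stats::sd(values) == 0)
    return(list(trend = "none", statistic = NA_real_, p_value = 1))
  ct <- suppressWarnings(
    stats::cor.test(values, generations, method = "spearman",
                    exact = FALSE))
  rho <- unname(ct$estimate)
  p <- ct$p.value
  if (is.na(rho) || is.na(p) || p >= alpha)
    return(list(trend = "none", statistic = rho, p_value = p))
  list(trend = if (rho > 0) "up" else "down", statistic = rho,
       p_value = p)
}

#' Trend table over all features of an expression matrix
#'
#' @param e An [expression_matrix()].
#' @param alpha Passed to [trend_classify()].
#' @return A `data.frame` with `feature_id`, `trend`, `statistic`,
#'   `p_value`.
#' @export
trend_table <- function(e, alpha = 0.05) {
  gens <- e$sheet$generation
  res <- lapply(seq_len(nrow(e$values)), function(i)
    trend_classify(e$values[i, ], gens, alpha))
  data.frame(feature_id = rownames(e$values),
             trend = vapply(res, `[[`, character(1), "trend"),
             statistic = vapply(res, `[[`, numeric(1), "statistic"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             stringsAsFactors = FALSE, row.names = NULL)
}
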