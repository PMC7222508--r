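#' Per-generation alternate-allele frequencies
#'
#' For every locus and generation, the frequency is the sum of
#' alternate-allele dosages over non-missing samples divided by the
#' number of callable chromosomes (2 x non-missing diploid samples).
#' Missing genotypes are excluded from both numerator and denominator
#' rather than imputed.  Note that this is the tracked non-reference
#' allele frequency, which can exceed 0.5; it is not folded to the minor
#' allele.
#'
#' @param g A [genotype_matrix()] whose sample sheet covers the study
#'   generations.
#' @return A `data.frame` with one row per locus: `locus_id`,
#'   `freq_g<1..G>` (NA where a generation has no callable sample;
#'   such loci are flagged `defined = FALSE` and are excluded from
#'   trajectory filtering), and `callable_g<1..G>` chromosome counts.
#' @export
#' @examples
#' # Per-generation dosage sums 0,1,2,2,4 over 3 diploid mice give
#' # frequencies 0, 1/6, 1/3, 1/3, 2/3.
per_generation_maf <- function(g) {
  gens <- generations_of(g$sheet)
  dos <- g$dosages
  freq <- callable <- matrix(NA_real_, nrow(dos), length(gens))
  for (j in seq_along(gens)) {
    cols <- g$sheet$sample_id[g$sheet$generation == gens[j]]
    sub <- dos[, cols, drop = FALSE]
    num <- rowSums(sub, na.rm = TRUE)
    den <- 2 * rowSums(!is.na(sub))
    freq[, j] <- ifelse(den > 0, num / den, NA_real_)
    callable[, j] <- den
  }
  colnames(freq) <- paste0("freq_g", gens)
  colnames(callable) <- paste0("callable_g", gens)
  out <- data.frame(locus_id = g$loci$locus_id, freq, callable,
                    defined = rowSums(is.na(freq)) == 0L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Monotone allele-frequency trajectory filter
#'
#' Keeps loci whose allele frequency moves monotonically across the full
#' frequency range: increasing loci must be non-decreasing from first to
#' last generation with first-generation frequency <= `low` and
#' last-generation frequency >= `high`; decreasing loci satisfy the
#' mirrored rule.  Monotonicity is non-strict (internal ties allowed):
#' the canonical passing trajectory 0, 1/6, 1/3, 1/3, 2/3 contains a tie.
#' Boundary comparisons use `<=`/`>=` exactly; with up to three diploid
#' replicates all frequencies are exact multiples of small fractions and
#' the comparisons are free of floating-point artifacts.
#'
#' @param freqs Numeric vector of per-generation frequencies (ordered
#'   g1..gG, all defined).
#' @param low,high Boundary thresholds (defaults 1/3 and 2/3).
#' @return A list with `passes` (logical) and `direction`
#'   (`"increasing"`, `"decreasing"` or `"none"`).
#' @export
#' @examples
#' trajectory_filter(c(0, 1/6, 1/3, 1/3, 2/3))  # pass, increasing
trajectory_filter <- function(freqs, low = 1/3, high = 2/3) {
  if (any(is.na(freqs)))
    stop("trajectory_filter: undefined frequency in trajectory",
         call. = FALSE)
  n <- length(freqs)
  d <- diff(freqs)
  inc <- all(d >= 0) && freqs[1L] <= low && freqs[n] >= high
  dec <- all(d <= 0) && freqs[1L] >= high && freqs[n] <= low
  if (inc) list(passes = TRUE, direction = "increasing")
  else if (dec) list(passes = TRUE, direction = "decreasing")
  else list(passes = FALSE, direction = "none")
}

#' Apply the trajectory filter to a frequency table
#'
#' Vectorized form of [trajectory_filter()] over the output of
#' [per_generation_maf()].  Loci with an undefined frequency in any
#' generation fail with direction `"none"`.
#'
#' @param maf Output of [per_generation_maf()].
#' @param low,high Boundary thresholds (defaults 1/3 and 2/3).
#' @return `maf` with columns `passes` and `direction` appended.
#' @export
trajectory_verdicts <- function(maf, low = 1/3, high = 2/3) {
  fr <- as.matrix(maf[, grep("^freq_g", names(maf)), drop = FALSE])
  n <- ncol(fr)
  d <- fr[, -1L, drop = FALSE] - fr[, -n, drop = FALSE]
  inc <- rowSums(d < 0) == 0L & fr[, 1L] <= low & fr[, n] >= high
  dec <- rowSums(d > 0) == 0L & fr[, 1L] >= high & fr[, n] <= low
  inc[is.na(inc)] <- FALSE
  dec[is.na(dec)] <- FALSE
  undef <- !maf$defined
  inc[undef] <- dec[undef] <- FALSE
  maf$passes <- inc | dec
  maf$direction <- ifelse(inc, "increasing",
                          ifelse(dec, "decreasing", "none"))
  maf
}

#' Pairwise Hamming distances between samples
#'
#' For each sample pair, the proportion of loci at which both samples
#' are callable and the dosages differ, over the mutually callable loci
#' (missing-aware, PLINK-like).
#'
#' @param g A [genotype_matrix()].
#' @param loci Optional character vector of locus ids to restrict to
#'   (e.g. trajectory-filter survivors); default all loci.
#' @return A symmetric numeric matrix (samples x samples) with zero
#'   diagonal.
#' @export
hamming_distance <- function(g, loci = NULL) {
  dos <- g$dosages
  if (!is.null(loci)) {
    missing_loci <- setdiff(loci, rownames(dos))
    if (length(missing_loci))
      stop("hamming_distance: unknown locus id: ", missing_loci[1L],
           call. = FALSE)
    dos <- dos[loci, , drop = FALSE]
  }
  ns <- ncol(dos)
  if (ns < 2L) stop("hamming_distance: need >= 2 samples", call. = FALSE)
  d <- matrix(0, ns, ns, dimnames = list(colnames(dos), colnames(dos)))
  for (i in seq_len(ns - 1L)) {
    for (j in seq.int(i + 1L, ns)) {
      ok <- !is.na(dos[, i]) & !is.na(dos[, j])
      n_ok <- sum(ok)
      if (n_ok == 0L)
        stop(sprintf(
          "hamming_distance: no mutually callable loci for pair %s / %s",
          colnames(dos)[i], colnames(dos)[j]), call. = FALSE)
      d[i, j] <- d[j, i] <- sum(dos[ok, i] != dos[ok, j]) / n_ok
    }
  }
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes it, and
#' returns the top-`k` coordinates scaled by the square roots of the
#' (non-negative) eigenvalues, as `stats::cmdscale` computes them.  A
#' deterministic sign convention is applied: in every coordinate the
#' entry of largest magnitude is made positive.  Dimensions beyond the
#' rank of the configuration are zero-filled.
#'
#' @param d Symmetric distance matrix with sample names, or a `dist`.
#' @param k Number of coordinates (default 4; must be <= samples - 1).
#' @return A list of class `mds_embedding` with `coords` (samples x k),
#'   `eig` (all eigenvalues, for scree inspection) and `sample_ids`.
#' @export
classical_mds <- function(d, k = 4L) {
  d <- as.matrix(d)
  ns <- nrow(d)
  if (k > ns - 1L)
    stop("classical_mds: k must be <= samples - 1", call. = FALSE)
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {       # rank-deficient configuration
    pad <- matrix(0, ns, k - if (is.null(pts)) 0L else ncol(pts))
    pts <- cbind(pts, pad)
  }
  for (j in seq_len(k)) {
    m <- which.max(abs(pts[, j]))
    if (length(m) && pts[m, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("C", seq_len(k))
  structure(list(coords = pts, eig = fit$eig, sample_ids = rownames(d)),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("mds_embedding: %d samples x %d coordinates\n",
              nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

#' Silhouette-style separation of a generation split in MDS space
#'
#' Mean silhouette width of the two-group split (declared generations vs
#' the rest) computed on the first two MDS coordinates.  Used to ask
#' whether, e.g., generation-5 samples separate from earlier passages.
#'
#' @param emb An [classical_mds()] embedding.
#' @param sheet The cohort [sample_sheet()].
#' @param group_generations Generations forming one side of the split.
#' @return Mean silhouette width in \[-1, 1\]; 0 when all coordinates
#'   coincide.
#' @export
separation_score <- function(emb, sheet, group_generations) {
  idx <- match(emb$sample_ids, sheet$sample_id)
  if (any(is.na(idx)))
    stop("separation_score: embedding samples not in sample sheet",
         call. = FALSE)
  grp <- sheet$generation[idx] %in% group_generations
  if (!any(grp) || all(grp))
    stop("separation_score: split must have two non-empty sides",
         call. = FALSE)
  if (sum(grp) == 1L || sum(!grp) == 1L)
    warning("separation_score: singleton group in split", call. = FALSE)
  xy <- emb$coords[, seq_len(min(2L, ncol(emb$coords))), drop = FALSE]
  dd <- stats::dist(xy)
  if (all(dd == 0)) return(0)
  sil <- cluster::silhouette(as.integer(grp) + 1L, dd)
  mean(sil[, "sil_width"])
}
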