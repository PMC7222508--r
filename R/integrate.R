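#' Map loci to the genes containing them
#'
#' A locus maps to every gene whose interval contains its position
#' (positional containment; strand ignored), so a locus inside two
#' overlapping genes yields two pairs.  Overlap is computed with
#' `GenomicRanges`.  Loci falling in no gene are dropped; their count is
#' recorded in the `n_unmapped` attribute.
#'
#' @param loci Locus `data.frame` with columns `locus_id`, `chrom`,
#'   `pos` (1-based, as in VCF).
#' @param annotation Gene annotation from [read_gene_annotation()]
#'   (1-based closed intervals).
#' @return A `data.frame` of pairs (`locus_id`, `gene_id`) with
#'   attribute `n_unmapped`.
#' @export
map_loci_to_genes <- function(loci, annotation) {
  if (any(annotation$start > annotation$end))
    stop("map_loci_to_genes: invalid annotation interval", call. = FALSE)
  locus_gr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$pos, loci$pos))
  gene_gr <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(annotation$start, annotation$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(locus_gr, gene_gr, ignore.strand = TRUE))
  pairs <- data.frame(
    locus_id = loci$locus_id[S4Vectors::queryHits(hits)],
    gene_id = annotation$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$locus_id, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "n_unmapped") <-
    length(unique(setdiff(loci$locus_id, pairs$locus_id)))
  pairs
}

#' Genotype-expression association for one locus/gene pair
#'
#' Simple linear regression of log2(expression + 1) (or raw expression)
#' on the additive alternate-allele dosage across all samples with a
#' non-missing genotype; significance by the regression F test.
#'
#' @param dosages Integer vector in \{0,1,2,NA\}, one per sample.
#' @param expression Non-negative numeric vector, same length.
#' @param transform `"log2"` (default) or `"raw"`.
#' @return A list with `slope` (analysis-scale units per alt allele),
#'   `f_stat`, `p_value`, `n_used` and `degenerate` (TRUE for an exact
#'   fit, where p underflows to 0), or `NULL` with a `skip_reason`
#'   attribute when fewer than 3 samples are callable or the dosage is
#'   monomorphic.
#' @export
genotype_expression_association <- function(dosages, expression,
                                            transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  ok <- !is.na(dosages)
  d <- dosages[ok]
  y <- if (transform == "log2") log2(expression[ok] + 1) else expression[ok]
  skip <- function(reason)
    structure(list(), skip_reason = reason, class = "association_skip")
  if (length(d) < 3L) return(skip("fewer than 3 callable samples"))
  if (length(unique(d)) < 2L) return(skip("monomorphic dosage"))
  fit <- stats::lm(y ~ d)
  # summary.lm warns on zero-residual fits; degeneracy is detected and
  # flagged explicitly below
  sm <- suppressWarnings(summary(fit))
  fs <- sm$fstatistic
  if (is.null(fs)) return(skip("zero response variance"))
  p <- suppressWarnings(
    stats::pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]],
              lower.tail = FALSE))
  degenerate <- is.na(p) ||
    sm$sigma^2 < .Machine$double.eps * stats::var(y)
  if (degenerate) p <- 0
  list(slope = unname(stats::coef(fit)["d"]),
       f_stat = unname(fs[["value"]]), p_value = unname(p),
       n_used = length(d), degenerate = degenerate)
}

#' Association table over locus/gene pairs
#'
#' Runs [genotype_expression_association()] for every pair, typically
#' the trajectory-filter survivors mapped to their containing genes.
#' Pairs whose gene is absent from the expression matrix, or whose
#' genotype is monomorphic, are skipped; skip counts per reason are
#' attached as the `skipped` attribute.
#'
#' @param g A [genotype_matrix()].
#' @param e A gene [expression_matrix()].
#' @param pairs `data.frame` with columns `locus_id`, `gene_id` (see
#'   [map_loci_to_genes()]).
#' @param transform Passed to [genotype_expression_association()].
#' @return A `data.frame` with `locus_id`, `gene_id`, `slope`, `f_stat`,
#'   `p_value`, `n_used`, `degenerate`.
#' @export
association_table <- function(g, e, pairs, transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(pairs))) {
    lid <- pairs$locus_id[i]; gid <- pairs$gene_id[i]
    if (!lid %in% rownames(g$dosages)) {
      skipped[lid] <- "locus not in genotype matrix"; next
    }
    if (!gid %in% rownames(e$values)) {
      skipped[paste(lid, gid)] <- "gene not in expression matrix"; next
    }
    res <- genotype_expression_association(
      g$dosages[lid, e$sheet$sample_id],
      e$values[gid, e$sheet$sample_id], transform)
    if (inherits(res, "association_skip")) {
      skipped[paste(lid, gid)] <- attr(res, "skip_reason"); next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(locus_id = lid, gene_id = gid, slope = res$slope,
                 f_stat = res$f_stat, p_value = res$p_value,
                 n_used = res$n_used, degenerate = res$degenerate,
                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(), gene_id = character(),
               slope = numeric(), f_stat = numeric(), p_value = numeric(),
               n_used = integer(), degenerate = logical())
  attr(out, "skipped") <- skipped
  out
}

#' Select candidate loci and genes from association results
#'
#' Keeps associations with unadjusted p strictly below `alpha`; the gene
#' list is de-duplicated, which is why the locus count can exceed the
#' gene count.
#'
#' @param records An [association_table()] `data.frame`.
#' @param alpha Significance threshold (default 0.01, strict `<`).
#' @return A list with `loci` (locus ids, p-ascending) and `genes`
#'   (unique gene ids, sorted).
#' @export
select_candidates <- function(records, alpha = 0.01) {
  hit <- records[records$p_value < alpha, , drop = FALSE]
  hit <- hit[order(hit$p_value, hit$locus_id), , drop = FALSE]
  list(loci = hit$locus_id, genes = sort(unique(hit$gene_id)))
}

#' Intersect candidate genes with an immune gene set
#'
#' @param candidate_genes,immune_genes Character vectors of gene ids.
#' @return Sorted character vector of the intersection.
#' @export
immune_intersection <- function(candidate_genes, immune_genes) {
  sort(intersect(unique(candidate_genes), unique(immune_genes)))
}

#' miRNA-target expression trend concordance
#'
#' Classifies the temporal trend ([trend_classify()]) of each miRNA and
#' of its target gene and scores each pair.  In `mode = "same"` a pair
#' is concordant when both trends are non-none and equal — the pattern
#' reported for serially passaged cohorts even though canonical miRNA
#' repression predicts the opposite; `mode = "inverse"` requires
#' opposite trends.  Pairs with either member absent from its matrix are
#' skipped (reason recorded in the `skipped` attribute).
#'
#' @param mirna_e miRNA [expression_matrix()].
#' @param gene_e Gene [expression_matrix()].
#' @param pairs `data.frame` with columns `mirna_id`, `gene_id`.
#' @param mode `"same"` (default) or `"inverse"`.
#' @param alpha Trend-significance threshold (default 0.05).
#' @return A `data.frame` with `mirna_id`, `gene_id`, `mirna_trend`,
#'   `gene_trend`, `concordant`.
#' @export
mirna_target_concordance <- function(mirna_e, gene_e, pairs,
                                     mode = c("same", "inverse"),
                                     alpha = 0.05) {
  mode <- match.arg(mode)
  rows <- list()
  skipped <- character()
  gens_m <- mirna_e$sheet$generation
  gens_g <- gene_e$sheet$generation
  for (i in seq_len(nrow(pairs))) {
    mid <- pairs$mirna_id[i]; gid <- pairs$gene_id[i]
    if (!mid %in% rownames(mirna_e$values)) {
      skipped[mid] <- "miRNA not in matrix"; next
    }
    if (!gid %in% rownames(gene_e$values)) {
      skipped[gid] <- "gene not in matrix"; next
    }
    tm <- trend_classify(mirna_e$values[mid, ], gens_m, alpha)$trend
    tg <- trend_classify(gene_e$values[gid, ], gens_g, alpha)$trend
    conc <- tm != "none" && tg != "none" &&
      if (mode == "same") tm == tg else tm != tg
    rows[[length(rows) + 1L]] <-
      data.frame(mirna_id = mid, gene_id = gid, mirna_trend = tm,
                 gene_trend = tg, concordant = conc,
                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), gene_id = character(),
               mirna_trend = character(), gene_trend = character(),
               concordant = logical())
  attr(out, "skipped") <- skipped
  out
}

#' Read a miRNA-target pair list from a 2-column TSV
#'
#' @param path Path to a tab-separated file with columns `mirna_id`,
#'   `gene_id` (header required).
#' @return A `data.frame` with those two columns.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% names(df)))
    stop("pair list must have columns mirna_id, gene_id", call. = FALSE)
  df[, c("mirna_id", "gene_id")]
}
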