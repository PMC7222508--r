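#' Build a pipeline run configuration
#'
#' Collects the input file paths and analysis thresholds for a full
#' run.  Thresholds default to the package's standard analysis settings:
#' gene presence FPKM > 5 (miRNA > 1), DEG selection at unadjusted
#' ANOVA p < 0.05 and < 0.001, genotype-expression association at
#' p < 0.01, trajectory-filter boundaries 1/3 and 2/3, trend
#' significance 0.05, and a responsive/resistant TGI cut-off of 30%.
#'
#' @param vcf,sample_sheet,gene_expression,mirna_expression,annotation,pairs,immune,growth
#'   Input file paths (see the `formats` readers).  `mirna_expression`,
#'   `pairs`, `immune` and `growth` may be `NULL` to skip those stages.
#' @param out_dir Output directory for stage TSVs and the report.
#' @param presence_threshold,mirna_presence_threshold Presence-filter
#'   cut-offs.
#' @param deg_alpha,deg_alpha_strict DEG thresholds.
#' @param association_alpha Association candidate threshold.
#' @param maf_low,maf_high Trajectory-filter boundaries.
#' @param trend_alpha Trend-significance threshold.
#' @param concordance_mode `"same"` or `"inverse"`.
#' @param tgi_threshold Responsive/resistant TGI cut-off (percent).
#' @param mds_k MDS dimensions.
#' @param seed Integer recorded in the report (the analysis itself is
#'   deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf, sample_sheet, gene_expression,
                       mirna_expression = NULL, annotation = NULL,
                       pairs = NULL, immune = NULL, growth = NULL,
                       out_dir = tempfile("clonaltraj_run_"),
                       presence_threshold = 5,
                       mirna_presence_threshold = 1,
                       deg_alpha = 0.05, deg_alpha_strict = 0.001,
                       association_alpha = 0.01,
                       maf_low = 1/3, maf_high = 2/3,
                       trend_alpha = 0.05,
                       concordance_mode = c("same", "inverse"),
                       tgi_threshold = 30, mds_k = 4L, seed = 1L) {
  cfg <- as.list(environment())
  cfg$concordance_mode <- match.arg(concordance_mode)
  stopifnot(cfg$deg_alpha > 0, cfg$deg_alpha <= 1,
            cfg$association_alpha > 0, cfg$association_alpha <= 1,
            cfg$maf_low >= 0, cfg$maf_high <= 1,
            cfg$maf_low < cfg$maf_high)
  for (f in c("vcf", "sample_sheet", "gene_expression")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("run_config: required input missing: ", f, call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  path_keys <- c("vcf", "sample_sheet", "gene_expression",
                 "mirna_expression", "annotation", "pairs", "immune",
                 "growth", "out_dir")
  for (k in intersect(path_keys, names(y))) {
    if (!is.null(y[[k]]) && !grepl("^/", y[[k]]))
      y[[k]] <- file.path(base, y[[k]])
  }
  do.call(run_config, y)
}

# Small stable polynomial checksum of the configuration, for the report.
# Paths enter by basename so equivalent runs in different directories
# hash identically.
config_hash <- function(cfg) {
  path_keys <- c("vcf", "sample_sheet", "gene_expression",
                 "mirna_expression", "annotation", "pairs", "immune",
                 "growth", "out_dir")
  cfg <- cfg[order(names(cfg))]
  for (k in intersect(path_keys, names(cfg)))
    if (!is.null(cfg[[k]])) cfg[[k]] <- basename(cfg[[k]])
  s <- utf8ToInt(paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 15), collapse = ","), character(1)),
    collapse = ";"))
  h <- 5381
  for (b in s) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — growth efficacy, allele-frequency
#' trajectories and MDS, expression filtering / ANOVA / clustering /
#' trends, then genotype-expression integration (locus-to-gene mapping,
#' association, immune intersection, miRNA-target concordance) — writing
#' each stage's table to `out_dir` and returning a machine-readable
#' report with the counts at every stage.  Stages whose inputs were not
#' configured are skipped.  Any stage failure aborts with the stage
#' name; tables already written are preserved.
#'
#' @param cfg A [run_config()].
#' @return A list of class `run_report`: `counts`, `efficacy`,
#'   `candidates`, `immune_overlap`, `concordant_pairs`, `thresholds`,
#'   `config_hash`, `seed`, `package_version`, `outputs` (paths).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(cfg$out_dir, f)
  wr <- function(df, f) {
    utils::write.table(df, outp(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outp(f)
  }
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  outputs <- list()
  counts <- list()

  sheet <- stage("inputs", read_sample_sheet(cfg$sample_sheet))

  eff <- NULL
  if (!is.null(cfg$growth)) {
    eff <- stage("growth", {
      rec <- read_growth_csv(cfg$growth)
      passage_efficacy(rec, threshold_percent = cfg$tgi_threshold)
    })
    outputs$efficacy <- wr(eff, "efficacy.tsv")
  }

  vt <- stage("vartraj", {
    g <- read_vcf(cfg$vcf, sheet)
    maf <- trajectory_verdicts(per_generation_maf(g),
                               low = cfg$maf_low, high = cfg$maf_high)
    passing <- maf$locus_id[maf$passes]
    mds_all <- classical_mds(hamming_distance(g), k = cfg$mds_k)
    mds_filt <- if (length(passing) >= 1L)
      classical_mds(hamming_distance(g, passing), k = cfg$mds_k) else NULL
    list(g = g, maf = maf, passing = passing,
         mds_all = mds_all, mds_filt = mds_filt)
  })
  outputs$trajectories <- wr(vt$maf, "trajectories.tsv")
  outputs$mds_all <- wr(data.frame(sample_id = vt$mds_all$sample_ids,
                                   vt$mds_all$coords), "mds_all.tsv")
  if (!is.null(vt$mds_filt))
    outputs$mds_filtered <- wr(
      data.frame(sample_id = vt$mds_filt$sample_ids, vt$mds_filt$coords),
      "mds_filtered.tsv")
  counts$variants_in <- nrow(vt$g$dosages)
  counts$trajectories_passing <- length(vt$passing)
  counts$passing_increasing <- sum(vt$maf$direction == "increasing")
  counts$passing_decreasing <- sum(vt$maf$direction == "decreasing")

  ex <- stage("exprdyn", {
    e <- read_expression_tsv(cfg$gene_expression, sheet, "gene")
    kept <- presence_filter(e, cfg$presence_threshold)
    av <- anova_table(kept)
    degs <- select_degs(av, cfg$deg_alpha)
    degs_strict <- select_degs(av, cfg$deg_alpha_strict)
    clust <- if (length(degs_strict) >= 2L)
      cluster_samples(kept, degs_strict) else NULL
    trends <- trend_table(kept, cfg$trend_alpha)
    list(e = e, kept = kept, anova = av, degs = degs,
         degs_strict = degs_strict, clust = clust, trends = trends)
  })
  outputs$anova <- wr(ex$anova, "anova.tsv")
  outputs$degs <- wr(data.frame(feature_id = ex$degs), "degs.tsv")
  outputs$degs_strict <- wr(data.frame(feature_id = ex$degs_strict),
                            "degs_strict.tsv")
  outputs$trends <- wr(ex$trends, "trends.tsv")
  if (!is.null(ex$clust))
    outputs$clusters <- wr(
      data.frame(sample_id = names(ex$clust$assignment),
                 cluster = unname(ex$clust$assignment)), "clusters.tsv")
  counts$genes_in <- n_features(ex$e)
  counts$genes_kept <- n_features(ex$kept)
  counts$degs <- length(ex$degs)
  counts$degs_strict <- length(ex$degs_strict)

  assoc <- cand <- NULL
  immune_hits <- character()
  if (!is.null(cfg$annotation)) {
    int <- stage("integrate", {
      ann <- read_gene_annotation(cfg$annotation)
      loci <- vt$g$loci[vt$g$loci$locus_id %in% vt$passing, , drop = FALSE]
      pairs_lg <- map_loci_to_genes(loci, ann)
      assoc <- association_table(vt$g, ex$kept, pairs_lg)
      cand <- select_candidates(assoc, cfg$association_alpha)
      list(pairs_lg = pairs_lg, assoc = assoc, cand = cand)
    })
    assoc <- int$assoc; cand <- int$cand
    outputs$association <- wr(assoc, "association.tsv")
    outputs$candidate_loci <- wr(data.frame(locus_id = cand$loci),
                                 "candidate_loci.tsv")
    outputs$candidate_genes <- wr(data.frame(gene_id = cand$genes),
                                  "candidate_genes.tsv")
    counts$loci_mapped <- length(unique(int$pairs_lg$locus_id))
    counts$loci_unmapped <- attr(int$pairs_lg, "n_unmapped")
    counts$associations_tested <- nrow(assoc)
    counts$candidate_loci <- length(cand$loci)
    counts$candidate_genes <- length(cand$genes)
    if (!is.null(cfg$immune)) {
      immune_hits <- stage("immune", {
        immune_intersection(cand$genes, read_gene_set(cfg$immune))
      })
      outputs$immune_overlap <- wr(data.frame(gene_id = immune_hits),
                                   "immune_overlap.tsv")
      counts$immune_overlap <- length(immune_hits)
    }
  }

  conc <- NULL
  if (!is.null(cfg$mirna_expression) && !is.null(cfg$pairs)) {
    conc <- stage("concordance", {
      mir <- read_expression_tsv(cfg$mirna_expression, sheet, "mirna")
      mir_kept <- presence_filter(mir, cfg$mirna_presence_threshold)
      mirna_target_concordance(mir_kept, ex$kept, read_pairs_tsv(cfg$pairs),
                               mode = cfg$concordance_mode,
                               alpha = cfg$trend_alpha)
    })
    outputs$concordance <- wr(conc, "concordance.tsv")
    counts$pairs_scored <- nrow(conc)
    counts$concordant_pairs <- sum(conc$concordant)
  }

  report <- structure(list(
    counts = counts,
    efficacy = eff,
    candidates = cand,
    immune_overlap = immune_hits,
    concordant_pairs = if (is.null(conc)) NULL else
      conc[conc$concordant, c("mirna_id", "gene_id")],
    thresholds = cfg[c("presence_threshold", "mirna_presence_threshold",
                       "deg_alpha", "deg_alpha_strict", "association_alpha",
                       "maf_low", "maf_high", "trend_alpha",
                       "tgi_threshold", "mds_k", "concordance_mode")],
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("clonaltraj")),
    outputs = outputs), class = "run_report")
  jsonlite::write_json(report[setdiff(names(report), "outputs")],
                       outp("report.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  report$outputs$report <- outp("report.json")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("clonaltraj run report\n")
  for (n in names(x$counts))
    cat(sprintf("  %-24s %s\n", n, x$counts[[n]]))
  if (!is.null(x$efficacy)) {
    cat("  per-passage efficacy:\n")
    print(x$efficacy[, c("passage", "tgi_percent", "call")], row.names = FALSE)
  }
  invisible(x)
}
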