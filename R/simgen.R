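#' Configuration for the synthetic-cohort generator
#'
#' Defines a serially passaged PDX study: `n_generations` passages with
#' `n_replicates` mice each (default 5 x 3 = 15 samples), exome-scale
#' loci with a planted fraction under directional selection, a gene
#' expression layer with planted differentially expressed genes (DEGs)
#' and genotype-linked (eQTL-style) genes, a miRNA layer with a planted
#' number of trend-concordant miRNA/target pairs, an immune gene list
#' overlapping the planted eQTL genes, and per-passage tumor growth
#' curves whose expected tumor growth inhibition (TGI) follows a
#' responsive-to-resistant profile.
#'
#' All randomness flows from `seed`; the same configuration always
#' produces bit-identical cohorts.  Setting `noise_sd = 0` switches
#' genotypes to exact deterministic frequency paths and expression to
#' noise-free values, so every planted signal is recoverable with
#' recall and precision 1.
#'
#' @param seed Integer seed (mandatory; no implicit entropy).
#' @param n_generations,n_replicates Study design (defaults 5 and 3).
#' @param n_loci Total variant loci (default 2000).
#' @param frac_selected_up,frac_selected_down Fractions of loci on a
#'   rising / falling allele-frequency path (defaults 0.01 each).
#' @param selected_path Latent rising frequency path, one value per
#'   generation; the default is the canonical observed trajectory
#'   0, 1/6, 1/3, 1/3, 2/3.  Falling loci use its mirror (1 - path).
#' @param n_genes Genes in the expression layer (default 500).
#' @param n_planted_degs Planted DEGs with a monotone generation trend
#'   (default 25, alternating up/down).
#' @param deg_effect_sd_units Per-generation-step mean shift of planted
#'   DEGs, in units of the replicate noise SD (default 3).
#' @param n_eqtl_links Selected loci wired to gene expression
#'   (default 15; must not exceed the planted selected-up loci).
#' @param n_eqtl_genes Genes receiving those links (default 12; fewer
#'   genes than links, so some genes carry two loci, mirroring a locus
#'   count above the gene count).
#' @param eqtl_slope log2-expression change per alternate allele
#'   (default 2).
#' @param n_mirnas miRNAs (default 50).
#' @param n_target_pairs miRNA-target pairs (default 50).
#' @param n_concordant_pairs Pairs planted with matching miRNA and
#'   target trends (default 16).
#' @param n_immune_planted Planted eQTL genes carrying an immune label
#'   (default 10).
#' @param n_immune_extra Immune ids outside the expression layer,
#'   padding the list (default 40).
#' @param noise_sd Replicate noise SD on the log2 expression scale
#'   (default 0.25); 0 selects the exact, noise-free regime.
#' @param baseline_range Tumor baseline volume range in mm^3
#'   (default c(100, 300), the randomization window).
#' @param response_tgi_percent Expected endpoint TGI per treated
#'   passage, defaults c(44.62, 43.93, -44.04, 7.42) for passages 2-5
#'   (responsive, responsive, resistant, resistant).
#' @param growth_days Measurement days (default days 0-21, twice
#'   weekly).
#' @param vehicle_growth_rate Exponential growth rate per day of
#'   vehicle tumors (default log(6)/21: a six-fold volume increase over
#'   three weeks).
#' @param growth_noise_sd Lognormal sdlog of measurement noise on
#'   volumes (default 0.2); 0 for exact curves.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_generations = 5L, n_replicates = 3L,
                       n_loci = 2000L,
                       frac_selected_up = 0.01, frac_selected_down = 0.01,
                       selected_path = c(0, 1, 2, 2, 4) / 6,
                       n_genes = 500L, n_planted_degs = 25L,
                       deg_effect_sd_units = 3,
                       n_eqtl_links = 15L, n_eqtl_genes = 12L,
                       eqtl_slope = 2,
                       n_mirnas = 50L, n_target_pairs = 50L,
                       n_concordant_pairs = 16L,
                       n_immune_planted = 10L, n_immune_extra = 40L,
                       noise_sd = 0.25,
                       baseline_range = c(100, 300),
                       response_tgi_percent = c(44.62, 43.93, -44.04, 7.42),
                       growth_days = c(0L, 4L, 7L, 11L, 14L, 18L, 21L),
                       vehicle_growth_rate = log(6) / 21,
                       growth_noise_sd = 0.2) {
  if (missing(seed) || !is.finite(seed))
    stop("sim_config: an integer seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (cfg$frac_selected_up < 0 || cfg$frac_selected_up > 1 ||
      cfg$frac_selected_down < 0 || cfg$frac_selected_down > 1 ||
      cfg$frac_selected_up + cfg$frac_selected_down > 1)
    stop("sim_config: selected fractions must lie in [0,1] and sum <= 1",
         call. = FALSE)
  if (length(cfg$selected_path) != cfg$n_generations ||
      any(cfg$selected_path < 0 | cfg$selected_path > 1))
    stop("sim_config: selected_path must give one frequency in [0,1] ",
         "per generation", call. = FALSE)
  n_up <- round(cfg$frac_selected_up * cfg$n_loci)
  if (cfg$n_eqtl_links > n_up)
    stop("sim_config: n_eqtl_links exceeds the planted selected-up loci",
         call. = FALSE)
  if (cfg$n_eqtl_genes > cfg$n_eqtl_links)
    stop("sim_config: n_eqtl_genes exceeds n_eqtl_links", call. = FALSE)
  if (cfg$n_immune_planted > cfg$n_eqtl_genes)
    stop("sim_config: n_immune_planted exceeds n_eqtl_genes", call. = FALSE)
  if (cfg$n_concordant_pairs > cfg$n_target_pairs)
    stop("sim_config: n_concordant_pairs exceeds n_target_pairs",
         call. = FALSE)
  if (cfg$n_concordant_pairs > cfg$n_planted_degs)
    stop("sim_config: n_concordant_pairs exceeds n_planted_degs ",
         "(concordant targets are planted DEGs)", call. = FALSE)
  n_null <- cfg$n_genes - cfg$n_eqtl_genes - cfg$n_planted_degs
  if (n_null < cfg$n_target_pairs - cfg$n_concordant_pairs)
    stop("sim_config: not enough null genes for discordant pairs",
         call. = FALSE)
  if (any(cfg$n_loci < 1, cfg$n_genes < 1, cfg$noise_sd < 0,
          cfg$growth_noise_sd < 0))
    stop("sim_config: counts must be positive and noise SDs >= 0",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Reference SD for planted effect sizes: the replicate noise SD, with a
# fixed floor so the noise-free regime still plants non-zero effects.
effect_ref_sd <- function(cfg) max(cfg$noise_sd, 0.25)

# Gene ids and their planted roles under a config.
sim_gene_roles <- function(cfg) {
  ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  eqtl <- ids[seq_len(cfg$n_eqtl_genes)]
  deg <- ids[cfg$n_eqtl_genes + seq_len(cfg$n_planted_degs)]
  null <- setdiff(ids, c(eqtl, deg))
  list(ids = ids, eqtl = eqtl, deg = deg, null = null,
       deg_direction = stats::setNames(
         rep_len(c(1, -1), cfg$n_planted_degs), deg))
}

# Distribute an allele count over diploid replicates, greedily: the
# first mice take two copies, then one, then none.  Deterministic.
split_count <- function(count, n_replicates) {
  count <- as.integer(round(count))
  out <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    take <- min(2L, count)
    out[r] <- take
    count <- count - take
  }
  out
}

#' Simulate cohort genotypes with planted selection
#'
#' Neutral loci keep a constant latent allele frequency drawn uniformly
#' from (0.05, 0.95); selected loci follow the configured latent path
#' (rising, or its mirror for falling loci).  With `noise_sd > 0` each
#' mouse's dosage is drawn binomial(2, p) around the latent frequency;
#' with `noise_sd = 0` per-generation allele counts equal the latent
#' path exactly (so observed frequencies reproduce the path).  The first
#' `n_eqtl_links` selected-up loci are placed inside gene bodies on
#' chr1; all other loci are intergenic on chr2.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (`data.frame`: `locus_id`, `class`, `is_eqtl`, `gene_id`).
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed + 1L)
  sheet <- default_sample_sheet(cfg$n_generations, cfg$n_replicates)
  n_up <- round(cfg$frac_selected_up * cfg$n_loci)
  n_dn <- round(cfg$frac_selected_down * cfg$n_loci)
  classes <- c(rep("selected_up", n_up), rep("selected_down", n_dn),
               rep("neutral", cfg$n_loci - n_up - n_dn))
  roles <- sim_gene_roles(cfg)
  gene_for_link <- rep(seq_len(cfg$n_eqtl_genes),
                       length.out = cfg$n_eqtl_links)
  ann <- simulated_gene_annotation(cfg)

  chrom <- rep("chr2", cfg$n_loci)
  pos <- 1000L * seq_len(cfg$n_loci)
  is_eqtl <- rep(FALSE, cfg$n_loci)
  gene_id <- rep(NA_character_, cfg$n_loci)
  if (cfg$n_eqtl_links > 0) {
    idx <- seq_len(cfg$n_eqtl_links)   # within the selected-up block
    chrom[idx] <- "chr1"
    gstart <- ann$start[match(roles$ids[gene_for_link], ann$gene_id)]
    # unique in-gene offsets for loci sharing a gene
    off <- stats::ave(idx, gene_for_link, FUN = seq_along)
    pos[idx] <- gstart + 500L + 10L * off
    is_eqtl[idx] <- TRUE
    gene_id[idx] <- roles$ids[gene_for_link]
  }

  path_up <- cfg$selected_path
  latent <- matrix(NA_real_, cfg$n_loci, cfg$n_generations)
  if (n_up > 0)
    latent[classes == "selected_up", ] <-
      matrix(path_up, n_up, cfg$n_generations, byrow = TRUE)
  if (n_dn > 0)
    latent[classes == "selected_down", ] <-
      matrix(1 - path_up, n_dn, cfg$n_generations, byrow = TRUE)
  p0 <- stats::runif(sum(classes == "neutral"), 0.05, 0.95)
  latent[classes == "neutral", ] <-
    matrix(rep(p0, cfg$n_generations), ncol = cfg$n_generations)

  nr <- cfg$n_replicates
  dos <- matrix(NA_integer_, cfg$n_loci, nrow(sheet))
  for (g in seq_len(cfg$n_generations)) {
    cols <- which(sheet$generation == g)
    if (cfg$noise_sd == 0) {
      counts <- round(latent[, g] * 2 * nr)
      dos[, cols] <- t(vapply(counts, split_count, integer(nr), nr))
    } else {
      dos[, cols] <- matrix(
        stats::rbinom(cfg$n_loci * nr, 2L, rep(latent[, g], nr)),
        cfg$n_loci, nr)
    }
  }
  colnames(dos) <- sheet$sample_id
  ref_alt <- cbind(rep("A", cfg$n_loci), rep("G", cfg$n_loci))
  loci <- data.frame(
    locus_id = sprintf("%s:%d_%s/%s", chrom, pos, ref_alt[, 1], ref_alt[, 2]),
    chrom = chrom, pos = pos, ref = ref_alt[, 1], alt = ref_alt[, 2],
    stringsAsFactors = FALSE)
  truth <- data.frame(locus_id = loci$locus_id, class = classes,
                      is_eqtl = is_eqtl, gene_id = gene_id,
                      stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dos, loci, sheet), truth = truth)
}

#' Gene annotation for a simulated cohort
#'
#' Lays genes head to tail on chr1: gene j occupies the 1-based closed
#' interval [(j-1) * 10000 + 1, (j-1) * 10000 + 2000].
#'
#' @param cfg A [sim_config()].
#' @return Annotation `data.frame` as from [read_gene_annotation()].
#' @export
simulated_gene_annotation <- function(cfg) {
  j <- seq_len(cfg$n_genes)
  data.frame(gene_id = sprintf("gene%04d", j), chrom = "chr1",
             start = (j - 1L) * 10000L + 1L,
             end = (j - 1L) * 10000L + 2000L,
             strand = rep(c("+", "-"), length.out = cfg$n_genes),
             stringsAsFactors = FALSE)
}

#' Simulate gene expression with planted DEGs and eQTL links
#'
#' Baseline FPKM is log-normal.  Planted DEGs receive a linear
#' generation trend on the log2 scale of `deg_effect_sd_units` noise SDs
#' per generation step (sign alternating over the planted genes); eQTL
#' genes receive `eqtl_slope` log2 units per alternate allele of their
#' linked locus; replicate noise is normal on the log2 scale with SD
#' `noise_sd`.  Values are mapped back to FPKM as 2^x - 1, floored at 0.
#'
#' @param cfg A [sim_config()].
#' @param genotypes Output of [simulate_genotypes()].
#' @return A list with `expression` (gene [expression_matrix()]) and
#'   `truth` (`data.frame`: `gene_id`, `class`
#'   (null/planted_deg/eqtl_target), `deg_direction`, `eqtl_locus`).
#' @export
simulate_expression <- function(cfg, genotypes) {
  set.seed(cfg$seed + 2L)
  sheet <- genotypes$genotypes$sheet
  roles <- sim_gene_roles(cfg)
  ns <- nrow(sheet)
  sd_ref <- effect_ref_sd(cfg)

  special <- c(roles$eqtl, roles$deg)
  base_fpkm <- stats::setNames(numeric(cfg$n_genes), roles$ids)
  base_fpkm[roles$null] <- stats::rlnorm(length(roles$null), 3, 1)
  base_fpkm[special] <- stats::rlnorm(length(special), 4, 0.3)

  x <- matrix(rep(log2(base_fpkm + 1), ns), ncol = ns,
              dimnames = list(roles$ids, sheet$sample_id))
  centre <- (cfg$n_generations + 1) / 2
  gen_centred <- sheet$generation - centre
  for (gid in roles$deg) {
    x[gid, ] <- x[gid, ] +
      roles$deg_direction[gid] * cfg$deg_effect_sd_units * sd_ref *
      gen_centred
  }
  link_truth <- genotypes$truth[genotypes$truth$is_eqtl, , drop = FALSE]
  for (i in seq_len(nrow(link_truth))) {
    d <- genotypes$genotypes$dosages[link_truth$locus_id[i], ]
    x[link_truth$gene_id[i], ] <- x[link_truth$gene_id[i], ] +
      cfg$eqtl_slope * as.numeric(d)
  }
  if (cfg$noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, cfg$noise_sd), nrow(x))
  vals <- pmax(2^x - 1, 0)

  eqtl_locus <- stats::setNames(rep(NA_character_, cfg$n_genes), roles$ids)
  first_link <- link_truth[!duplicated(link_truth$gene_id), , drop = FALSE]
  eqtl_locus[first_link$gene_id] <- first_link$locus_id
  truth <- data.frame(
    gene_id = roles$ids,
    class = ifelse(roles$ids %in% roles$eqtl, "eqtl_target",
                   ifelse(roles$ids %in% roles$deg, "planted_deg", "null")),
    deg_direction = ifelse(roles$ids %in% roles$deg,
                           roles$deg_direction[roles$ids], 0),
    eqtl_locus = eqtl_locus,
    stringsAsFactors = FALSE, row.names = NULL)
  list(expression = expression_matrix(vals, sheet, "gene"), truth = truth)
}

#' Simulate miRNA expression and a target pair list
#'
#' The first `n_concordant_pairs` miRNAs are planted with a monotone
#' log2-scale trend matching the direction of their paired planted DEG
#' target; the remaining pairs link trend-free miRNAs to trend-free
#' (null) genes, so under the "same trend" concordance rule exactly the
#' planted pairs score concordant.
#'
#' @param cfg A [sim_config()].
#' @param expression Output of [simulate_expression()].
#' @return A list with `mirna` (miRNA [expression_matrix()]), `pairs`
#'   (`data.frame`: `mirna_id`, `gene_id`) and `truth` (pairs plus
#'   `planted_concordant`).
#' @export
simulate_mirna_and_pairs <- function(cfg, expression) {
  set.seed(cfg$seed + 3L)
  sheet <- expression$expression$sheet
  roles <- sim_gene_roles(cfg)
  ns <- nrow(sheet)
  sd_ref <- effect_ref_sd(cfg)
  ids <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  base <- stats::rlnorm(cfg$n_mirnas, 4, 0.3)
  x <- matrix(rep(log2(base + 1), ns), ncol = ns,
              dimnames = list(ids, sheet$sample_id))
  centre <- (cfg$n_generations + 1) / 2
  gen_centred <- sheet$generation - centre

  nc <- cfg$n_concordant_pairs
  conc_genes <- roles$deg[seq_len(nc)]
  for (i in seq_len(nc)) {
    dir <- roles$deg_direction[conc_genes[i]]
    x[ids[i], ] <- x[ids[i], ] +
      dir * cfg$deg_effect_sd_units * sd_ref * gen_centred
  }
  if (cfg$noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, cfg$noise_sd), nrow(x))
  vals <- pmax(2^x - 1, 0)

  n_disc <- cfg$n_target_pairs - nc
  disc_mirnas <- rep_len(ids[seq.int(nc + 1L, cfg$n_mirnas)], n_disc)
  pairs <- data.frame(
    mirna_id = c(ids[seq_len(nc)], disc_mirnas),
    gene_id = c(conc_genes, roles$null[seq_len(n_disc)]),
    stringsAsFactors = FALSE)
  truth <- cbind(pairs,
                 planted_concordant = c(rep(TRUE, nc), rep(FALSE, n_disc)))
  list(mirna = expression_matrix(vals, sheet, "mirna"),
       pairs = pairs, truth = truth)
}

#' Simulate per-passage tumor growth curves
#'
#' Vehicle tumors grow exponentially from baselines drawn uniformly
#' from `baseline_range`; treatment tumors are constructed so that the
#' expected group-level TGI at the endpoint equals the configured
#' per-passage response profile (treatment growth = (1 - TGI/100) x
#' mean vehicle growth).  Multiplicative lognormal measurement noise is
#' applied when `growth_noise_sd > 0`; with noise off, [efficacy()]
#' recovers the configured TGI exactly.
#'
#' @param cfg A [sim_config()].
#' @return A growth `data.frame` (see [read_growth_csv()]) covering
#'   passages 2 .. 1 + length(response_tgi_percent).
#' @export
simulate_growth <- function(cfg) {
  set.seed(cfg$seed + 4L)
  days <- cfg$growth_days
  out <- list()
  for (k in seq_along(cfg$response_tgi_percent)) {
    passage <- k + 1L
    f <- 1 - cfg$response_tgi_percent[k] / 100
    bv <- stats::runif(cfg$n_replicates, cfg$baseline_range[1],
                       cfg$baseline_range[2])
    bt <- stats::runif(cfg$n_replicates, cfg$baseline_range[1],
                       cfg$baseline_range[2])
    for (d in days) {
      growth_factor <- exp(cfg$vehicle_growth_rate * d)
      v_vol <- bv * growth_factor
      t_vol <- bt + f * mean(bv) * (growth_factor - 1)
      if (cfg$growth_noise_sd > 0 && d > 0) {
        v_vol <- v_vol * stats::rlnorm(cfg$n_replicates, 0,
                                       cfg$growth_noise_sd)
        t_vol <- pmax(t_vol * stats::rlnorm(cfg$n_replicates, 0,
                                            cfg$growth_noise_sd), 0)
      }
      out[[length(out) + 1L]] <- data.frame(
        animal_id = c(sprintf("P%d_v%d", passage, seq_len(cfg$n_replicates)),
                      sprintf("P%d_t%d", passage, seq_len(cfg$n_replicates))),
        group = rep(c("vehicle", "treatment"), each = cfg$n_replicates),
        day = d, passage = passage,
        length_mm = NA_real_, width_mm = NA_real_,
        volume_mm3 = c(v_vol, t_vol), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate a complete cohort
#'
#' Runs all four generators under one configuration and assembles the
#' immune gene list (the first `n_immune_planted` eQTL genes plus
#' `n_immune_extra` filler ids outside the expression layer, emulating a
#' genome-wide immune list of which only a few members are candidates).
#'
#' @param cfg A [sim_config()].
#' @return A list with `genotypes`, `genotype_truth`, `expression`,
#'   `expression_truth`, `mirna`, `pairs`, `pair_truth`, `annotation`,
#'   `immune_genes`, `growth`, `sheet`, `cfg`.
#' @export
simulate_cohort <- function(cfg) {
  gen <- simulate_genotypes(cfg)
  expr <- simulate_expression(cfg, gen)
  mir <- simulate_mirna_and_pairs(cfg, expr)
  growth <- simulate_growth(cfg)
  roles <- sim_gene_roles(cfg)
  immune <- c(roles$eqtl[seq_len(cfg$n_immune_planted)],
              sprintf("immune_extra_%03d", seq_len(cfg$n_immune_extra)))
  list(genotypes = gen$genotypes, genotype_truth = gen$truth,
       expression = expr$expression, expression_truth = expr$truth,
       mirna = mir$mirna, pairs = mir$pairs, pair_truth = mir$truth,
       annotation = simulated_gene_annotation(cfg),
       immune_genes = immune, growth = growth,
       sheet = gen$genotypes$sheet, cfg = cfg)
}

#' Write a simulated cohort to disk
#'
#' Emits every input file the pipeline consumes (VCF, expression TSVs,
#' pair TSV, BED annotation, immune list, growth CSV, sample sheet) plus
#' the truth tables, all as plain text.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named list of the file paths written, invisibly.
#' @export
write_simulated_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_vcf(sim$genotypes, p("cohort.vcf"))
  write_sample_sheet(sim$sheet, p("sample_sheet.tsv"))
  write_expression_tsv(sim$expression, p("genes.tsv"), "gene_id")
  write_expression_tsv(sim$mirna, p("mirna.tsv"), "mirna_id")
  utils::write.table(sim$pairs, p("pairs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gene_annotation(sim$annotation, p("genes.bed"))
  writeLines(sim$immune_genes, p("immune.txt"))
  write_growth_csv(sim$growth, p("growth.csv"))
  utils::write.table(sim$genotype_truth, p("truth_loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$expression_truth, p("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$pair_truth, p("truth_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(
    vcf = p("cohort.vcf"), sample_sheet = p("sample_sheet.tsv"),
    gene_expression = p("genes.tsv"), mirna_expression = p("mirna.tsv"),
    pairs = p("pairs.tsv"), annotation = p("genes.bed"),
    immune = p("immune.txt"), growth = p("growth.csv"),
    truth_loci = p("truth_loci.tsv"), truth_genes = p("truth_genes.tsv"),
    truth_pairs = p("truth_pairs.tsv")))
}
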