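test_that("configurations validate their planted structure", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, n_loci = 100, n_eqtl_links = 50),
               "selected-up")
  expect_error(sim_config(seed = 1, n_concordant_pairs = 60), "exceeds")
  expect_error(sim_config(seed = 1, frac_selected_up = 0.9,
                          frac_selected_down = 0.2), "sum <= 1")
  expect_error(sim_config(seed = 1, selected_path = c(0, 1)), "per generation")
})

test_that("the same seed reproduces the cohort bit for bit", {
  cfg <- sim_config(seed = 99, n_loci = 80, n_genes = 60,
                    n_planted_degs = 16, n_eqtl_links = 1L,
                    n_eqtl_genes = 1L, n_immune_planted = 1L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$growth, b$growth)
})

test_that("the noise-free planted path reproduces the canonical trajectory", {
  cfg <- sim_config(seed = 2, n_loci = 100, frac_selected_up = 0.01,
                    frac_selected_down = 0, noise_sd = 0,
                    n_eqtl_links = 1L, n_eqtl_genes = 1L,
                    n_immune_planted = 1L)
  sim <- simulate_genotypes(cfg)
  up_id <- sim$truth$locus_id[sim$truth$class == "selected_up"]
  expect_length(up_id, 1L)
  maf <- per_generation_maf(sim$genotypes)
  fr <- unlist(maf[maf$locus_id == up_id, paste0("freq_g", 1:5)],
               use.names = FALSE)
  expect_equal(round(fr, 6), c(0, 0.166667, 0.333333, 0.333333, 0.666667))
  v <- trajectory_filter(fr)
  expect_true(v$passes)
  expect_equal(v$direction, "increasing")
})

test_that("neutral pass rates match the filter's own enumeration", {
  # With binomial sampling at constant latent frequency, the chance a
  # neutral locus passes is computable by enumerating generation counts.
  cfg <- sim_config(seed = 23, n_loci = 20000L, frac_selected_up = 0,
                    frac_selected_down = 0, n_eqtl_links = 0L,
                    n_eqtl_genes = 0L, n_immune_planted = 0L)
  sim <- simulate_genotypes(cfg)
  v <- trajectory_verdicts(per_generation_maf(sim$genotypes))
  observed <- mean(v$passes)

  # analytic expectation, averaged over the latent-frequency prior
  pass_prob <- function(p) {
    probs <- dbinom(0:6, 6, p)
    inc <- 0
    for (c1 in 0:2) for (c2 in c1:6) for (c3 in c2:6)
      for (c4 in c3:6) for (c5 in max(c4, 4):6)
        inc <- inc + probs[c1 + 1] * probs[c2 + 1] * probs[c3 + 1] *
          probs[c4 + 1] * probs[c5 + 1]
    2 * inc   # decreasing rule is symmetric under count reflection
  }
  expected <- mean(vapply(seq(0.05, 0.95, length.out = 101), pass_prob,
                          numeric(1)))
  expect_lt(abs(observed - expected), 3 * sqrt(expected / cfg$n_loci) + 1e-4)
})

test_that("planted eQTL links are recoverable by association", {
  cfg <- sim_config(seed = 41, n_loci = 300, frac_selected_up = 0.05,
                    noise_sd = 0.1)
  sim <- simulate_cohort(cfg)
  links <- sim$genotype_truth[sim$genotype_truth$is_eqtl, ]
  for (i in seq_len(nrow(links))) {
    res <- genotype_expression_association(
      sim$genotypes$dosages[links$locus_id[i], ],
      sim$expression$values[links$gene_id[i], ])
    expect_lt(res$p_value, 0.01)
    expect_gt(res$slope, 0)
  }
})

test_that("null expression calibrates the ANOVA false-positive rate", {
  cfg <- sim_config(seed = 57, n_loci = 20, n_genes = 1000,
                    frac_selected_up = 0, frac_selected_down = 0,
                    n_planted_degs = 0L, n_eqtl_links = 0L,
                    n_eqtl_genes = 0L, n_immune_planted = 0L,
                    n_concordant_pairs = 0L)
  sim <- simulate_cohort(cfg)
  av <- anova_table(sim$expression)
  expect_gt(mean(av$p_value < 0.05), 0.03)
  expect_lt(mean(av$p_value < 0.05), 0.07)
})

test_that("planted concordant pairs are exactly recovered at zero noise", {
  cfg <- sim_config(seed = 3, n_loci = 100, frac_selected_up = 0.05,
                    n_genes = 200, noise_sd = 0,
                    n_eqtl_links = 5L, n_eqtl_genes = 5L,
                    n_immune_planted = 5L)
  sim <- simulate_cohort(cfg)
  conc <- mirna_target_concordance(sim$mirna, sim$expression, sim$pairs)
  expect_equal(sum(conc$concordant), 16L)
  expect_setequal(
    paste(conc$mirna_id[conc$concordant], conc$gene_id[conc$concordant]),
    paste(sim$pair_truth$mirna_id[sim$pair_truth$planted_concordant],
          sim$pair_truth$gene_id[sim$pair_truth$planted_concordant]))

  cfg0 <- sim_config(seed = 3, n_loci = 100, frac_selected_up = 0.05,
                     n_genes = 200, noise_sd = 0,
                     n_eqtl_links = 5L, n_eqtl_genes = 5L,
                     n_immune_planted = 5L, n_concordant_pairs = 0L)
  sim0 <- simulate_cohort(cfg0)
  conc0 <- mirna_target_concordance(sim0$mirna, sim0$expression, sim0$pairs)
  expect_equal(sum(conc0$concordant), 0L)
})

test_that("noise-free growth curves invert the TGI formula exactly", {
  cfg <- sim_config(seed = 5, growth_noise_sd = 0)
  eff <- passage_efficacy(simulate_growth(cfg))
  expect_equal(eff$tgi_percent, c(44.62, 43.93, -44.04, 7.42),
               tolerance = 1e-9)
  expect_equal(eff$call,
               c("responsive", "responsive", "resistant", "resistant"))

  # TGI 100: treated tumors do not grow at all
  cfg100 <- sim_config(seed = 5, growth_noise_sd = 0,
                       response_tgi_percent = 100)
  g100 <- simulate_growth(cfg100)
  tr <- g100[g100$group == "treatment", ]
  expect_true(all(tapply(tr$volume_mm3, tr$animal_id,
                         function(v) diff(range(v))) < 1e-9))
  expect_equal(passage_efficacy(g100)$tgi_percent, 100)

  # TGI 0: treated growth equals vehicle growth
  cfg0 <- sim_config(seed = 5, growth_noise_sd = 0,
                     response_tgi_percent = 0)
  expect_equal(passage_efficacy(simulate_growth(cfg0))$tgi_percent, 0,
               tolerance = 1e-12)
})

test_that("a written cohort round-trips through the format readers", {
  cfg <- sim_config(seed = 11, n_loci = 60, n_genes = 80,
                    n_planted_degs = 16, n_target_pairs = 30L,
                    n_eqtl_links = 1L, n_eqtl_genes = 1L,
                    n_immune_planted = 1L)
  sim <- simulate_cohort(cfg)
  dir <- tempfile()
  paths <- write_simulated_cohort(sim, dir)
  sheet <- read_sample_sheet(paths$sample_sheet)
  expect_equal(sheet, sim$sheet)
  g <- read_vcf(paths$vcf, sheet)
  expect_identical(g$dosages, sim$genotypes$dosages)
  e <- read_expression_tsv(paths$gene_expression, sheet)
  expect_equal(e$values, sim$expression$values, tolerance = 1e-12)
  m <- read_expression_tsv(paths$mirna_expression, sheet, "mirna")
  expect_equal(m$values, sim$mirna$values, tolerance = 1e-12)
  ann <- read_gene_annotation(paths$annotation)
  expect_equal(ann[, c("gene_id", "chrom", "start", "end")],
               sim$annotation[, c("gene_id", "chrom", "start", "end")])
  expect_setequal(read_gene_set(paths$immune), sim$immune_genes)
  gr <- read_growth_csv(paths$growth)
  expect_equal(gr$volume_mm3, sim$growth$volume_mm3, tolerance = 1e-9)
})
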