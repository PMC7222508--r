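test_that("per-generation frequencies divide dosage sums by callable chromosomes", {
  g <- genotypes_from_generation_sums(c(0, 1, 2, 2, 4))
  maf <- per_generation_maf(g)
  expect_equal(unlist(maf[1, paste0("freq_g", 1:5)], use.names = FALSE),
               c(0, 1, 2, 2, 4) / 6)
  expect_equal(unlist(maf[1, paste0("callable_g", 1:5)], use.names = FALSE),
               rep(6, 5))

  allref <- genotypes_from_generation_sums(c(0, 0, 0, 0, 0))
  expect_true(all(per_generation_maf(allref)[, paste0("freq_g", 1:5)] == 0))
})

test_that("frequencies are invariant to sample and locus order", {
  sim <- simulate_genotypes(sim_config(seed = 5, n_loci = 30,
                                       n_eqtl_links = 0L, n_eqtl_genes = 0L,
                                       n_immune_planted = 0L))
  g <- sim$genotypes
  maf <- per_generation_maf(g)
  # permute both loci and sample columns, rebuild, recompute
  set.seed(1)
  li <- sample(nrow(g$dosages))
  si <- sample(ncol(g$dosages))
  g2 <- genotype_matrix(g$dosages[li, si], g$loci[li, ], g$sheet)
  maf2 <- per_generation_maf(g2)
  maf2 <- maf2[match(maf$locus_id, maf2$locus_id), ]
  rownames(maf2) <- NULL
  expect_equal(maf2, maf)
})

test_that("a generation with no callable samples flags the locus undefined", {
  g <- genotypes_from_generation_sums(c(0, 1, 2, 2, 4))
  dos <- g$dosages
  dos[1, g$sheet$sample_id[g$sheet$generation == 3]] <- NA
  g2 <- genotype_matrix(dos, g$loci, g$sheet)
  maf <- per_generation_maf(g2)
  expect_true(is.na(maf$freq_g3))
  expect_false(maf$defined)
  v <- trajectory_verdicts(maf)
  expect_false(v$passes)
  expect_error(trajectory_filter(unlist(maf[1, paste0("freq_g", 1:5)])),
               "undefined")
})

test_that("the trajectory filter applies the monotone boundary rules", {
  up <- trajectory_filter(c(0, 1, 2, 2, 4) / 6)
  expect_true(up$passes)
  expect_equal(up$direction, "increasing")  # non-strict: internal tie allowed

  flat <- trajectory_filter(rep(0.5, 5))
  expect_false(flat$passes)

  down <- trajectory_filter(c(0.8, 0.7, 0.5, 0.4, 0.2))
  expect_true(down$passes)
  expect_equal(down$direction, "decreasing")

  # boundary excursion required on both ends
  expect_false(trajectory_filter(c(0, 0.1, 0.2, 0.3, 0.5))$passes)
  expect_false(trajectory_filter(c(0.5, 0.6, 0.6, 0.7, 1))$passes)
})

test_that("vectorized verdicts agree with the scalar filter on random trajectories", {
  set.seed(9)
  fr <- matrix(sample(0:6, 200 * 5, replace = TRUE) / 6, ncol = 5)
  maf <- data.frame(locus_id = sprintf("l%03d", 1:200), fr,
                    defined = TRUE)
  names(maf)[2:6] <- paste0("freq_g", 1:5)
  v <- trajectory_verdicts(maf)
  for (i in seq_len(nrow(fr))) {
    s <- trajectory_filter(fr[i, ])
    expect_equal(v$passes[i], s$passes)
    expect_equal(v$direction[i], s$direction)
  }
})

test_that("neutral cohorts pass rarely and symmetrically in direction", {
  cfg <- sim_config(seed = 17, n_loci = 100000L, frac_selected_up = 0,
                    frac_selected_down = 0, n_eqtl_links = 0L,
                    n_eqtl_genes = 0L, n_immune_planted = 0L)
  sim <- simulate_genotypes(cfg)
  v <- trajectory_verdicts(per_generation_maf(sim$genotypes))
  n_inc <- sum(v$direction == "increasing")
  n_dec <- sum(v$direction == "decreasing")
  expect_lt((n_inc + n_dec) / nrow(v), 0.05)   # rare under drift-free noise
  if (n_inc + n_dec > 0) {
    bt <- binom.test(n_inc, n_inc + n_dec, 0.5)
    expect_gt(bt$p.value, 0.01)
  }
})

test_that("noise-free planted loci are recovered with no neutral false positives", {
  cfg <- sim_config(seed = 21, n_loci = 500, noise_sd = 0,
                    n_eqtl_links = 5L, n_eqtl_genes = 4L,
                    n_immune_planted = 4L)
  sim <- simulate_genotypes(cfg)
  v <- trajectory_verdicts(per_generation_maf(sim$genotypes))
  expect_setequal(v$locus_id[v$passes],
                  sim$truth$locus_id[sim$truth$class != "neutral"])
  expect_true(all(v$direction[match(
    sim$truth$locus_id[sim$truth$class == "selected_up"], v$locus_id)] ==
      "increasing"))
})

test_that("Hamming distances are missing-aware proportions", {
  sheet <- sample_sheet(c("s1", "s2"), c(1, 1), c(1, 2))
  dos <- cbind(s1 = c(0L, 0L, 1L, 2L, 0L, 1L, 1L, 0L, 2L, 2L),
               s2 = c(1L, 0L, 1L, 0L, 0L, 1L, 1L, 0L, 2L, 0L))
  loci <- data.frame(locus_id = sprintf("l%02d", 1:10), chrom = "chr1",
                     pos = 1:10, ref = "A", alt = "G")
  g <- genotype_matrix(dos, loci, sheet)
  d <- hamming_distance(g)
  expect_equal(d["s1", "s2"], 3 / 10)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))

  # identical columns
  g0 <- genotype_matrix(cbind(s1 = dos[, 1], s2 = dos[, 1]), loci, sheet)
  expect_true(all(hamming_distance(g0) == 0))

  # permuted locus order gives the identical matrix
  set.seed(2)
  li <- sample(10)
  gp <- genotype_matrix(dos[li, ], loci[li, ], sheet)
  expect_equal(hamming_distance(gp), d)

  # pairwise-missing loci drop from that pair's denominator
  dosm <- dos; dosm[1, 1] <- NA
  gm <- genotype_matrix(dosm, loci, sheet)
  expect_equal(hamming_distance(gm)["s1", "s2"], 2 / 9)

  dos_none <- dos; dos_none[, 1] <- NA
  expect_error(
    hamming_distance(genotype_matrix(dos_none, loci, sheet)),
    "no mutually callable")
})

test_that("classical MDS reconstructs embeddable configurations", {
  # two points: 1-D coordinates +-d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  emb2 <- classical_mds(d2, k = 1)
  expect_equal(sort(unname(emb2$coords[, 1])), c(-1.5, 1.5))

  # equilateral triangle: pairwise embedded distances all 1
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  emb3 <- classical_mds(d3, k = 2)
  expect_equal(as.numeric(dist(emb3$coords)), rep(1, 3), tolerance = 1e-9)

  # random Euclidean configuration: full-rank embedding reproduces d
  set.seed(4)
  pts <- matrix(rnorm(6 * 3), 6, 3)
  rownames(pts) <- sprintf("s%d", 1:6)
  d <- as.matrix(dist(pts))
  emb <- classical_mds(d, k = 5)
  expect_equal(as.matrix(dist(emb$coords)), d, tolerance = 1e-9,
               ignore_attr = TRUE)

  # all-zero distances embed to all-zero coordinates
  dz <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(classical_mds(dz, k = 2)$coords == 0))
  expect_error(classical_mds(dz, k = 4), "k must be")

  # deterministic sign convention: largest-magnitude entry positive
  expect_true(all(apply(emb$coords, 2, function(co) co[which.max(abs(co))] >= 0)))
})

test_that("separation scores rank clear splits above degenerate ones", {
  sheet <- default_sample_sheet()
  coords <- cbind(C1 = c(rep(0, 12), rep(10, 3)) + seq(0, 1.4, length.out = 15),
                  C2 = rep(0, 15))
  emb <- structure(list(coords = coords, eig = NULL,
                        sample_ids = sheet$sample_id),
                   class = "mds_embedding")
  expect_gt(separation_score(emb, sheet, 5), 0.5)

  emb0 <- structure(list(coords = matrix(0, 15, 2), eig = NULL,
                         sample_ids = sheet$sample_id),
                    class = "mds_embedding")
  expect_equal(separation_score(emb0, sheet, 5), 0)
  expect_error(separation_score(emb, sheet, 1:5), "two non-empty sides")
})
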