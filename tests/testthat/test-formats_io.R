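sheet15 <- default_sample_sheet()

test_that("sample sheets enforce the balanced design", {
  expect_equal(nrow(sheet15), 15L)
  expect_error(sample_sheet(c("a", "a"), c(1, 1), c(1, 2)), "unique")
  expect_error(sample_sheet(c("a", "b", "c"), c(1, 1, 2), c(1, 2, 1)),
               "replicate count")
  tf <- tempfile()
  write_sample_sheet(sheet15, tf)
  expect_equal(read_sample_sheet(tf), sheet15)
})

test_that("GT fields parse to dosages, phase-insensitively", {
  sheet <- sample_sheet(c("s1", "s2", "s3"), c(1, 1, 1), c(1, 2, 3))
  path <- write_vcf_fixture(list(c("0/0", "0/1", "1/1"),
                                 c("0|1", "1|0", "./.")),
                            sheet$sample_id)
  g <- read_vcf(path, sheet)
  expect_equal(unname(g$dosages[1, ]), c(0L, 1L, 2L))
  expect_equal(unname(g$dosages[2, ]), c(1L, 1L, NA_integer_))
})

test_that("missing genotypes are excluded from frequency denominators", {
  # one sample missing in g1, the other two 0/1: freq = 2/4
  path <- write_vcf_fixture(
    list(c("./.", "0/1", "0/1", rep("0/0", 12))), sheet15$sample_id)
  maf <- per_generation_maf(read_vcf(path, sheet15))
  expect_equal(maf$freq_g1, 2 / 4)
  expect_equal(maf$callable_g1, 4)
  expect_equal(maf$freq_g2, 0)
})

test_that("multi-allelic records split into one locus per alt allele", {
  sheet <- sample_sheet(c("s1", "s2"), c(1, 1), c(1, 2))
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t500\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2\t0/1"), path)
  g <- read_vcf(path, sheet)
  expect_equal(nrow(g$dosages), 2L)
  expect_equal(g$loci$locus_id, c("chr1:500_A/G", "chr1:500_A/T"))
  expect_equal(unname(g$dosages[1, ]), c(1L, 1L))  # G allele
  expect_equal(unname(g$dosages[2, ]), c(1L, 0L))  # T allele
})

test_that("read_vcf rejects bad headers and non-diploid calls", {
  sheet <- sample_sheet(c("s1", "sX"), c(1, 1), c(1, 2))
  path <- write_vcf_fixture(list(c("0/0", "0/1")), c("s1", "s2"))
  expect_error(read_vcf(path, sheet), "absent from the VCF header")
  sheet2 <- sample_sheet(c("s1", "s2"), c(1, 1), c(1, 2))
  bad <- write_vcf_fixture(list(c("0/0/1", "0/1")), c("s1", "s2"))
  expect_error(read_vcf(bad, sheet2), "non-diploid")
})

test_that("VCF writing round-trips dosages exactly", {
  sim <- simulate_genotypes(sim_config(seed = 3, n_loci = 40,
                                       n_eqtl_links = 0L, n_eqtl_genes = 0L,
                                       n_immune_planted = 0L))
  tf <- tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, tf)
  back <- read_vcf(tf, sim$genotypes$sheet)
  expect_identical(back$dosages, sim$genotypes$dosages)
  expect_identical(back$loci$locus_id, sim$genotypes$loci$locus_id)
})

test_that("expression TSVs validate and are column-order invariant", {
  vals <- matrix(seq_len(30), 2, 15,
                 dimnames = list(c("gA", "gB"), sheet15$sample_id))
  tf <- tempfile()
  df <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE)
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  e <- read_expression_tsv(tf, sheet15)
  expect_equal(dim(e$values), c(2L, 15L))

  shuf <- df[, c(1L, 1L + sample(15))]
  tf2 <- tempfile()
  write.table(shuf, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_expression_tsv(tf2, sheet15)$values, e$values)

  df_neg <- df; df_neg[1, 2] <- -1
  tf3 <- tempfile()
  write.table(df_neg, tf3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_tsv(tf3, sheet15), "negative")

  df_dup <- rbind(df, df[1, ])
  tf4 <- tempfile()
  write.table(df_dup, tf4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_tsv(tf4, sheet15), "duplicate")
})

test_that("growth CSVs derive volumes from calipers and validate", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("animal_id,group,day,length_mm,width_mm,volume_mm3",
               "m1,treatment,0,10,10,",
               "m2,vehicle,0,,,350",
               "m3,vehicle,7,10,10,500"), tf)
  rec <- read_growth_csv(tf)
  expect_equal(rec$volume_mm3, c(500, 350, 500))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("animal_id,group,day,length_mm,width_mm,volume_mm3",
               "m1,treatment,0,10,10,123"), bad)
  expect_error(read_growth_csv(bad), "disagrees")

  badgrp <- tempfile(fileext = ".csv")
  writeLines(c("animal_id,group,day,volume_mm3",
               "m1,placebo,0,100"), badgrp)
  expect_error(read_growth_csv(badgrp), "unknown group")
})

test_that("gene sets de-duplicate, skip comments, and scale to a full immune list", {
  tf <- tempfile()
  writeLines(c("TP53", "# a comment", "EGFR", "TP53", ""), tf)
  expect_setequal(read_gene_set(tf), c("TP53", "EGFR"))

  tf2 <- tempfile()
  writeLines(c("# only", "# comments"), tf2)
  expect_warning(ids <- read_gene_set(tf2), "empty")
  expect_length(ids, 0L)

  tf3 <- tempfile()
  writeLines(sprintf("IMM%04d", 1:1040), tf3)
  expect_length(read_gene_set(tf3), 1040L)
})

test_that("BED annotation converts coordinates once, at read time", {
  tf <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tgeneA\t0\t+", tf)
  ann <- read_gene_annotation(tf)
  expect_equal(ann$start, 101L)   # 0-based half-open -> 1-based closed
  expect_equal(ann$end, 200L)
  tf2 <- tempfile(fileext = ".bed")
  write_gene_annotation(ann, tf2)
  expect_equal(readLines(tf2), "chr1\t100\t200\tgeneA\t0\t+")
})
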