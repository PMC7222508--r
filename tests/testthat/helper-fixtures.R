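# Shared fixtures and independent oracles for the test suite.

# Write a VCF text fixture by hand (independent of write_vcf).
# `gt_rows` is a list of character vectors, one GT string per sample.
write_vcf_fixture <- function(gt_rows, samples,
                              chrom = "chr1", pos = NULL,
                              ref = "A", alt = "G") {
  if (is.null(pos)) pos <- seq_along(gt_rows) * 100L
  path <- tempfile(fileext = ".vcf")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(gt_rows)) {
    lines <- c(lines, paste(c(chrom, pos[i], ".", ref, alt, ".", "PASS",
                              ".", "GT", gt_rows[[i]]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# Genotype matrix with given per-generation dosage sums for one locus,
# distributed over replicates as (2,2,...,1,0,...).
genotypes_from_generation_sums <- function(sums, sheet = default_sample_sheet()) {
  gens <- sort(unique(sheet$generation))
  stopifnot(length(sums) == length(gens))
  dos <- matrix(NA_integer_, 1L, nrow(sheet),
                dimnames = list(NULL, sheet$sample_id))
  for (j in seq_along(gens)) {
    cols <- sheet$sample_id[sheet$generation == gens[j]]
    remaining <- sums[j]
    for (s in cols) {
      take <- min(2L, remaining)
      dos[1L, s] <- take
      remaining <- remaining - take
    }
  }
  loci <- data.frame(locus_id = "chr1:100_A/G", chrom = "chr1", pos = 100L,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(dos, loci, sheet)
}

# Brute-force trajectory rule: a literal transcription of the two
# filtering rules, evaluated term by term.
oracle_trajectory <- function(freqs, low = 1/3, high = 2/3) {
  n <- length(freqs)
  monotone_up <- TRUE
  monotone_down <- TRUE
  for (i in seq_len(n - 1L)) {
    if (freqs[i + 1L] < freqs[i]) monotone_up <- FALSE
    if (freqs[i + 1L] > freqs[i]) monotone_down <- FALSE
  }
  if (monotone_up && freqs[1L] <= low && freqs[n] >= high)
    return(list(passes = TRUE, direction = "increasing"))
  if (monotone_down && freqs[1L] >= high && freqs[n] <= low)
    return(list(passes = TRUE, direction = "decreasing"))
  list(passes = FALSE, direction = "none")
}

# Brute-force one-way ANOVA F from explicit sums of squares.
oracle_anova_f <- function(y, groups) {
  groups <- as.character(groups)
  grand <- mean(y)
  ssb <- 0
  ssw <- 0
  for (g in unique(groups)) {
    yg <- y[groups == g]
    ssb <- ssb + length(yg) * (mean(yg) - grand)^2
    ssw <- ssw + sum((yg - mean(yg))^2)
  }
  dfb <- length(unique(groups)) - 1L
  dfw <- length(y) - length(unique(groups))
  (ssb / dfb) / (ssw / dfw)
}

# Simple-regression F via explicit normal equations.
oracle_regression_f <- function(x, y) {
  n <- length(y)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  resid <- y - alpha - beta * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  ((ss_tot - ss_res) / 1) / (ss_res / (n - 2))
}

# Two partitions are the same up to label renaming.
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

expr_matrix_from_rows <- function(rows, sheet = default_sample_sheet(),
                                  kind = "gene") {
  m <- do.call(rbind, rows)
  colnames(m) <- sheet$sample_id
  if (is.null(rownames(m))) rownames(m) <- names(rows)
  expression_matrix(m, sheet, kind)
}
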