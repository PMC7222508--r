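#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses the GT field of every sample into an alternate-allele dosage:
#' `0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> missing (`NA`).
#' Phased separators (`|`) are accepted.  Multi-allelic records are split
#' into one locus per alternate allele; the dosage of each split locus
#' counts that allele only, and the locus id is suffixed with the allele.
#' Missing calls are excluded from allele-frequency denominators
#' downstream (see [per_generation_maf()]).
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param sheet A [sample_sheet()]; every `sample_id` must appear in the
#'   VCF header.  Extra VCF samples are ignored.
#' @return A [genotype_matrix()] with columns in sample-sheet order.
#' @export
#' @examples
#' \dontrun{
#' g <- read_vcf("cohort.vcf", default_sample_sheet())
#' }
read_vcf <- function(path, sheet) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt))
    stop("VCF has no GT FORMAT field", call. = FALSE)
  missing_samples <- setdiff(sheet$sample_id, colnames(gt))
  if (length(missing_samples))
    stop("samples in the sample sheet are absent from the VCF header: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  gt <- gt[, sheet$sample_id, drop = FALSE]

  n_rec <- nrow(fix)
  out_dosage <- list()
  out_loci <- list()
  for (i in seq_len(n_rec)) {
    chrom <- fix[i, "CHROM"]; pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    rec_id <- sprintf("%s:%d_%s", chrom, pos, ref)
    alleles <- parse_gt_row(gt[i, ], rec_id)
    for (a in seq_along(alts)) {
      dos <- colSums(alleles == a)
      dos[apply(is.na(alleles), 2, any)] <- NA_integer_
      id <- sprintf("%s:%d_%s/%s", chrom, pos, ref, alts[a])
      out_dosage[[length(out_dosage) + 1L]] <- dos
      out_loci[[length(out_loci) + 1L]] <-
        data.frame(locus_id = id, chrom = chrom, pos = pos,
                   ref = ref, alt = alts[a], stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, out_loci)
  dosages <- do.call(rbind, out_dosage)
  colnames(dosages) <- sheet$sample_id
  genotype_matrix(dosages, loci, sheet)
}

# Parse one record's GT strings into a 2 x n_samples allele-index matrix
# (NA for missing).  Errors on non-diploid calls, naming the record.
parse_gt_row <- function(gts, rec_id) {
  gts[is.na(gts)] <- "."   # vcfR may convert missing calls to NA
  parts <- strsplit(gts, "[/|]")
  n_alleles <- lengths(parts)
  # a bare "." is a fully missing call
  bare_missing <- vapply(parts, function(p) identical(p, "."), logical(1))
  if (any(n_alleles != 2L & !bare_missing))
    stop("non-diploid GT at record ", rec_id, call. = FALSE)
  al <- vapply(parts, function(p) {
    if (identical(p, ".")) return(c(NA_integer_, NA_integer_))
    p[p == "."] <- NA_character_
    suppressWarnings(as.integer(p))
  }, integer(2))
  al
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with one biallelic record per locus and a GT-only
#' FORMAT column (0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, missing -> `./.`).
#' Reading the file back with [read_vcf()] reproduces the dosage matrix
#' exactly.
#'
#' @param g A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=clonaltraj",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", g$sheet$sample_id), collapse = "\t")
  ), con)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (i in seq_len(nrow(g$dosages))) {
    dos <- g$dosages[i, ]
    gt <- ifelse(is.na(dos), "./.", code[as.character(dos)])
    writeLines(paste(c(g$loci$chrom[i], g$loci$pos[i], g$loci$locus_id[i],
                       g$loci$ref[i], g$loci$alt[i], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
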