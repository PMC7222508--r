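#' Read an expression matrix from a TSV file
#'
#' The first column holds feature ids; the remaining columns are samples.
#' Columns are reordered to sample-sheet order, so the matrix on disk may
#' list samples in any order.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param sheet A [sample_sheet()].
#' @param kind `"gene"` or `"mirna"`.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, sheet, kind = c("gene", "mirna")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression TSV needs a feature column plus sample columns",
         call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature id in expression TSV: ",
         ids[duplicated(ids)][1L], call. = FALSE)
  samp <- names(df)[-1L]
  missing_samples <- setdiff(sheet$sample_id, samp)
  if (length(missing_samples))
    stop("expression TSV is missing samples: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L,
                                     dimnames = list(NULL, samp))
  if (any(is.na(vals)))
    stop("non-numeric cell in expression TSV", call. = FALSE)
  if (any(vals < 0))
    stop("negative expression value in expression TSV", call. = FALSE)
  rownames(vals) <- ids
  expression_matrix(vals[, sheet$sample_id, drop = FALSE], sheet, kind)
}

#' Write an expression matrix to a TSV file
#'
#' @param e An [expression_matrix()].
#' @param path Output file path.
#' @param id_column Header of the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(e, path, id_column = "feature_id") {
  df <- data.frame(rownames(e$values), e$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tumor caliper measurements from a CSV file
#'
#' Expects columns `animal_id`, `group` (`treatment` or `vehicle`),
#' `day`, and either `volume_mm3` or the caliper pair
#' `length_mm`/`width_mm`.  An optional `passage` column identifies the
#' serial passage (default 1).  When only calipers are given the volume
#' is computed as length x width^2 / 2 (see [tumor_volume()]); when both
#' are given they must agree to 1e-9.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` with columns `animal_id`, `group`, `day`,
#'   `passage`, `length_mm`, `width_mm`, `volume_mm3`.
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("animal_id", "group", "day")
  if (!all(need %in% names(df)))
    stop("growth CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$group), c("treatment", "vehicle"))
  if (length(bad))
    stop("unknown group label in growth CSV: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(df$passage)) df$passage <- 1L
  has_cal <- all(c("length_mm", "width_mm") %in% names(df))
  has_vol <- "volume_mm3" %in% names(df)
  if (!has_cal && !has_vol)
    stop("growth CSV needs volume_mm3 or length_mm/width_mm columns",
         call. = FALSE)
  if (!has_cal) df$length_mm <- df$width_mm <- NA_real_
  if (!has_vol) df$volume_mm3 <- NA_real_
  cal_ok <- !is.na(df$length_mm) & !is.na(df$width_mm)
  derived <- ifelse(cal_ok,
                    tumor_volume(ifelse(cal_ok, df$length_mm, 0),
                                 ifelse(cal_ok, df$width_mm, 0),
                                 warn = FALSE),
                    NA_real_)
  fill <- is.na(df$volume_mm3) & cal_ok
  df$volume_mm3[fill] <- derived[fill]
  both <- !is.na(df$volume_mm3) & cal_ok
  if (any(both & abs(df$volume_mm3 - derived) > 1e-9))
    stop("growth CSV: volume_mm3 disagrees with (length x width^2)/2",
         call. = FALSE)
  if (any(is.na(df$volume_mm3)))
    stop("growth CSV: rows with neither volume nor caliper pair",
         call. = FALSE)
  if (any(df$volume_mm3 < 0))
    stop("growth CSV: negative volume", call. = FALSE)
  df$day <- as.integer(df$day)
  df[, c("animal_id", "group", "day", "passage",
         "length_mm", "width_mm", "volume_mm3")]
}

#' Write growth records to a CSV file
#' @param records Growth `data.frame` as returned by [read_growth_csv()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene set from a plain-text file
#'
#' One id per line; blank lines and `#` comments are ignored; duplicates
#' are dropped.
#'
#' @param path Path to the file.
#' @return A character vector of unique ids (a set; order not meaningful).
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  ids <- unique(lines[nzchar(lines)])
  if (!length(ids)) warning("gene set file is empty: ", path, call. = FALSE)
  ids
}

#' Read gene annotation from a BED file
#'
#' BED intervals are 0-based half-open on disk; they are converted to
#' 1-based closed coordinates exactly once, at read time, by
#' `rtracklayer`.  Strand is retained but ignored by locus-to-gene
#' mapping (positional containment only).
#'
#' @param path Path to a BED file (>= 4 columns; column 4 is the gene id).
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based closed), `strand`.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  ids <- gr$name
  if (is.null(ids) || any(is.na(ids)))
    stop("BED annotation must carry a gene id in column 4", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate gene id in annotation: ",
         ids[duplicated(ids)][1L], call. = FALSE)
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write gene annotation as BED6
#' @param ann Annotation `data.frame` from [read_gene_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  strand <- ifelse(ann$strand %in% c("+", "-"), ann$strand, ".")
  bed <- data.frame(ann$chrom, ann$start - 1L, ann$end, ann$gene_id,
                    0L, strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
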