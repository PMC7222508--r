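#' Genotype matrix container
#'
#' Holds alternate-allele dosages (0, 1, 2 or `NA` for missing) for a set
#' of loci across the cohort samples, together with the locus table and
#' the sample sheet.  Columns are always in sample-sheet order, so all
#' downstream computations are invariant to the sample order on disk.
#'
#' @param dosages Integer matrix, loci x samples, values in \{0,1,2,NA\}.
#' @param loci `data.frame` with columns `locus_id`, `chrom`, `pos`
#'   (1-based position as in VCF), `ref`, `alt`; one row per matrix row.
#' @param sheet A [sample_sheet()]; its `sample_id`s must equal the
#'   matrix column names (any order; columns are reordered to match).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `loci`, `sheet`.
#' @export
genotype_matrix <- function(dosages, loci, sheet) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  ok <- is.na(dosages) | dosages %in% 0:2
  if (!all(ok))
    stop("genotype_matrix: dosages must be 0, 1, 2 or NA", call. = FALSE)
  if (anyDuplicated(loci$locus_id))
    stop("genotype_matrix: locus ids must be unique", call. = FALSE)
  if (nrow(loci) != nrow(dosages))
    stop("genotype_matrix: locus table and dosage matrix disagree",
         call. = FALSE)
  if (is.null(colnames(dosages)))
    stop("genotype_matrix: dosage columns must be named by sample",
         call. = FALSE)
  if (!setequal(colnames(dosages), sheet$sample_id))
    stop("genotype_matrix: matrix samples do not match the sample sheet",
         call. = FALSE)
  dosages <- dosages[, sheet$sample_id, drop = FALSE]
  rownames(dosages) <- loci$locus_id
  structure(list(dosages = dosages, loci = loci, sheet = sheet),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d samples (%.1f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Expression matrix container
#'
#' Features (genes or miRNAs) by samples abundance matrix with
#' non-negative FPKM-like values, tied to the cohort sample sheet.
#' Columns are kept in sample-sheet order.
#'
#' @param values Numeric matrix, features x samples, finite and >= 0,
#'   with feature row names and sample column names.
#' @param sheet A [sample_sheet()].
#' @param kind `"gene"` or `"mirna"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `sheet`, `kind`.
#' @export
expression_matrix <- function(values, sheet, kind = c("gene", "mirna")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression_matrix: values must be finite and non-negative",
         call. = FALSE)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("expression_matrix: feature ids must be present and unique",
         call. = FALSE)
  if (!setequal(colnames(values), sheet$sample_id))
    stop("expression_matrix: samples do not match the sample sheet",
         call. = FALSE)
  values <- values[, sheet$sample_id, drop = FALSE]
  structure(list(values = values, sheet = sheet, kind = kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s): %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Number of features in an expression matrix
#' @param e An [expression_matrix()].
#' @return Integer count of features (rows).
#' @export
n_features <- function(e) nrow(e$values)
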