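#' Construct a sample sheet for a serial-passage cohort
#'
#' A sample sheet assigns every sequenced sample to a passage (generation)
#' and a replicate animal within that passage.  The study design modelled
#' throughout this package is five generations with three replicate mice
#' each, i.e. 15 samples, but any balanced design is accepted.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param generation Integer vector, the passage index of each sample
#'   (1-based; the canonical design uses 1..5).
#' @param replicate Integer vector, the replicate index within each
#'   generation (the canonical design uses 1..3).
#'
#' @return A `data.frame` of class `sample_sheet` with columns
#'   `sample_id`, `generation`, `replicate`, ordered by generation then
#'   replicate.
#' @export
#' @examples
#' sheet <- default_sample_sheet()
#' nrow(sheet)  # 15
sample_sheet <- function(sample_id, generation, replicate) {
  if (anyDuplicated(sample_id))
    stop("sample_sheet: sample ids must be unique", call. = FALSE)
  generation <- as.integer(generation)
  replicate <- as.integer(replicate)
  if (length(sample_id) != length(generation) ||
      length(sample_id) != length(replicate))
    stop("sample_sheet: column lengths differ", call. = FALSE)
  if (any(is.na(generation)) || any(generation < 1L))
    stop("sample_sheet: generation must be a positive integer", call. = FALSE)
  if (any(is.na(replicate)) || any(replicate < 1L))
    stop("sample_sheet: replicate must be a positive integer", call. = FALSE)
  reps_per_gen <- tapply(replicate, generation, length)
  if (length(unique(reps_per_gen)) > 1L)
    stop("sample_sheet: every generation must have the same replicate count",
         call. = FALSE)
  df <- data.frame(sample_id = as.character(sample_id),
                   generation = generation, replicate = replicate,
                   stringsAsFactors = FALSE)
  df <- df[order(df$generation, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname sample_sheet
#' @param n_generations,n_replicates Design dimensions for the default
#'   sheet; sample ids are `g<generation>_r<replicate>`.
#' @export
default_sample_sheet <- function(n_generations = 5L, n_replicates = 3L) {
  gen <- rep(seq_len(n_generations), each = n_replicates)
  rep_ <- rep(seq_len(n_replicates), times = n_generations)
  sample_sheet(sprintf("g%d_r%d", gen, rep_), gen, rep_)
}

#' Read a sample sheet from a TSV file
#'
#' Expects columns `sample_id`, `generation`, `replicate`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "generation", "replicate")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  sample_sheet(df$sample_id, df$generation, df$replicate)
}

#' Write a sample sheet to a TSV file
#'
#' @param sheet A [sample_sheet()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

generations_of <- function(sheet) sort(unique(sheet$generation))

#' @export
print.sample_sheet <- function(x, ...) {
  cat(sprintf("sample_sheet: %d samples, %d generations x %d replicates\n",
              nrow(x), length(unique(x$generation)),
              length(unique(x$replicate))))
  print(as.data.frame(x), ...)
  invisible(x)
}
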