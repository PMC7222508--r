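#' Tumor volume from caliper measurements
#'
#' The standard ellipsoid approximation used for subcutaneous xenografts:
#' volume = length x width^2 / 2, in mm^3 for mm inputs.
#'
#' @param length_mm,width_mm Caliper length and width in mm (vectorized).
#'   Convention is length >= width; if width exceeds length a warning is
#'   issued and the volume computed anyway.
#' @param warn Emit the width-greater-than-length warning (default TRUE).
#' @return Numeric vector of volumes in mm^3.
#' @export
#' @examples
#' tumor_volume(10, 10)  # 500
tumor_volume <- function(length_mm, width_mm, warn = TRUE) {
  if (any(length_mm < 0, na.rm = TRUE) || any(width_mm < 0, na.rm = TRUE))
    stop("tumor_volume: negative caliper measurement", call. = FALSE)
  if (warn && any(width_mm > length_mm, na.rm = TRUE))
    warning("tumor_volume: width > length; computing anyway", call. = FALSE)
  length_mm * width_mm^2 / 2
}

#' Treatment/vehicle comparison at a given day
#'
#' Bundles the four group-mean volumes entering the efficacy formulas:
#' treatment at baseline (`tt0`) and at day `day` (`tti`), vehicle at
#' baseline (`vc0`) and at day `day` (`vci`).
#'
#' @param tt0,tti,vc0,vci Group-mean volumes in mm^3 (all >= 0).
#' @param day Integer day since treatment start (>= 0).
#' @return A list of class `treatment_comparison`.
#' @export
treatment_comparison <- function(tt0, tti, vc0, vci, day = NA_integer_) {
  vols <- c(tt0 = tt0, tti = tti, vc0 = vc0, vci = vci)
  if (any(!is.finite(vols)) || any(vols < 0))
    stop("treatment_comparison: volumes must be finite and >= 0",
         call. = FALSE)
  structure(list(tt0 = tt0, tti = tti, vc0 = vc0, vci = vci,
                 day = as.integer(day)),
            class = "treatment_comparison")
}

#' T/C and tumor growth inhibition (TGI)
#'
#' T/C (%) = (Tti - Tt0) / (Vci - Vc0) x 100 compares treatment-group
#' growth with vehicle-group growth; TGI (%) = \[1 - (Tti - Tt0) /
#' (Vci - Vc0)\] x 100 is its complement, so T/C + TGI = 100 identically.
#' TGI may be negative when the treated tumors grow faster than vehicle.
#'
#' @param comparison A [treatment_comparison()].
#' @return A list of class `efficacy_result` with elements
#'   `t_over_c_percent` and `tgi_percent`.
#' @export
#' @examples
#' efficacy(treatment_comparison(200, 200, 200, 700))  # TGI 100
efficacy <- function(comparison) {
  stopifnot(inherits(comparison, "treatment_comparison"))
  dv <- comparison$vci - comparison$vc0
  if (dv == 0)
    stop("efficacy: vehicle group did not grow (Vci == Vc0); ",
         "T/C denominator undefined", call. = FALSE)
  tc <- (comparison$tti - comparison$tt0) / dv * 100
  structure(list(t_over_c_percent = tc, tgi_percent = 100 - tc,
                 day = comparison$day),
            class = "efficacy_result")
}

#' Group mean, SD and n of tumor volume at a day
#'
#' @param records Growth `data.frame` (see [read_growth_csv()]).
#' @param group `"treatment"` or `"vehicle"`.
#' @param day Measurement day.
#' @param passage Passage to restrict to (default: all rows).
#' @return A list with `mean`, `sd` (sample SD, n-1 denominator; 0 with a
#'   `single_animal` flag when n = 1), and `n`.
#' @export
group_summary <- function(records, group, day, passage = NULL) {
  keep <- records$group == group & records$day == day
  if (!is.null(passage)) keep <- keep & records$passage == passage
  v <- records$volume_mm3[keep]
  if (!length(v))
    stop(sprintf("no growth records for group '%s' at day %s", group, day),
         call. = FALSE)
  list(mean = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else 0,
       n = length(v),
       single_animal = length(v) == 1L)
}

#' Responsive/resistant call from TGI
#'
#' A passage is called responsive when TGI meets or exceeds the
#' threshold (default 30%, a conventional efficacy cut-off), otherwise
#' resistant.
#'
#' @param eff An [efficacy_result][efficacy] or a numeric TGI percent.
#' @param threshold_percent Responsiveness threshold on TGI (default 30).
#' @return `"responsive"` or `"resistant"`.
#' @export
resistance_call <- function(eff, threshold_percent = 30) {
  tgi <- if (inherits(eff, "efficacy_result")) eff$tgi_percent else eff
  if (tgi >= threshold_percent) "responsive" else "resistant"
}

#' Per-passage efficacy table from growth records
#'
#' For each passage, takes the group means at the baseline day and at the
#' last measured day (or a given day), computes T/C and TGI, and calls
#' the passage responsive or resistant.
#'
#' @param records Growth `data.frame` (see [read_growth_csv()]).
#' @param baseline_day Day of the treatment start (default: earliest day
#'   present within each passage).
#' @param day Endpoint day (default: latest day present within each
#'   passage).
#' @param threshold_percent Passed to [resistance_call()].
#' @return A `data.frame` with one row per passage: group means at
#'   baseline and endpoint, `t_over_c_percent`, `tgi_percent`, `call`.
#' @export
passage_efficacy <- function(records, baseline_day = NULL, day = NULL,
                             threshold_percent = 30) {
  out <- lapply(sort(unique(records$passage)), function(p) {
    rec <- records[records$passage == p, , drop = FALSE]
    d0 <- if (is.null(baseline_day)) min(rec$day) else baseline_day
    d1 <- if (is.null(day)) max(rec$day) else day
    tt0 <- group_summary(rec, "treatment", d0)$mean
    tti <- group_summary(rec, "treatment", d1)
    vc0 <- group_summary(rec, "vehicle", d0)$mean
    vci <- group_summary(rec, "vehicle", d1)
    eff <- efficacy(treatment_comparison(tt0, tti$mean, vc0, vci$mean, d1))
    data.frame(passage = p, baseline_day = d0, day = d1,
               treatment_mean = tti$mean, treatment_sd = tti$sd,
               vehicle_mean = vci$mean, vehicle_sd = vci$sd,
               t_over_c_percent = eff$t_over_c_percent,
               tgi_percent = eff$tgi_percent,
               call = resistance_call(eff, threshold_percent),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
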