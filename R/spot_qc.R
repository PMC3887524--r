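#' Evaluate the three spot-quality criteria
#'
#' A spot is retained when all three criteria hold:
#' \enumerate{
#'   \item at least 70% of its foreground pixels exceed the background
#'     median + 2 background SDs, in at least one channel;
#'   \item the foreground median is at least three times the background
#'     median, in at least one channel;
#'   \item the spot has more than 30 foreground pixels (strict), evaluated
#'     on both channels' pixel counts.
#' }
#' The 70% and three-fold thresholds are inclusive; a zero background
#' median with positive foreground passes criterion 2 (infinite ratio).
#'
#' @param spots a spot data.frame (see [spot_columns()]) or a
#'   `"hybridization"`.
#' @return data.frame with logical columns `crit1_ch1`, `crit1_ch2`,
#'   `crit2_ch1`, `crit2_ch2`, `crit3`, `passed`, one row per spot.
#' @export
evaluate_spot_qc <- function(spots) {
  if (inherits(spots, "hybridization")) spots <- spots$spots
  num <- spots[, setdiff(spot_columns(), "probe_id")]
  if (any(vapply(num, function(v) any(v < 0, na.rm = TRUE), logical(1)))) {
    stop_data("negative values in spot summary fields")
  }
  d <- data.frame(
    crit1_ch1 = spots$frac_fg_gt_bg2sd_ch1 >= 0.70,
    crit1_ch2 = spots$frac_fg_gt_bg2sd_ch2 >= 0.70,
    crit2_ch1 = spots$fg_median_ch1 >= 3 * spots$bg_median_ch1,
    crit2_ch2 = spots$fg_median_ch2 >= 3 * spots$bg_median_ch2,
    crit3 = pmin(spots$fg_pixels_ch1, spots$fg_pixels_ch2) > 30
  )
  d$passed <- (d$crit1_ch1 | d$crit1_ch2) &
    (d$crit2_ch1 | d$crit2_ch2) & d$crit3
  d
}

#' Filter a hybridization to QC-passing spots
#'
#' Applies [evaluate_spot_qc()] and keeps only passing spots, preserving
#' spot order. The report counts, per criterion, how many spots failed it.
#'
#' @param hyb a `"hybridization"`.
#' @return list with `hyb` (filtered hybridization; `NULL` spots slot kept
#'   as an empty data.frame when nothing passes) and `report` (named list:
#'   `array_id`, `n_in`, `n_passed`, `fail_crit1`, `fail_crit2`,
#'   `fail_crit3`, `warning`).
#' @export
filter_hybridization <- function(hyb) {
  stopifnot(inherits(hyb, "hybridization"))
  d <- evaluate_spot_qc(hyb$spots)
  report <- list(
    array_id = hyb$array_id,
    n_in = nrow(hyb$spots),
    n_passed = sum(d$passed),
    fail_crit1 = sum(!(d$crit1_ch1 | d$crit1_ch2)),
    fail_crit2 = sum(!(d$crit2_ch1 | d$crit2_ch2)),
    fail_crit3 = sum(!d$crit3),
    warning = NA_character_
  )
  out <- hyb
  out$spots <- hyb$spots[d$passed, , drop = FALSE]
  if (report$n_passed == 0L) {
    report$warning <- "no spots passed QC"
    warning("array ", hyb$array_id, ": no spots passed QC")
  }
  list(hyb = out, report = report)
}

#' Tabulate QC reports across arrays
#' @param reports list of reports from [filter_hybridization()].
#' @return data.frame, one row per array.
#' @export
qc_report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(array_id = r$array_id, n_in = r$n_in, n_passed = r$n_passed,
               fail_crit1 = r$fail_crit1, fail_crit2 = r$fail_crit2,
               fail_crit3 = r$fail_crit3, stringsAsFactors = FALSE)
  }))
}
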