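#' Compute per-spot M and A values
#'
#' M = log2(foreground median channel 1 / channel 2), A = mean of the two
#' log2 foreground medians. No background subtraction is applied (see the
#' methods vignette); background enters QC only. Spots with a nonpositive
#' foreground median in either channel are dropped and counted.
#'
#' @param hyb a QC-filtered `"hybridization"`.
#' @return data.frame with `probe_id`, `M`, `A`, `x`, `y`; the number of
#'   dropped spots is attached as attribute `n_dropped`.
#' @export
compute_ma <- function(hyb) {
  stopifnot(inherits(hyb, "hybridization"))
  s <- hyb$spots
  ok <- s$fg_median_ch1 > 0 & s$fg_median_ch2 > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(hyb$array_id, ": dropped ", n_dropped,
            " spot(s) with nonpositive foreground before MA computation")
  }
  s <- s[ok, , drop = FALSE]
  out <- data.frame(
    probe_id = s$probe_id,
    M = log2(s$fg_median_ch1) - log2(s$fg_median_ch2),
    A = (log2(s$fg_median_ch1) + log2(s$fg_median_ch2)) / 2,
    x = s$x, y = s$y,
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

loess_fit_safe <- function(formula, data, span) {
  # symmetric (robust) first; a perfect first-pass fit makes the robustness
  # weights degenerate (0/0), in which case the plain least-squares fit is
  # already exact
  tryCatch(
    stats::loess(formula, data = data, span = span, degree = 1,
                 family = "symmetric", normalize = FALSE,
                 control = stats::loess.control(surface = "interpolate")),
    error = function(e) {
      stats::loess(formula, data = data, span = span, degree = 1,
                   family = "gaussian", normalize = FALSE,
                   control = stats::loess.control(surface = "interpolate"))
    }
  )
}

# Residuals of a smoother shrink true per-spot deviations by the per-point
# leverage; dividing by the average leverage complement (1 - enp/n) restores
# first-order unbiasedness of spot-level signal (analogous to standardized
# residuals r / (1 - h)).
loess_residuals <- function(fit, n, bias_correct) {
  r <- as.numeric(stats::residuals(fit))
  if (bias_correct) {
    shrink <- max(0.1, 1 - fit$enp / n)
    r <- r / shrink
  }
  r
}

#' Intensity-dependent loess normalization
#'
#' Removes the smooth dependence of M on A by replacing M with the
#' residual M - g(A), where g is a local-linear loess fit (tricube
#' weights, robust iterations) with the given span.
#'
#' @param points MA data.frame from [compute_ma()].
#' @param span loess span, fraction of points per local fit (default 0.3).
#' @param bias_correct divide residuals by (1 - enp/n), the average
#'   leverage complement, so spot-level signal is not shrunk by the
#'   smoother (default `TRUE`).
#' @return the input with `M` replaced by the residual.
#' @export
intensity_normalize <- function(points, span = 0.3, bias_correct = TRUE) {
  if (!(span > 0 && span <= 1)) stop_data("span must lie in (0, 1]")
  if (nrow(points) < 10) stop_data("need at least 10 points to normalize")
  fit <- loess_fit_safe(M ~ A, points, span)
  points$M <- loess_residuals(fit, nrow(points), bias_correct)
  points
}

#' Spatial loess normalization
#'
#' Removes smooth spatial variation by replacing M with the residual of a
#' two-dimensional local-linear regression surface over the slide
#' coordinates. The span is the fraction of spots in each local
#' neighborhood; the default 0.002 corresponds to ~43 spots on a
#' 21,487-spot array. If span*n < 10 the span is widened to 10/n with a
#' warning.
#'
#' @param points MA data.frame from [compute_ma()] (normally already
#'   intensity-normalized; the pipeline applies intensity then spatial).
#' @param span neighborhood fraction (default 0.002).
#' @param bias_correct see [intensity_normalize()]; with small spans the
#'   leverage correction matters (enp/n is ~8% at span 0.002).
#' @return the input with `M` replaced by the residual.
#' @export
spatial_normalize <- function(points, span = 0.002, bias_correct = TRUE) {
  if (!(span > 0 && span <= 1)) stop_data("span must lie in (0, 1]")
  n <- nrow(points)
  if (stats::sd(points$x) == 0 && stats::sd(points$y) == 0) {
    stop_data("degenerate coordinates: all spots at one location")
  }
  if (span * n < 10) {
    span <- min(1, 10 / n)
    warning("spatial span widened to ", signif(span, 3),
            " to keep >= 10 neighbors")
  }
  # guard single-valued axes: loess needs variation in each predictor used
  form <- if (stats::sd(points$x) == 0) M ~ y
          else if (stats::sd(points$y) == 0) M ~ x
          else M ~ x + y
  fit <- loess_fit_safe(form, points, span)
  points$M <- loess_residuals(fit, nrow(points), bias_correct)
  points
}

#' Two-pass normalization of one hybridization
#'
#' QC-filtered spots are turned into MA values, then intensity-normalized
#' (span `intensity_span`), then spatially normalized (span
#' `spatial_span`) — in that fixed order.
#'
#' @param hyb a QC-filtered `"hybridization"`.
#' @param intensity_span,spatial_span loess spans for the two passes.
#' @return normalized MA data.frame.
#' @export
normalize_hybridization <- function(hyb, intensity_span = 0.3,
                                    spatial_span = 0.002) {
  ma <- compute_ma(hyb)
  ma <- intensity_normalize(ma, span = intensity_span)
  spatial_normalize(ma, span = spatial_span)
}
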