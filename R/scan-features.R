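# Characteristic-angle extraction from SPR angle scans. The TIR edge is
# located at the maximum of the first derivative of reflectivity with respect
# to angle, refined by a local quadratic fit of the derivative; the plasmon
# coupling angle is the reflectivity minimum, refined by a local quadratic
# fit. Both refinements resolve well below the angle grid spacing.

# Fit a parabola y ~ a + b x + c x^2 to (x, y) and return the vertex and a
# rough vertex standard error from the fit covariance; NULL if degenerate.
# The predictor is centered before fitting: x and x^2 are near-collinear on
# the narrow angle ranges involved.
.quad_vertex <- function(x, y, maximum = FALSE) {
  if (length(x) < 3) return(NULL)
  x0 <- mean(x)
  xc <- x - x0
  fit <- lm(y ~ xc + I(xc^2))
  cf <- coef(fit)
  c2 <- cf[[3]]
  if (!is.finite(c2) || (maximum && c2 >= 0) || (!maximum && c2 <= 0)) {
    return(NULL)
  }
  v <- x0 - cf[[2]] / (2 * c2)
  se <- tryCatch({
    V <- suppressWarnings(stats::vcov(fit))
    g <- c(0, -1 / (2 * c2), cf[[2]] / (2 * c2^2))
    sqrt(drop(t(g) %*% V %*% g))
  }, error = function(e) NA_real_)
  list(vertex = v, se = se)
}

#' Locate the total-internal-reflection edge of a scan
#'
#' The TIR edge is the angle of maximum positive slope of reflectivity versus
#' angle within the search window. The finite-difference derivative is
#' computed on the grid midpoints and a quadratic is fitted to the derivative
#' within `refine_halfwidth` of its maximum; the parabola vertex is returned.
#'
#' @param scan An [angle_scan()].
#' @param window Angle window (degrees) searched for the edge.
#' @param refine_halfwidth Half-width (degrees) of the local quadratic
#'   refinement of the derivative peak. The default (1.5 grid spacings, i.e.
#'   the peak sample and its two neighbours) keeps the refinement local: the
#'   derivative peak at a TIR kink is essentially one bin wide and wider fits
#'   are biased by the peak's asymmetry.
#' @return The edge angle in degrees, with attribute `uncertainty_deg`.
#' @export
find_tir_edge <- function(scan, window = c(48, 52), refine_halfwidth = NULL) {
  stopifnot(inherits(scan, "angle_scan"))
  sel <- scan$angle_deg >= window[1] & scan$angle_deg <= window[2]
  if (sum(sel) < 5) {
    abort("TIR window must span at least 5 scan points.",
          class = "sprgamma_feature_error")
  }
  a <- scan$angle_deg[sel]
  r <- scan$reflectivity[sel]
  mid <- (a[-1] + a[-length(a)]) / 2
  dr <- diff(r) / diff(a)
  if (max(dr) <= 0) {
    abort("No positive-slope edge found in the TIR window.",
          class = "sprgamma_feature_error")
  }
  i0 <- which.max(dr)
  refine_halfwidth <- refine_halfwidth %||% (1.5 * stats::median(diff(a)))
  near <- abs(mid - mid[i0]) <= refine_halfwidth
  qv <- .quad_vertex(mid[near], dr[near], maximum = TRUE)
  spacing <- stats::median(diff(a))
  if (is.null(qv) || qv$vertex < min(mid[near]) || qv$vertex > max(mid[near])) {
    # refinement degenerate: fall back to the raw derivative maximum
    return(structure(mid[i0], uncertainty_deg = spacing))
  }
  structure(qv$vertex,
            uncertainty_deg = max(qv$se, spacing / 10, na.rm = TRUE))
}

#' Locate the plasmon-coupling (SPR) minimum of a scan
#'
#' The reflectivity minimum within the window, refined by a quadratic fit
#' through the minimum sample and its neighbourhood: all contiguous samples
#' whose reflectivity lies within `depth_fraction` of the dip depth above the
#' minimum. Near its bottom an SPR dip is shallow compared with realistic
#' reflectivity noise, so fitting this extended neighbourhood (rather than
#' only the three samples around the minimum) is what makes the sub-grid
#' location stable. If several grid points tie for the minimum, the smallest
#' angle is taken and the reported uncertainty is inflated to the span of
#' the tie.
#'
#' @inheritParams find_tir_edge
#' @param window Angle window (degrees) that must contain the minimum away
#'   from its boundaries.
#' @param depth_fraction Fraction of the dip depth (window maximum minus
#'   minimum) defining the neighbourhood fitted by the quadratic.
#' @return The minimum angle in degrees, with attribute `uncertainty_deg`.
#' @export
find_spr_minimum <- function(scan, window = c(60, 66), depth_fraction = 0.3) {
  stopifnot(inherits(scan, "angle_scan"))
  sel <- scan$angle_deg >= window[1] & scan$angle_deg <= window[2]
  if (sum(sel) < 5) {
    abort("SPR window must span at least 5 scan points.",
          class = "sprgamma_feature_error")
  }
  a <- scan$angle_deg[sel]
  r <- scan$reflectivity[sel]
  ties <- which(r == min(r))
  i0 <- ties[1]
  tie_span <- if (length(ties) > 1) diff(range(a[ties])) else 0
  if (i0 == 1 || ties[length(ties)] == length(a)) {
    abort("Reflectivity minimum sits on the SPR window boundary.",
          class = "sprgamma_feature_error")
  }
  # all samples within depth_fraction of the dip depth above the minimum;
  # the dip is unimodal, so these form its bottom neighbourhood. The set is
  # chosen on a lightly smoothed curve so that membership does not correlate
  # with the noise of individual samples (which would bias the vertex); the
  # quadratic is then fitted to the raw samples of that set.
  k <- min(7L, length(r) - (1 - length(r) %% 2))
  rs <- as.numeric(stats::filter(r, rep(1 / k, k), sides = 2))
  rs[is.na(rs)] <- r[is.na(rs)]
  thr <- min(rs) + depth_fraction * (max(rs) - min(rs))
  near <- which(rs <= thr)
  if (length(near) < 3) near <- max(1, i0 - 1):min(length(r), i0 + 1)
  qv <- .quad_vertex(a[near], r[near], maximum = FALSE)
  spacing <- stats::median(diff(a))
  if (is.null(qv) || qv$vertex < a[1] || qv$vertex > a[length(a)]) {
    return(structure(a[i0], uncertainty_deg = max(spacing, tie_span)))
  }
  structure(qv$vertex,
            uncertainty_deg = max(qv$se, spacing / 10, tie_span, na.rm = TRUE))
}

#' Extract both characteristic angles of a scan
#'
#' @inheritParams find_tir_edge
#' @param tir_window,spr_window Search windows (degrees) for the TIR edge and
#'   the SPR minimum. The defaults bracket the edge near 49-50 deg and the
#'   resonance near 62-63 deg of the calibrated default chip.
#' @return One-row tibble of class `scan_features` with columns `theta_tir`,
#'   `theta_spr`, `theta_tir_uncertainty`, `theta_spr_uncertainty` (degrees).
#' @export
scan_features <- function(scan, tir_window = c(48, 52), spr_window = c(60, 66)) {
  tir <- find_tir_edge(scan, window = tir_window)
  spr <- find_spr_minimum(scan, window = spr_window)
  out <- tibble(
    theta_tir = as.numeric(tir),
    theta_spr = as.numeric(spr),
    theta_tir_uncertainty = attr(tir, "uncertainty_deg"),
    theta_spr_uncertainty = attr(spr, "uncertainty_deg"))
  if (out$theta_tir >= out$theta_spr) {
    warn("theta_TIR >= theta_SPR: scan is not a valid Kretschmann scan.")
  }
  class(out) <- c("scan_features", class(out))
  out
}

#' Calibrate the effective prism permittivity from a reference liquid
#'
#' Inverts the analytic TIR relation using a reference scan of a liquid with
#' known bulk permittivity: `eps_prism = eps_bulk_known / sin^2(theta_TIR)`.
#' This one-parameter calibration absorbs the unknown instrument-to-internal
#' angle mapping.
#'
#' @param reference_scan An [angle_scan()] of the reference liquid.
#' @param eps_bulk_known Literature bulk permittivity of the reference liquid
#'   (e.g. 1.8507 for ethanol at room temperature).
#' @param tir_window Search window passed to [find_tir_edge()].
#' @return The effective prism permittivity (dimensionless).
#' @export
calibrate_prism <- function(reference_scan, eps_bulk_known,
                            tir_window = c(48, 52)) {
  if (!is.numeric(eps_bulk_known) || eps_bulk_known <= 0) {
    abort("`eps_bulk_known` must be positive.", class = "sprgamma_domain_error")
  }
  edge <- find_tir_edge(reference_scan, window = tir_window)
  eps_bulk_known / sin(as.numeric(edge) * pi / 180)^2
}
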