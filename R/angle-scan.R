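#' Construct an angle scan
#'
#' A reflectivity-versus-angle record: a tibble with columns `angle_deg`
#' (strictly increasing internal angles) and `reflectivity`. Metadata (sample
#' label, temperature, provenance) travels in the `metadata` attribute.
#'
#' @param angle_deg Strictly increasing angles in degrees, at least 10 points.
#' @param reflectivity Dimensionless reflectivities; values may stray slightly
#'   outside \[0, 1\] (up to -0.05/1.05) to accommodate raw measured data prior
#'   to normalization.
#' @param sample Sample label.
#' @param temperature_c Sample temperature in degrees Celsius.
#' @param source `"measured"` or `"synthetic"`.
#' @param metadata Optional named list merged into the metadata attribute
#'   (e.g. seed, generating truth).
#' @return A tibble of class `angle_scan`.
#' @export
angle_scan <- function(angle_deg, reflectivity, sample = "scan",
                       temperature_c = NA_real_, source = "measured",
                       metadata = list()) {
  if (length(angle_deg) < 10) {
    abort("An angle scan needs at least 10 points.",
          class = "sprgamma_format_error")
  }
  if (length(reflectivity) != length(angle_deg)) {
    abort("`angle_deg` and `reflectivity` must have equal length.",
          class = "sprgamma_format_error")
  }
  if (is.unsorted(angle_deg, strictly = TRUE)) {
    abort("Angles must be strictly increasing.",
          class = "sprgamma_format_error")
  }
  if (any(!is.finite(reflectivity)) ||
      any(reflectivity < -0.05) || any(reflectivity > 1.05)) {
    abort("Reflectivity must be finite and within [-0.05, 1.05].",
          class = "sprgamma_format_error")
  }
  source <- match.arg(source, c("measured", "synthetic"))
  meta <- c(list(sample = sample, temperature_c = temperature_c,
                 source = source), metadata)
  new_tibble(
    tibble(angle_deg = as.numeric(angle_deg),
           reflectivity = as.numeric(reflectivity)),
    metadata = meta, class = "angle_scan", nrow = length(angle_deg))
}

#' Scan metadata
#' @param scan An [angle_scan()].
#' @return The metadata list.
#' @export
scan_metadata <- function(scan) attr(scan, "metadata")

#' Normalize a measured scan to its pre-edge plateau
#'
#' Raw SPR intensities come in arbitrary units; this rescales the scan so
#' that the mean reflectivity over the plateau below the TIR edge is 1. The
#' same convention must be applied to model curves when fitting normalized
#' data. Synthetic scans from [simulate_scan()] are already on an absolute
#' scale and normally need no normalization.
#'
#' @param scan An [angle_scan()].
#' @param plateau_window Angle window (degrees) defining the pre-edge plateau.
#' @return A rescaled [angle_scan()].
#' @export
normalize_scan <- function(scan, plateau_window = c(45, 48)) {
  stopifnot(inherits(scan, "angle_scan"))
  sel <- scan$angle_deg >= plateau_window[1] & scan$angle_deg <= plateau_window[2]
  if (sum(sel) < 3) {
    abort("Plateau window contains fewer than 3 points.",
          class = "sprgamma_domain_error")
  }
  s <- mean(scan$reflectivity[sel])
  if (s <= 0) {
    abort("Plateau mean is non-positive; cannot normalize.",
          class = "sprgamma_domain_error")
  }
  meta <- scan_metadata(scan)
  angle_scan(scan$angle_deg, pmin(pmax(scan$reflectivity / s, -0.05), 1.05),
             sample = meta$sample, temperature_c = meta$temperature_c,
             source = meta$source,
             metadata = c(meta[setdiff(names(meta),
                                       c("sample", "temperature_c", "source"))],
                          list(normalized = TRUE)))
}
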