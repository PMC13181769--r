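# Analysis of species-resolved density profiles of a solution film against a
# wall: histogram binning of particle frames, film width by the solvent
# density criterion, window averages, and the profile-based surface excess.
# Distances are measured from the wall in nm; densities are in g/cm^3.

#' Construct a density profile
#'
#' A long-format tibble with columns `z_nm` (bin centers on a uniform grid
#' starting at `bin_width/2`), `species` and `density_g_cm3`, with the bin
#' width, cross-sectional area and number of averaged frames carried as
#' attributes.
#'
#' @param data Data frame with columns `z_nm`, `species`, `density_g_cm3`.
#' @param bin_width_nm Uniform bin width in nm (0.05 by default).
#' @param area_nm2 Cross-sectional area in nm^2 (may be `NA` for analytic
#'   profiles).
#' @param frames Number of frames averaged.
#' @return A tibble of class `density_profile`.
#' @export
density_profile <- function(data, bin_width_nm = 0.05, area_nm2 = NA_real_,
                            frames = 1L) {
  data <- as_tibble(data)
  stopifnot(all(c("z_nm", "species", "density_g_cm3") %in% names(data)))
  if (any(data$density_g_cm3 < 0)) {
    abort("Densities must be >= 0.", class = "sprgamma_domain_error")
  }
  for (sp in unique(data$species)) {
    z <- sort(data$z_nm[data$species == sp])
    if (length(z) > 1 &&
        max(abs(diff(z) - bin_width_nm)) > 1e-9 * max(1, bin_width_nm)) {
      abort("Bin centers must lie on a uniform grid of width `bin_width_nm`.",
            class = "sprgamma_format_error")
    }
  }
  new_tibble(data[order(data$species, data$z_nm), ],
             bin_width_nm = bin_width_nm, area_nm2 = area_nm2,
             frames = frames, class = "density_profile", nrow = nrow(data))
}

#' Bin particle frames into a species-resolved mass density profile
#'
#' Per-species mass histogram along the wall normal, divided by the bin
#' volume (area x bin width) and averaged over frames, in g/cm^3. Particle
#' positions are taken as molecular centers (one row per molecule) with the
#' molecular mass in g/mol.
#'
#' @param frames Data frame with columns `z_nm` (>= 0), `species`,
#'   `mass_g_mol` and optionally `frame` (integer; a single frame is assumed
#'   if absent).
#' @param area_nm2 Cross-sectional area of the simulation cell in nm^2.
#' @param bin_width_nm Bin width in nm; the default 0.05 nm matches the
#'   resolution the profiles are reported at.
#' @param z_max_nm Extent of the binned region; defaults to the smallest
#'   multiple of the bin width covering all particles.
#' @param frame_range Optional `c(first, last)` selector restricting which
#'   frames enter the average.
#' @return A [density_profile()].
#' @export
bin_density_profile <- function(frames, area_nm2, bin_width_nm = 0.05,
                                z_max_nm = NULL, frame_range = NULL) {
  frames <- as_tibble(frames)
  stopifnot(all(c("z_nm", "species", "mass_g_mol") %in% names(frames)))
  if (!"frame" %in% names(frames)) frames$frame <- 1L
  if (!is.null(frame_range)) {
    frames <- frames[frames$frame >= frame_range[1] &
                     frames$frame <= frame_range[2], , drop = FALSE]
  }
  if (nrow(frames) == 0) {
    abort("No particles to bin.", class = "sprgamma_domain_error")
  }
  if (any(frames$z_nm < 0)) {
    abort("Wall distances must be >= 0.", class = "sprgamma_domain_error")
  }
  if (!is.numeric(area_nm2) || length(area_nm2) != 1 || area_nm2 <= 0) {
    abort("`area_nm2` must be a single positive number.",
          class = "sprgamma_domain_error")
  }
  n_frames <- length(unique(frames$frame))
  z_max_nm <- z_max_nm %||% (ceiling(max(frames$z_nm) / bin_width_nm) *
                               bin_width_nm)
  n_bins <- max(1L, as.integer(round(z_max_nm / bin_width_nm)))
  edges <- seq(0, n_bins * bin_width_nm, by = bin_width_nm)
  centers <- edges[-1] - bin_width_nm / 2
  vol_cm3 <- area_nm2 * bin_width_nm * 1e-21
  out <- map(sort(unique(frames$species)), function(sp) {
    sub <- frames[frames$species == sp, ]
    idx <- pmin(pmax(findInterval(sub$z_nm, edges, left.open = FALSE,
                                  rightmost.closed = TRUE), 1L), n_bins)
    mass <- vapply(seq_len(n_bins), function(i) sum(sub$mass_g_mol[idx == i]),
                   numeric(1))
    tibble(z_nm = centers, species = sp,
           density_g_cm3 = mass / .AVOGADRO / n_frames / vol_cm3)
  })
  density_profile(bind_rows(out), bin_width_nm = bin_width_nm,
                  area_nm2 = area_nm2, frames = n_frames)
}

.species_profile <- function(profile, species) {
  sub <- profile[profile$species == species, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(paste0("Species `", species, "` not present in profile."),
          class = "sprgamma_domain_error")
  }
  sub[order(sub$z_nm), ]
}

#' Film width from the solvent density criterion
#'
#' The film extends to the distance at which the solvent density first falls
#' below `solvent_threshold` (0.1 g/cm^3 by default), scanning outward from
#' the last bin in which the solvent exceeds half of its maximum (the bulk/2
#' guard prevents near-wall depletion dips from being mistaken for the film
#' edge). The crossing is located by linear interpolation between bins.
#'
#' @param profile A [density_profile()].
#' @param species Name of the solvent species in the profile.
#' @param solvent_threshold Edge criterion in g/cm^3.
#' @return Film width in nm. Degenerate cases carry a `flag` attribute:
#'   `"no_edge"` when the solvent never falls below the threshold (the full
#'   profile extent is returned) and `"threshold_above_bulk"` when the
#'   threshold exceeds the solvent plateau (width 0).
#' @export
film_width <- function(profile, species = "solvent", solvent_threshold = 0.1) {
  stopifnot(inherits(profile, "density_profile"))
  sub <- .species_profile(profile, species)
  z <- sub$z_nm
  d <- sub$density_g_cm3
  bw <- attr(profile, "bin_width_nm")
  if (max(d) == 0) return(0)
  guard <- max(d) / 2
  if (guard < solvent_threshold) {
    return(structure(0, flag = "threshold_above_bulk"))
  }
  start <- max(which(d > guard))
  beyond <- which(d < solvent_threshold & seq_along(d) > start)
  if (length(beyond) == 0) {
    return(structure(z[length(z)] + bw / 2, flag = "no_edge"))
  }
  j <- beyond[1]
  # linear interpolation of the crossing between bins j-1 and j
  z0 <- z[j - 1] + (d[j - 1] - solvent_threshold) / (d[j - 1] - d[j]) *
    (z[j] - z[j - 1])
  z0
}

#' Window average of a species density
#'
#' Volume-weighted mean of the species density over `window`, with bins that
#' only partly overlap the window weighted by their overlap.
#'
#' @param profile A [density_profile()].
#' @param species Species name.
#' @param window `c(lower, upper)` in nm from the wall; the default 0-1 nm is
#'   the interfacial region the pipeline reports.
#' @return Mean density in g/cm^3.
#' @export
interfacial_average <- function(profile, species = "solute",
                                window = c(0, 1)) {
  stopifnot(inherits(profile, "density_profile"))
  sub <- .species_profile(profile, species)
  bw <- attr(profile, "bin_width_nm")
  lo <- sub$z_nm - bw / 2
  hi <- sub$z_nm + bw / 2
  if (window[1] < min(lo) - 1e-9 || window[2] > max(hi) + 1e-9 ||
      window[2] <= window[1]) {
    abort("Averaging window lies outside the profile extent.",
          class = "sprgamma_domain_error")
  }
  w <- pmax(0, pmin(hi, window[2]) - pmax(lo, window[1]))
  sum(w * sub$density_g_cm3) / sum(w)
}

#' Profile-based surface excess
#'
#' Integrates the species density above its bulk value from the wall to the
#' start of the bulk region: \eqn{\int_0^{z_1} (\rho(z) - \rho_{bulk})\,dz},
#' with \eqn{\rho_{bulk}} the mean over `bulk_region = c(z1, z2)`. This is
#' the density-profile counterpart of the SPR-derived excess interfacial
#' mass density.
#'
#' @param profile A [density_profile()].
#' @param species Species name.
#' @param bulk_region `c(z1, z2)` in nm: a window inside the film, past the
#'   interfacial peaks, whose mean defines the bulk density.
#' @return Surface excess in ng/cm^2.
#' @export
profile_surface_excess <- function(profile, species = "solute",
                                   bulk_region) {
  stopifnot(inherits(profile, "density_profile"))
  sub <- .species_profile(profile, species)
  bw <- attr(profile, "bin_width_nm")
  extent <- max(sub$z_nm) + bw / 2
  if (bulk_region[1] < 0 || bulk_region[2] > extent + 1e-9 ||
      bulk_region[2] <= bulk_region[1]) {
    abort("Bulk region lies outside the profile extent.",
          class = "sprgamma_domain_error")
  }
  rho_bulk <- interfacial_average(profile, species = species,
                                  window = bulk_region)
  lo <- sub$z_nm - bw / 2
  hi <- sub$z_nm + bw / 2
  w <- pmax(0, pmin(hi, bulk_region[1]) - pmax(lo, 0))
  integral <- sum(w * (sub$density_g_cm3 - rho_bulk))  # (g/cm^3) nm
  integral * .NG_CM2_PER_GCM3_NM
}
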