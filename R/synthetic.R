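# Seeded generators for every input the pipeline consumes: sensor chips with
# chip-to-chip variation, index-matched angle-scan pairs with reflectivity
# noise, and wall-enriched density profiles (analytic or realized as
# particles). Everything is bitwise-reproducible from (parameters, seed), and
# generation does not disturb the caller's RNG stream.

# Run `code` under a private RNG seeded with `seed`, restoring the caller's
# RNG state afterwards.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic sensor chip
#'
#' Draws a chip-specific metal film (thickness and a small permittivity
#' jitter around the calibrated defaults) and, for polystyrene-coated chips,
#' a thin polymer coat, emulating chip-to-chip variation of real sensor
#' chips. Identical seeds give identical chips.
#'
#' @param seed Integer seed.
#' @param surface `"gold"` (bare metal) or `"polystyrene"` (metal + coat).
#' @param d_metal_range Interval (nm) the metal thickness is drawn from;
#'   defaults to the calibrated thickness +/- 2 nm.
#' @param eps_metal_jitter Half-width of the uniform jitter applied to the
#'   real part of the metal permittivity.
#' @param d_ps_range Interval (nm) for the polystyrene coat thickness.
#' @return A [layer_stack()] with a placeholder bulk of water; the bulk entry
#'   is overwritten by the scan generators.
#' @export
make_chip <- function(seed, surface = c("gold", "polystyrene"),
                      d_metal_range = chip_constants()$d_metal_nm + c(-2, 2),
                      eps_metal_jitter = 0.1,
                      d_ps_range = c(4, 6)) {
  surface <- match.arg(surface)
  cc <- chip_constants()
  .with_seed(seed, {
    d_metal <- stats::runif(1, d_metal_range[1], d_metal_range[2])
    eps_re <- Re(cc$eps_metal) + stats::runif(1, -eps_metal_jitter,
                                              eps_metal_jitter)
    coat <- if (surface == "polystyrene") {
      list(eps = cc$eps_ps,
           thickness_nm = stats::runif(1, d_ps_range[1], d_ps_range[2]))
    } else NULL
    kretschmann_stack(
      eps_bulk = .N_WATER_22C^2,
      eps_prism = cc$eps_prism,
      eps_metal = complex(real = eps_re, imaginary = Im(cc$eps_metal)),
      d_metal_nm = d_metal,
      coat = coat,
      wavelength_nm = cc$wavelength_nm)
  })
}

#' Generate an index-matched pair of synthetic angle scans
#'
#' The sample scan carries an interfacial layer (`eps_interf`, `t_nm`) over
#' the bulk; the reference scan is the identical chip and bulk without the
#' layer, i.e. a perfectly index-matched solvent. Additive Gaussian
#' reflectivity noise is applied to both; noisy values are clipped to
#' \[0, 1\] and the clip rate is recorded in the metadata, together with the
#' generating truth and seed.
#'
#' @param chip A [layer_stack()] from [make_chip()] (or any layer-free chip
#'   stack).
#' @param eps_bulk Bulk permittivity shared exactly by both scans.
#' @param eps_interf Interfacial-layer permittivity of the sample scan.
#' @param t_nm Interfacial-layer thickness in nm.
#' @param noise_sigma Standard deviation of the additive reflectivity noise.
#' @param angle_grid Strictly increasing angle grid in degrees.
#' @param seed Integer seed.
#' @return List with elements `sample` and `reference` ([angle_scan()]s) and
#'   `truth` (the generating parameters).
#' @export
synth_scan_pair <- function(chip, eps_bulk, eps_interf, t_nm = 1.0,
                            noise_sigma = 0.002,
                            angle_grid = seq(45, 70, by = 0.01),
                            seed = 1L) {
  if (eps_interf < eps_bulk - 1e-12 && eps_interf < 1) {
    abort("Require eps_interf >= 1.", class = "sprgamma_domain_error")
  }
  ref_stack <- set_bulk_eps(chip, eps_bulk)
  smp_stack <- set_interfacial_layer(ref_stack, eps_interf, t_nm)
  r_ref <- reflectivity_tm(ref_stack, angle_grid)
  r_smp <- reflectivity_tm(smp_stack, angle_grid)
  truth <- list(eps_bulk = eps_bulk, eps_interf = eps_interf, t_nm = t_nm,
                noise_sigma = noise_sigma, seed = seed)
  noisy <- .with_seed(seed, {
    list(smp = r_smp + stats::rnorm(length(r_smp), 0, noise_sigma),
         ref = r_ref + stats::rnorm(length(r_ref), 0, noise_sigma))
  })
  clip <- function(x) pmin(pmax(x, 0), 1)
  clip_rate <- (sum(noisy$smp < 0 | noisy$smp > 1) +
                  sum(noisy$ref < 0 | noisy$ref > 1)) /
    (2 * length(angle_grid))
  list(
    sample = angle_scan(angle_grid, clip(noisy$smp), sample = "sample",
                        source = "synthetic",
                        metadata = list(truth = truth, seed = seed,
                                        clip_rate = clip_rate)),
    reference = angle_scan(angle_grid, clip(noisy$ref), sample = "reference",
                           source = "synthetic",
                           metadata = list(truth = truth[c("eps_bulk",
                                                           "noise_sigma")],
                                           seed = seed,
                                           clip_rate = clip_rate)),
    truth = truth)
}

#' Default near-wall peak structure of the synthetic solute profile
#'
#' Two strong sub-nanometer peaks and a weaker peak between 1.0 and 1.5 nm,
#' the canonical structure of the simulated glycine films.
#'
#' @return Tibble with columns `center_nm`, `width_nm`, `amplitude_g_cm3`.
#' @export
default_profile_peaks <- function() {
  tibble(center_nm = c(0.35, 0.70, 1.25),
         width_nm = c(0.10, 0.12, 0.18),
         amplitude_g_cm3 = c(1.3, 0.9, 0.30))
}

# Analytic species densities of the synthetic film at positions z.
.synth_profile_fun <- function(film_width_nm, peaks, bulk_solute,
                               bulk_solvent, edge_width_nm, depletion,
                               solvent_threshold = 0.1) {
  # place the smooth film edge so that the solvent crosses the threshold
  # exactly at film_width_nm
  frac <- 1 - 2 * solvent_threshold / bulk_solvent
  z_edge <- film_width_nm - edge_width_nm * atanh(frac)
  edge <- function(z) 0.5 * (1 - tanh((z - z_edge) / edge_width_nm))
  peak_sum <- function(z) {
    if (nrow(peaks) == 0) return(rep(0, length(z)))
    rowSums(vapply(seq_len(nrow(peaks)), function(i) {
      peaks$amplitude_g_cm3[i] *
        exp(-0.5 * ((z - peaks$center_nm[i]) / peaks$width_nm[i])^2)
    }, numeric(length(z))))
  }
  pmax_peak <- if (nrow(peaks)) max(peaks$amplitude_g_cm3) else 1
  list(
    solute = function(z) pmax(0, (bulk_solute + peak_sum(z)) * edge(z)),
    solvent = function(z) {
      pmax(0, bulk_solvent * (1 - depletion * peak_sum(z) / pmax_peak) *
             edge(z))
    })
}

#' Generate a synthetic wall-film density profile
#'
#' Emulates the species-resolved density profiles of a solution film at a
#' structureless wall: the solute density is a bulk plateau plus near-wall
#' Gaussian peaks, the solvent is complementarily depleted where the solute
#' is enriched, and both decay smoothly to zero at the film-vacuum edge. The
#' edge is placed so that the solvent density crosses the film-width
#' criterion (0.1 g/cm^3) exactly at `film_width_nm`. The default bulk
#' densities correspond to a 250 g/kg glycine solution (solution density
#' 1.082 g/cm^3).
#'
#' @param film_width_nm Requested film width in nm.
#' @param peaks Peak table as in [default_profile_peaks()] (`NULL` for a
#'   flat film).
#' @param bulk_solute,bulk_solvent Plateau densities in g/cm^3.
#' @param interfacial_target Optional target for the 0-1 nm solute average;
#'   when given, peak amplitudes are rescaled so the analytic 0-1 nm average
#'   equals it.
#' @param area_nm2 Cross-sectional area in nm^2.
#' @param bin_width_nm Bin width of the returned profile.
#' @param edge_width_nm Width parameter of the film-vacuum edge.
#' @param depletion Fractional solvent depletion at the strongest peak.
#' @param as_particles If `TRUE`, realize the profile as seeded molecular
#'   positions (inverse-CDF sampling along z) and return particle frames
#'   instead of an analytic profile.
#' @param n_frames Number of frames to realize when `as_particles`.
#' @param seed Integer seed (used only when `as_particles`).
#' @param solute_mass,solvent_mass Molecular masses in g/mol.
#' @return A [density_profile()] (with attribute `truth`), or a particle
#'   tibble suitable for [bin_density_profile()].
#' @export
synth_profile <- function(film_width_nm,
                          peaks = default_profile_peaks(),
                          bulk_solute = 0.216, bulk_solvent = 0.866,
                          interfacial_target = NULL,
                          area_nm2 = 25, bin_width_nm = 0.05,
                          edge_width_nm = 0.08, depletion = 0.6,
                          as_particles = FALSE, n_frames = 10L, seed = 1L,
                          solute_mass = .M_GLYCINE,
                          solvent_mass = .M_WATER) {
  if (film_width_nm <= 0) {
    abort("Film width must be positive.", class = "sprgamma_domain_error")
  }
  if (is.null(peaks)) {
    peaks <- tibble(center_nm = numeric(), width_nm = numeric(),
                    amplitude_g_cm3 = numeric())
  }
  peaks <- as_tibble(peaks)
  if (nrow(peaks) && any(peaks$center_nm < 0 |
                         peaks$center_nm > film_width_nm)) {
    abort("Peaks must lie inside the film.", class = "sprgamma_domain_error")
  }
  if (nrow(peaks) && any(peaks$amplitude_g_cm3 < 0)) {
    abort("Peak amplitudes must be >= 0.", class = "sprgamma_domain_error")
  }
  if (!is.null(interfacial_target) && nrow(peaks)) {
    # rescale peak amplitudes so the analytic 0-1 nm solute average hits the
    # target exactly
    zf <- seq(0.0005, 0.9995, by = 0.001)
    fns <- .synth_profile_fun(film_width_nm, peaks, bulk_solute,
                              bulk_solvent, edge_width_nm, depletion)
    base_peaks <- mean(fns$solute(zf)) - bulk_solute
    if (base_peaks <= 0) {
      abort("Cannot calibrate: peaks contribute nothing to the 0-1 nm window.",
            class = "sprgamma_domain_error")
    }
    peaks$amplitude_g_cm3 <- peaks$amplitude_g_cm3 *
      (interfacial_target - bulk_solute) / base_peaks
  }
  fns <- .synth_profile_fun(film_width_nm, peaks, bulk_solute, bulk_solvent,
                            edge_width_nm, depletion)
  z_max <- (film_width_nm + 10 * edge_width_nm)
  n_bins <- ceiling(z_max / bin_width_nm)
  centers <- (seq_len(n_bins) - 0.5) * bin_width_nm
  truth <- list(film_width_nm = film_width_nm, peaks = peaks,
                bulk_solute = bulk_solute, bulk_solvent = bulk_solvent,
                edge_width_nm = edge_width_nm, depletion = depletion,
                seed = if (as_particles) seed else NA_integer_)
  if (!as_particles) {
    prof <- density_profile(
      bind_rows(
        tibble(z_nm = centers, species = "solute",
               density_g_cm3 = fns$solute(centers)),
        tibble(z_nm = centers, species = "solvent",
               density_g_cm3 = fns$solvent(centers))),
      bin_width_nm = bin_width_nm, area_nm2 = area_nm2, frames = 1L)
    attr(prof, "truth") <- truth
    return(prof)
  }
  # particle realization: expected molecule counts from the density
  # integrals, positions by inverse-CDF sampling along z
  zg <- seq(0, n_bins * bin_width_nm, length.out = 4001)
  sample_species <- function(fn, mass, species) {
    dens <- fn(zg)  # g/cm^3
    cum <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(zg))  # g/cm^3 nm
    total_mass <- cum[length(cum)] * area_nm2 * 1e-21  # g
    n_mol <- max(1L, round(total_mass / (mass / .AVOGADRO)))
    cdf <- c(0, cum / cum[length(cum)])
    map(seq_len(n_frames), function(fr) {
      u <- stats::runif(n_mol)
      tibble(frame = fr,
             z_nm = approx(cdf, zg, xout = u, ties = "ordered")$y,
             species = species, mass_g_mol = mass)
    })
  }
  particles <- .with_seed(seed, bind_rows(
    sample_species(fns$solute, solute_mass, "solute"),
    sample_species(fns$solvent, solvent_mass, "solvent")))
  attr(particles, "truth") <- truth
  attr(particles, "area_nm2") <- area_nm2
  particles
}
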