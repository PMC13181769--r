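# Conversion of fitted permittivities to solution composition and excess
# interfacial mass density. The chain is: Clausius-Mossotti fraction
# (eps - 1)/(eps + 2) = rho(x) * [x r_gly + (1 - x) r_water], with the
# specific refractions r calibrated once from a water point and packaged
# literature solution points; the solution density rho(x) interpolates a
# packaged literature-derived table and extrapolates above solubility by a
# linear apparent-specific-volume blend toward the crystal density. The
# excess interfacial mass density of a layer of assumed thickness t is
# Gamma = t * [rho(x_i) x_i - rho(x_b) x_b].

#' Clausius-Mossotti fraction
#'
#' \eqn{(\epsilon - 1)/(\epsilon + 2)}, the quantity proportional to the
#' density-weighted sum of specific refractions of the mixture components.
#' Strictly increasing in \eqn{\epsilon} and bounded by 1.
#'
#' @param eps Relative permittivity (real, > 0); vectorized.
#' @return Dimensionless fraction.
#' @examples
#' cm_fraction(1) # 0
#' @export
cm_fraction <- function(eps) {
  if (any(!is.finite(eps)) || any(eps <= 0)) {
    abort("Permittivity must be positive.", class = "sprgamma_domain_error")
  }
  (eps - 1) / (eps + 2)
}

#' Packaged glycine solution density table
#' @return Tibble with `conc_g_per_kg`, `x_gly`, `density_g_cm3` at ~22 C.
#' @export
glycine_density_table <- function() {
  path <- system.file("extdata", "glycine_density_22C.csv",
                      package = "sprgamma", mustWork = TRUE)
  as_tibble(read.csv(path, comment.char = "#"))
}

#' Packaged glycine solution refraction points
#' @return Tibble with `x_gly`, `refractive_index`, `density_g_cm3` at ~22 C.
#' @export
glycine_refraction_points <- function() {
  path <- system.file("extdata", "glycine_refraction_22C.csv",
                      package = "sprgamma", mustWork = TRUE)
  as_tibble(read.csv(path, comment.char = "#"))
}

#' Mass density of an aqueous glycine solution
#'
#' Monotone (Hyman-filtered spline) interpolation through the packaged
#' literature density table up to its last tabulated composition; beyond it
#' (interfacial compositions can exceed bulk solubility) the apparent
#' specific volume of the solute is extended linearly toward the value
#' implied by the crystal density at `x = 1`, so the model returns the pure
#' water density at `x = 0` and the crystal density at `x = 1`.
#'
#' @param x_gly Glycine mass fraction(s) in \[0, 1\].
#' @param table Density table (defaults to [glycine_density_table()]).
#' @param crystal_density Density of pure solid glycine in g/cm^3.
#' @return Solution density in g/cm^3.
#' @export
density_of_solution <- function(x_gly, table = NULL,
                                crystal_density = .RHO_GLYCINE_CRYSTAL) {
  if (any(!is.finite(x_gly)) || any(x_gly < 0) || any(x_gly > 1)) {
    abort("Mass fraction must lie in [0, 1].", class = "sprgamma_domain_error")
  }
  table <- table %||% glycine_density_table()
  xs <- table$x_gly
  rhos <- table$density_g_cm3
  sp <- splinefun(xs, rhos, method = "hyman")
  x_last <- xs[length(xs)]
  rho_last <- rhos[length(rhos)]
  rho_w <- rhos[1]
  # apparent specific volume of the solute at the last tabulated point
  v_last <- (1 / rho_last - (1 - x_last) / rho_w) / x_last
  v_crys <- 1 / crystal_density
  vapply(x_gly, function(x) {
    if (x <= x_last) {
      sp(x)
    } else {
      v_app <- v_last + (x - x_last) / (1 - x_last) * (v_crys - v_last)
      1 / ((1 - x) / rho_w + x * v_app)
    }
  }, numeric(1))
}

#' Calibrate specific refractions from a water point and solution points
#'
#' Solves the Clausius-Mossotti mixture relation
#' `cm_fraction(eps) = rho * [x r_gly + (1 - x) r_water]` for the two
#' specific refractions: `r_water` exactly from the pure-water point, and
#' `r_gly` by least squares over the solution points.
#'
#' @param water_point List or named vector with `eps` and `rho` of pure water.
#' @param solution_points Data frame with columns `eps`, `x_gly`, `rho`; at
#'   least one row must have `x_gly > 0`.
#' @return Object of class `refraction_calibration`: list with `r_water`,
#'   `r_gly` (cm^3/g), `eps_water`, `rho_water` and the calibration `points`.
#' @export
calibrate_refractions <- function(water_point, solution_points) {
  eps_w <- water_point[["eps"]]
  rho_w <- water_point[["rho"]]
  r_water <- cm_fraction(eps_w) / rho_w
  pts <- as_tibble(solution_points)
  pts <- pts[pts$x_gly > 0, , drop = FALSE]
  if (nrow(pts) == 0) {
    abort("Need at least one solution point with x_gly > 0.",
          class = "sprgamma_calibration_error")
  }
  # cm(eps) - rho (1-x) r_w = (rho x) r_g, linear least squares through origin
  y <- cm_fraction(pts$eps) - pts$rho * (1 - pts$x_gly) * r_water
  z <- pts$rho * pts$x_gly
  r_gly <- sum(y * z) / sum(z^2)
  structure(list(r_water = r_water, r_gly = r_gly,
                 eps_water = eps_w, rho_water = rho_w, points = pts),
            class = "refraction_calibration")
}

#' @export
print.refraction_calibration <- function(x, ...) {
  cat(sprintf("Refraction calibration: r_water = %.5f, r_gly = %.5f cm^3/g (%d solution points)\n",
              x$r_water, x$r_gly, nrow(x$points)))
  invisible(x)
}

#' Default glycine/water refraction calibration
#'
#' Built from the packaged water point (eps 1.7770, rho 0.9977 at 22 C) and
#' the packaged literature refraction points for aqueous glycine.
#'
#' @param density_table Optional density table used for rho(x).
#' @return A `refraction_calibration`.
#' @export
glycine_calibration <- function(density_table = NULL) {
  pts <- glycine_refraction_points()
  calibrate_refractions(
    water_point = list(eps = .N_WATER_22C^2, rho = .RHO_WATER_22C),
    solution_points = tibble(eps = pts$refractive_index^2,
                             x_gly = pts$x_gly, rho = pts$density_g_cm3))
}

# Forward model: permittivity of a solution of mass fraction x under a
# calibration. Inverts cm = A for eps: eps = (1 + 2A)/(1 - A).
massfraction_to_eps <- function(x_gly, calib, table = NULL) {
  rho <- density_of_solution(x_gly, table = table)
  A <- rho * (x_gly * calib$r_gly + (1 - x_gly) * calib$r_water)
  if (any(A >= 1)) {
    abort("Composition outside the Clausius-Mossotti domain.",
          class = "sprgamma_domain_error")
  }
  (1 + 2 * A) / (1 - A)
}

#' Invert a permittivity to a solution composition
#'
#' Solves `cm_fraction(eps) = rho(x) [x r_gly + (1 - x) r_water]` for the
#' glycine mass fraction by bracketed root finding on \[0, 1\] (tolerance
#' 1e-10 in x), then attaches the corresponding solution density.
#' Permittivities below the calibration's water value return `x = 0` with
#' `below_water = TRUE` rather than an error.
#'
#' @param eps Relative permittivity (vectorized).
#' @param calib A `refraction_calibration` (default [glycine_calibration()]).
#' @param table Optional density table.
#' @return Tibble with one row per `eps`: `eps`, `x_gly`,
#'   `concentration_g_per_kg`, `rho`, `below_water`.
#' @export
eps_to_massfraction <- function(eps, calib = glycine_calibration(),
                                table = NULL) {
  table <- table %||% glycine_density_table()
  f <- function(x, target) {
    density_of_solution(x, table = table) *
      (x * calib$r_gly + (1 - x) * calib$r_water) - target
  }
  rows <- map(eps, function(e) {
    target <- cm_fraction(e)
    if (f(0, target) >= 0) {
      return(tibble(eps = e, x_gly = 0,
                    concentration_g_per_kg = 0,
                    rho = density_of_solution(0, table = table),
                    below_water = TRUE))
    }
    if (f(1, target) <= 0) {
      abort("Permittivity above the pure-glycine limit; no bracket in [0, 1].",
            class = "sprgamma_inversion_error")
    }
    x <- uniroot(f, c(0, 1), target = target, tol = 1e-10)$root
    tibble(eps = e, x_gly = x,
           concentration_g_per_kg = 1000 * x / (1 - x),
           rho = density_of_solution(x, table = table),
           below_water = FALSE)
  })
  bind_rows(rows)
}

#' Mass density to molecular number density
#'
#' @param mass_density Mass density in g/cm^3 (vectorized, >= 0).
#' @param molar_mass Molar mass in g/mol (glycine 75.07 by default).
#' @return Molecules per nm^3.
#' @examples
#' mass_to_number_density(1.6) # ~12.8, i.e. ~13 molecules/nm^3
#' @export
mass_to_number_density <- function(mass_density, molar_mass = .M_GLYCINE) {
  if (!is.numeric(molar_mass) || any(molar_mass <= 0)) {
    abort("Molar mass must be positive.", class = "sprgamma_domain_error")
  }
  if (any(mass_density < 0)) {
    abort("Mass density must be >= 0.", class = "sprgamma_domain_error")
  }
  mass_density * .AVOGADRO / molar_mass * 1e-21
}

#' Convert an areal excess from ng/cm^2 to ng/nm^2
#'
#' @param gamma_ng_cm2 Excess interfacial mass density in ng/cm^2.
#' @return The same quantity in ng/nm^2 (factor 1e-14).
#' @examples
#' convert_gamma_units(50) # 5e-13
#' @export
convert_gamma_units <- function(gamma_ng_cm2) gamma_ng_cm2 * 1e-14

#' Excess interfacial mass density from a permittivity pair
#'
#' The core observable of the pipeline: with the interfacial and bulk
#' permittivities mapped to compositions through the calibrated
#' Clausius-Mossotti relation, the solute mass per unit area in a layer of
#' assumed thickness `t_nm` in excess of what the bulk composition would
#' contribute is \eqn{\Gamma = t\,[\rho(x_i) x_i - \rho(x_b) x_b]}. A
#' depleted interface (`eps_interf < eps_bulk`) yields a negative excess.
#' Although `eps_interf` itself depends on the assumed thickness, Gamma is
#' nearly invariant to it (the epsilon-thickness trade-off).
#'
#' @param eps_interf,eps_bulk Fitted interfacial and bulk permittivities.
#' @param t_nm Assumed layer thickness in nm (> 0).
#' @param calib A `refraction_calibration`.
#' @param molar_mass Solute molar mass in g/mol.
#' @param table Optional density table.
#' @return One-row tibble of class `excess_density`: `eps_interf`,
#'   `eps_bulk`, `t_nm`, `x_interf`, `x_bulk`, `gamma_ng_cm2`,
#'   `gamma_ng_nm2`, `excess_molecules_per_nm3`.
#' @export
gamma_excess <- function(eps_interf, eps_bulk, t_nm = 1.0,
                         calib = glycine_calibration(),
                         molar_mass = .M_GLYCINE, table = NULL) {
  if (t_nm <= 0) {
    abort("Layer thickness must be positive.", class = "sprgamma_domain_error")
  }
  ci <- eps_to_massfraction(eps_interf, calib = calib, table = table)
  cb <- eps_to_massfraction(eps_bulk, calib = calib, table = table)
  delta <- ci$rho * ci$x_gly - cb$rho * cb$x_gly  # g/cm^3
  gamma <- t_nm * delta * .NG_CM2_PER_GCM3_NM     # ng/cm^2
  excess_n <- sign(delta) * mass_to_number_density(abs(delta), molar_mass)
  out <- tibble(eps_interf = eps_interf, eps_bulk = eps_bulk, t_nm = t_nm,
                x_interf = ci$x_gly, x_bulk = cb$x_gly,
                gamma_ng_cm2 = gamma,
                gamma_ng_nm2 = convert_gamma_units(gamma),
                excess_molecules_per_nm3 = excess_n)
  class(out) <- c("excess_density", class(out))
  out
}
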