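# Independent oracles and shared fixtures. Everything here is written from
# first principles, separately from the package internals it checks.

# Airy two-interface closed form for a prism/film/substrate stack,
# p-polarization: r = (r12 + r23 e^{2 i beta}) / (1 + r12 r23 e^{2 i beta}).
airy_reflectivity <- function(eps1, eps2, eps3, d_nm, wavelength_nm,
                              angle_deg) {
  k0 <- 2 * pi / wavelength_nm
  kx2 <- Re(eps1) * sin(angle_deg * pi / 180)^2 * k0^2
  kz <- function(eps) {
    v <- sqrt(eps * k0^2 - kx2 + 0i)
    if (Im(v) < 0) -v else v
  }
  kz1 <- kz(eps1); kz2 <- kz(eps2); kz3 <- kz(eps3)
  rp <- function(ea, eb, kza, kzb) (eb * kza - ea * kzb) / (eb * kza + ea * kzb)
  r12 <- rp(eps1, eps2, kz1, kz2)
  r23 <- rp(eps2, eps3, kz2, kz3)
  ph <- exp(2i * kz2 * d_nm)
  Mod((r12 + r23 * ph) / (1 + r12 * r23 * ph))^2
}

# Direct-sum surface excess of a binned profile: accumulate
# (rho - rho_bulk) * overlap(bin, [0, z1]) bin by bin, with rho_bulk the
# overlap-weighted mean over [z1, z2]. Units: (g/cm^3) nm -> ng/cm^2.
surface_excess_oracle <- function(z, rho, bin_width, z1, z2) {
  lo <- z - bin_width / 2
  hi <- z + bin_width / 2
  wb <- pmax(0, pmin(hi, z2) - pmax(lo, z1))
  rho_bulk <- sum(wb * rho) / sum(wb)
  wi <- pmax(0, pmin(hi, z1) - pmax(lo, 0))
  sum(wi * (rho - rho_bulk)) * 100
}

# Forward Clausius-Mossotti mixture model evaluated on a dense grid
# (vectorized re-derivation, independent of the package's inversion): returns
# rho(x) * (x r_g + (1 - x) r_w) on the grid.
cm_forward_grid <- function(x, calib, dens_table, crystal_density = 1.607) {
  xs <- dens_table$x_gly
  rhos <- dens_table$density_g_cm3
  sp <- stats::splinefun(xs, rhos, method = "hyman")
  x_last <- xs[length(xs)]
  rho_last <- rhos[length(rhos)]
  rho_w <- rhos[1]
  v_last <- (1 / rho_last - (1 - x_last) / rho_w) / x_last
  v_app <- v_last + (x - x_last) / (1 - x_last) * (1 / crystal_density - v_last)
  rho <- ifelse(x <= x_last, sp(x),
                1 / ((1 - x) / rho_w + x * v_app))
  rho * (x * calib$r_gly + (1 - x) * calib$r_water)
}

# Shared fixtures -----------------------------------------------------------

default_chip <- function() {
  cc <- chip_constants()
  kretschmann_stack(eps_bulk = 1.8489, eps_prism = cc$eps_prism,
                    eps_metal = cc$eps_metal, d_metal_nm = cc$d_metal_nm)
}

# noiseless scan of the default chip over a grid covering both features
default_scan <- function(eps_bulk = 1.8489, layer = NULL,
                         grid = seq(45, 68, by = 0.01)) {
  st <- set_bulk_eps(default_chip(), eps_bulk)
  if (!is.null(layer)) {
    st <- set_interfacial_layer(st, layer[1], layer[2])
  }
  simulate_scan(st, grid)
}

add_scan_noise <- function(scan, sigma, seed) {
  set.seed(seed)
  r <- pmin(pmax(scan$reflectivity + rnorm(nrow(scan), 0, sigma), 0), 1)
  angle_scan(scan$angle_deg, r, source = "synthetic")
}

random_valid_stack <- function() {
  n_internal <- sample(1:3, 1)
  eps <- c(complex(real = runif(1, 2.5, 4)),
           vapply(seq_len(n_internal), function(i) {
             if (runif(1) < 0.5) {
               complex(real = runif(1, -15, -2), imaginary = runif(1, 0.3, 3))
             } else {
               complex(real = runif(1, 1.2, 3), imaginary = runif(1, 0, 0.5))
             }
           }, complex(1)),
           complex(real = runif(1, 1.1, 2.2)))
  d <- c(NA, runif(n_internal, 5, 80), NA)
  layer_stack(tibble::tibble(
    label = c("prism", paste0("L", seq_len(n_internal)), "bulk"),
    eps = eps, thickness_nm = d))
}
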