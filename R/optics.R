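# Forward optical model: p-polarized reflectivity of a planar multilayer in the
# Kretschmann configuration, evaluated with the standard 2x2 characteristic
# (transfer) matrix method. All angles are internal incidence angles at the
# prism base, in degrees; all lengths are in nm; permittivities are relative
# and may be complex, with the sign convention that absorbing media have a
# positive imaginary part.

#' Construct a multilayer optical stack
#'
#' A layer stack is an ordered tibble of layers from the prism half-space to
#' the bulk-liquid half-space. The two terminal media are half-spaces and carry
#' no thickness; every internal layer must have a positive thickness. At most
#' one layer may be flagged as the interfacial layer and it must sit directly
#' against the bulk liquid.
#'
#' @param layers A data frame with columns `label` (character), `eps` (complex
#'   relative permittivity; a numeric column is promoted to complex) and
#'   `thickness_nm` (numeric, `NA` for the two terminal half-spaces). An
#'   optional logical column `interfacial` flags the interfacial layer.
#' @param wavelength_nm Vacuum wavelength of the exciting light in nm.
#' @return A tibble of class `layer_stack` with attribute `wavelength_nm`.
#' @examples
#' kretschmann_stack(eps_bulk = 1.8489)
#' @export
layer_stack <- function(layers, wavelength_nm = 632.8) {
  layers <- as_tibble(layers)
  if (nrow(layers) < 2) {
    abort("A layer stack needs at least two media (prism and bulk).",
          class = "sprgamma_config_error")
  }
  if (!all(c("label", "eps") %in% names(layers))) {
    abort("`layers` must have columns `label` and `eps`.",
          class = "sprgamma_config_error")
  }
  if (!"thickness_nm" %in% names(layers)) layers$thickness_nm <- NA_real_
  if (!"interfacial" %in% names(layers)) layers$interfacial <- FALSE
  layers$eps <- as.complex(layers$eps)
  layers$interfacial <- layers$interfacial %in% TRUE
  n <- nrow(layers)
  layers$thickness_nm[c(1, n)] <- NA_real_
  if (n > 2 && any(!is.finite(layers$thickness_nm[2:(n - 1)]) |
                   layers$thickness_nm[2:(n - 1)] <= 0)) {
    abort("Internal layers must have finite positive thickness.",
          class = "sprgamma_config_error")
  }
  if (any(Im(layers$eps) < 0)) {
    abort("Imaginary permittivity must be >= 0 (absorbing-medium convention).",
          class = "sprgamma_config_error")
  }
  if (sum(layers$interfacial) > 1) {
    abort("At most one layer may be flagged interfacial.",
          class = "sprgamma_config_error")
  }
  if (any(layers$interfacial) && which(layers$interfacial) != n - 1) {
    abort("The interfacial layer must be adjacent to the bulk liquid.",
          class = "sprgamma_config_error")
  }
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) != 1 ||
      wavelength_nm <= 0) {
    abort("`wavelength_nm` must be a single positive number.",
          class = "sprgamma_config_error")
  }
  new_tibble(layers, wavelength_nm = wavelength_nm,
             class = "layer_stack", nrow = nrow(layers))
}

#' Calibrated default chip constants
#'
#' Effective optical constants of the default sensor chip at 632.8 nm. The
#' prism permittivity is anchored to the total-internal-reflection angle
#' 49.53 deg observed for a liquid of permittivity 1.8489; the metal film's
#' real permittivity and thickness are calibrated (at fixed loss 1.26) so that
#' the layer-free stack resonates at 62.55 deg and a 1 nm layer of
#' permittivity 2.1070 shifts the resonance by 0.13 deg. They are effective,
#' instrument-level parameters, not tabulated gold constants.
#'
#' @return Named list: `eps_prism`, `eps_metal`, `d_metal_nm`, `eps_ps`,
#'   `d_ps_nm`, `wavelength_nm`.
#' @export
chip_constants <- function() {
  list(
    eps_prism = 1.8489 / sin(49.53 * pi / 180)^2,
    eps_metal = complex(real = -5.94375, imaginary = 1.26),
    d_metal_nm = 38.56375,
    eps_ps = 2.53 + 0i,
    d_ps_nm = 5,
    wavelength_nm = 632.8
  )
}

#' Build a Kretschmann stack (prism / metal / optional coat / optional
#' interfacial layer / bulk)
#'
#' @param eps_bulk Bulk-liquid relative permittivity.
#' @param eps_prism,eps_metal,d_metal_nm Prism and metal-film constants;
#'   defaults from [chip_constants()].
#' @param coat Optional polymer coat as `list(eps = , thickness_nm = )`.
#' @param interfacial Optional interfacial layer as
#'   `list(eps = , thickness_nm = )`, inserted against the bulk.
#' @param wavelength_nm Vacuum wavelength in nm.
#' @return A [layer_stack()].
#' @export
kretschmann_stack <- function(eps_bulk,
                              eps_prism = chip_constants()$eps_prism,
                              eps_metal = chip_constants()$eps_metal,
                              d_metal_nm = chip_constants()$d_metal_nm,
                              coat = NULL,
                              interfacial = NULL,
                              wavelength_nm = chip_constants()$wavelength_nm) {
  layers <- tibble(
    label = c("prism", "metal"),
    eps = c(as.complex(eps_prism), as.complex(eps_metal)),
    thickness_nm = c(NA_real_, d_metal_nm),
    interfacial = FALSE
  )
  if (!is.null(coat)) {
    layers <- bind_rows(layers, tibble(
      label = "coat", eps = as.complex(coat$eps),
      thickness_nm = coat$thickness_nm, interfacial = FALSE))
  }
  if (!is.null(interfacial)) {
    layers <- bind_rows(layers, tibble(
      label = "interfacial", eps = as.complex(interfacial$eps),
      thickness_nm = interfacial$thickness_nm, interfacial = TRUE))
  }
  layers <- bind_rows(layers, tibble(
    label = "bulk", eps = as.complex(eps_bulk),
    thickness_nm = NA_real_, interfacial = FALSE))
  layer_stack(layers, wavelength_nm = wavelength_nm)
}

#' Insert or replace the interfacial layer of a stack
#'
#' @param stack A [layer_stack()].
#' @param eps Layer relative permittivity.
#' @param thickness_nm Layer thickness in nm.
#' @return The stack with the interfacial layer set.
#' @export
set_interfacial_layer <- function(stack, eps, thickness_nm) {
  stopifnot(inherits(stack, "layer_stack"))
  wl <- attr(stack, "wavelength_nm")
  df <- as_tibble(stack)
  df <- df[!df$interfacial, ]
  n <- nrow(df)
  df <- bind_rows(
    df[seq_len(n - 1), ],
    tibble(label = "interfacial", eps = as.complex(eps),
           thickness_nm = thickness_nm, interfacial = TRUE),
    df[n, ])
  layer_stack(df, wavelength_nm = wl)
}

#' Replace the bulk permittivity of a stack
#' @param stack A [layer_stack()].
#' @param eps_bulk New bulk relative permittivity.
#' @return The modified stack.
#' @export
set_bulk_eps <- function(stack, eps_bulk) {
  stopifnot(inherits(stack, "layer_stack"))
  wl <- attr(stack, "wavelength_nm")
  df <- as_tibble(stack)
  df$eps[nrow(df)] <- as.complex(eps_bulk)
  layer_stack(df, wavelength_nm = wl)
}

# z-components of the wavevector in every layer for internal angle theta
# (radians measured in the prism). Principal-branch complex square root with
# the sign fixed so that Im(kz) >= 0, i.e. evanescent fields decay away from
# the prism.
.kz_layers <- function(eps, k0, theta_rad) {
  kx2 <- Re(eps[1]) * sin(theta_rad)^2 * k0^2
  kz <- sqrt(eps * k0^2 - kx2 + 0i)
  flip <- Im(kz) < 0
  kz[flip] <- -kz[flip]
  kz
}

# Complex reflection and transmission amplitudes (H-field) of the stack at one
# internal angle, TM polarization.
.tm_amplitudes <- function(stack, angle_deg) {
  eps <- stack$eps
  d <- stack$thickness_nm
  k0 <- 2 * pi / attr(stack, "wavelength_nm")
  th <- angle_deg * pi / 180
  kz <- .kz_layers(eps, k0, th)
  q <- kz / eps
  n <- length(eps)
  M <- diag(2) + 0i
  if (n > 2) {
    for (j in 2:(n - 1)) {
      beta <- kz[j] * d[j]
      # sin(beta)/q -> d * eps as kz -> 0 (layer at its critical angle)
      sin_over_q <- if (Mod(beta) < 1e-8) {
        d[j] * eps[j] * (1 - beta^2 / 6)
      } else {
        sin(beta) / q[j]
      }
      Mj <- matrix(c(cos(beta), -1i * sin(beta) * q[j],
                     -1i * sin_over_q, cos(beta)), 2, 2)
      M <- M %*% Mj
    }
  }
  a <- (M[1, 1] + M[1, 2] * q[n]) * q[1]
  b <- M[2, 1] + M[2, 2] * q[n]
  list(r = (a - b) / (a + b),
       t = 2 * q[1] / (a + b),
       q1 = q[1], qn = q[n])
}

#' Transfer-matrix reflectivity of a multilayer stack
#'
#' \eqn{|r_p|^2} for transverse-magnetic (p-polarized) light incident from the
#' prism at the given internal angle(s).
#'
#' @param stack A [layer_stack()].
#' @param angle_deg Internal incidence angle(s) in degrees, each in (0, 90).
#' @return Numeric vector of reflectivities, one per angle.
#' @export
reflectivity_tm <- function(stack, angle_deg) {
  if (!inherits(stack, "layer_stack")) {
    abort("`stack` must be a layer_stack.", class = "sprgamma_config_error")
  }
  if (any(!is.finite(angle_deg) | angle_deg <= 0 | angle_deg >= 90)) {
    abort("Angles must lie strictly between 0 and 90 degrees.",
          class = "sprgamma_domain_error")
  }
  vapply(angle_deg, function(a) Mod(.tm_amplitudes(stack, a)$r)^2, numeric(1))
}

#' Transfer-matrix transmittance of a multilayer stack
#'
#' Power transmittance into the bulk half-space for p-polarized light,
#' computed from the transmission amplitude and the impedance factors of the
#' two terminal media. For a lossless dielectric stack below the critical
#' angle, `reflectivity_tm + transmittance_tm == 1`.
#'
#' @inheritParams reflectivity_tm
#' @return Numeric vector of transmittances.
#' @export
transmittance_tm <- function(stack, angle_deg) {
  if (!inherits(stack, "layer_stack")) {
    abort("`stack` must be a layer_stack.", class = "sprgamma_config_error")
  }
  vapply(angle_deg, function(a) {
    amp <- .tm_amplitudes(stack, a)
    Re(amp$qn) / Re(amp$q1) * Mod(amp$t)^2
  }, numeric(1))
}

#' Analytic total-internal-reflection angle
#'
#' The critical angle \eqn{\theta_{TIR} = \arcsin\sqrt{\epsilon_{bulk} /
#' \epsilon_{prism}}} of a prism/liquid pair. It depends only on the bulk
#' permittivity, which is what makes the TIR edge a pure bulk probe.
#'
#' @param eps_prism,eps_bulk Real relative permittivities, with
#'   `0 < eps_bulk < eps_prism`.
#' @return Angle in degrees.
#' @examples
#' tir_angle_analytic(4, 1) # 30 degrees
#' @export
tir_angle_analytic <- function(eps_prism, eps_bulk) {
  if (any(eps_bulk <= 0) || any(eps_prism <= 0)) {
    abort("Permittivities must be positive.", class = "sprgamma_domain_error")
  }
  if (any(eps_bulk >= eps_prism)) {
    abort("No total internal reflection: eps_bulk >= eps_prism.",
          class = "sprgamma_no_tir_error")
  }
  asin(sqrt(eps_bulk / eps_prism)) * 180 / pi
}

#' Simulate an angle scan from a stack
#'
#' Pointwise application of [reflectivity_tm()] over an angle grid; the result
#' is marked as synthetic.
#'
#' @param stack A [layer_stack()].
#' @param angle_deg Strictly increasing grid of internal angles in degrees.
#' @param sample Sample label stored in the scan metadata.
#' @return An [angle_scan()] with `source = "synthetic"`.
#' @export
simulate_scan <- function(stack, angle_deg, sample = "synthetic") {
  if (is.unsorted(angle_deg, strictly = TRUE)) {
    abort("The angle grid must be strictly increasing.",
          class = "sprgamma_domain_error")
  }
  angle_scan(angle_deg, reflectivity_tm(stack, angle_deg),
             sample = sample, source = "synthetic")
}
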