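# Inversion of angle scans to bulk and interfacial permittivities. The
# default protocol is two-stage: stage 1 fixes the bulk permittivity from the
# TIR edge (of the scan itself or of an index-matched partner measured on the
# same chip); stage 2 frees only the interfacial-layer permittivity at an
# assumed thickness (1 nm by default), either by matching the extracted SPR
# minimum ("feature" mode) or by least squares over the SPR window of the
# reflectivity curve ("curve" mode). Full-curve fitting with an arbitrary
# small free-parameter subset is available as an expert mode.

#' Bulk permittivity from the TIR edge
#'
#' Stage 1 of the inversion: `eps_bulk = eps_prism * sin^2(theta_TIR)`. The
#' TIR edge depends only on the bulk refractive index, so this estimate is
#' blind to any nanoscale interfacial layer.
#'
#' @param scan An [angle_scan()].
#' @param eps_prism Calibrated prism permittivity (see [calibrate_prism()]).
#' @param tir_window Search window passed to [find_tir_edge()].
#' @return Bulk relative permittivity (dimensionless).
#' @export
fit_bulk_eps <- function(scan, eps_prism, tir_window = c(48, 52)) {
  edge <- find_tir_edge(scan, window = tir_window)
  eps <- eps_prism * sin(as.numeric(edge) * pi / 180)^2
  if (eps >= eps_prism) {
    abort("Extracted edge implies eps_bulk >= eps_prism (no TIR).",
          class = "sprgamma_no_tir_error")
  }
  eps
}

# SPR minimum angle of the forward model, found by continuous minimization of
# the transfer-matrix reflectivity (not on a grid).
.model_spr_minimum <- function(stack, window) {
  optimize(function(a) reflectivity_tm(stack, a),
           lower = window[1], upper = window[2], tol = 1e-9)$minimum
}

.new_interfacial_fit <- function(eps_bulk, eps_interf, t_nm, residual,
                                 converged, mode, window, iterations = NA_integer_) {
  structure(
    list(eps_bulk = eps_bulk, eps_interf = eps_interf,
         assumed_thickness = t_nm, residual = residual,
         converged = converged, mode = mode, window = window,
         iterations = iterations),
    class = "interfacial_fit")
}

#' @export
print.interfacial_fit <- function(x, ...) {
  cat("Interfacial permittivity fit (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  eps_bulk   = %.4f\n", x$eps_bulk))
  cat(sprintf("  eps_interf = %.4f at assumed t = %g nm\n",
              x$eps_interf, x$assumed_thickness))
  cat(sprintf("  residual   = %.3g; converged: %s\n",
              x$residual, x$converged))
  invisible(x)
}

#' Fit the interfacial-layer permittivity at fixed thickness
#'
#' Stage 2 of the inversion. With the bulk permittivity fixed (from the same
#' scan's TIR edge or from an index-matched partner), a single interfacial
#' layer of assumed thickness `t_nm` is inserted against the bulk and its
#' permittivity is adjusted until the model matches the observation. In
#' `"feature"` mode (default) the model's SPR minimum is matched to the
#' extracted minimum of the scan by bracketed root finding; in `"curve"` mode
#' the squared reflectivity mismatch over the SPR window is minimized by
#' Brent's method. Note that a single scan cannot decouple the layer's
#' permittivity from its thickness: `eps_interf` is conditional on `t_nm`,
#' but the excess mass density derived downstream is insensitive to that
#' choice.
#'
#' @param scan An [angle_scan()].
#' @param stack_without_layer The chip's [layer_stack()] without an
#'   interfacial layer (its bulk entry is overwritten by `eps_bulk`).
#' @param eps_bulk Bulk permittivity fixed in stage 1.
#' @param t_nm Assumed interfacial-layer thickness in nm.
#' @param mode `"feature"` or `"curve"`.
#' @param spr_window Angle window (degrees) for the SPR minimum / the
#'   least-squares fit.
#' @param eps_range Search bracket for the layer permittivity.
#' @param tol Convergence tolerance in permittivity.
#' @param max_iter Iteration budget for the bracketed search.
#' @return An `interfacial_fit` object; see [tidy.interfacial_fit()].
#' @export
fit_interfacial_eps <- function(scan, stack_without_layer, eps_bulk,
                                t_nm = 1.0,
                                mode = c("feature", "curve"),
                                spr_window = c(60, 66),
                                eps_range = c(1.0, 3.8),
                                tol = 1e-6, max_iter = 200) {
  mode <- match.arg(mode)
  if (t_nm <= 0) {
    abort("Assumed thickness must be positive.", class = "sprgamma_domain_error")
  }
  base <- set_bulk_eps(stack_without_layer, eps_bulk)
  with_layer <- function(eps) set_interfacial_layer(base, eps, t_nm)

  sel <- scan$angle_deg >= spr_window[1] & scan$angle_deg <= spr_window[2]
  rms <- function(eps) {
    model <- reflectivity_tm(with_layer(eps), scan$angle_deg[sel])
    sqrt(mean((model - scan$reflectivity[sel])^2))
  }

  if (mode == "feature") {
    target <- as.numeric(find_spr_minimum(scan, window = spr_window))
    # the model minimum is extracted on the scan's own grid with the same
    # estimator, so any small estimator bias cancels in the match
    g <- function(eps) {
      model <- simulate_scan(with_layer(eps), scan$angle_deg)
      as.numeric(find_spr_minimum(model, window = spr_window)) - target
    }
    glo <- g(eps_range[1]); ghi <- g(eps_range[2])
    if (sign(glo) == sign(ghi)) {
      return(.new_interfacial_fit(eps_bulk, NA_real_, t_nm, NA_real_,
                                  converged = FALSE, mode = mode,
                                  window = spr_window))
    }
    root <- uniroot(g, lower = eps_range[1], upper = eps_range[2],
                    tol = tol, maxiter = max_iter)
    converged <- root$estim.prec <= 10 * tol
    eps_i <- root$root
    iterations <- root$iter
  } else {
    opt <- optimize(rms, lower = eps_range[1], upper = eps_range[2], tol = tol)
    eps_i <- opt$minimum
    # boundary solutions indicate the bracket did not contain the optimum
    converged <- eps_i > eps_range[1] + 10 * tol && eps_i < eps_range[2] - 10 * tol
    iterations <- NA_integer_
  }
  .new_interfacial_fit(eps_bulk, eps_i, t_nm, rms(eps_i),
                       converged = converged, mode = mode,
                       window = spr_window, iterations = iterations)
}

# Allowed free-parameter addresses for full-curve fitting: "<label>.<field>"
# with field one of eps_re, eps_im, thickness_nm.
.apply_params <- function(stack, params) {
  df <- as_tibble(stack)
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% df$label ||
        !parts[2] %in% c("eps_re", "eps_im", "thickness_nm")) {
      abort(paste0("Unknown free parameter `", nm,
                   "`; use \"<layer label>.<eps_re|eps_im|thickness_nm>\"."),
            class = "sprgamma_config_error")
    }
    i <- which(df$label == parts[1])[1]
    if (parts[2] == "eps_re") {
      df$eps[i] <- complex(real = params[[nm]], imaginary = Im(df$eps[i]))
    } else if (parts[2] == "eps_im") {
      df$eps[i] <- complex(real = Re(df$eps[i]), imaginary = params[[nm]])
    } else {
      df$thickness_nm[i] <- params[[nm]]
    }
  }
  layer_stack(df, wavelength_nm = attr(stack, "wavelength_nm"))
}

#' Bounded least-squares fit of a scan with a free parameter subset
#'
#' Expert mode: fits up to three stack parameters simultaneously to the full
#' reflectivity curve by bounded Levenberg-Marquardt. Parameters are addressed
#' as `"<layer label>.<eps_re|eps_im|thickness_nm>"`. A parameter covariance
#' estimate is attached; strongly collinear parameter requests (such as the
#' permittivity and thickness of the same thin layer, which trade off almost
#' exactly) are flagged as unidentifiable, and an exactly degenerate Jacobian
#' is an error.
#'
#' @param scan An [angle_scan()].
#' @param stack Starting [layer_stack()]; entries named in `free` are varied.
#' @param free Named numeric vector of starting values for the free
#'   parameters (length 0 to 3).
#' @param lower,upper Named bounds for the free parameters (required for each
#'   free parameter).
#' @param angle_window Optional angle window restricting the fitted points.
#' @return An object of class `spr_curve_fit`: list with `parameters`
#'   (tibble of estimate, std.error), `residual` (RMS), `covariance`,
#'   `identifiable`, `converged`, and the fitted `stack`.
#' @export
fit_full_curve <- function(scan, stack, free = numeric(),
                           lower = NULL, upper = NULL,
                           angle_window = NULL) {
  if (length(free) > 3) {
    abort("At most 3 simultaneously free parameters are supported.",
          class = "sprgamma_config_error")
  }
  sel <- rep(TRUE, nrow(scan))
  if (!is.null(angle_window)) {
    sel <- scan$angle_deg >= angle_window[1] & scan$angle_deg <= angle_window[2]
  }
  ang <- scan$angle_deg[sel]
  obs <- scan$reflectivity[sel]
  resid_fn <- function(p) {
    names(p) <- names(free)
    reflectivity_tm(.apply_params(stack, as.list(p)), ang) - obs
  }
  if (length(free) == 0) {
    r <- reflectivity_tm(stack, ang) - obs
    return(structure(list(parameters = tibble(term = character(),
                                              estimate = numeric(),
                                              std.error = numeric()),
                          residual = sqrt(mean(r^2)), covariance = NULL,
                          identifiable = TRUE, converged = TRUE,
                          stack = stack),
                     class = "spr_curve_fit"))
  }
  if (is.null(lower) || is.null(upper) ||
      !all(names(free) %in% names(lower)) ||
      !all(names(free) %in% names(upper))) {
    abort("Bounds `lower` and `upper` must be supplied for every free parameter.",
          class = "sprgamma_config_error")
  }
  jac <- function(p) {
    f0 <- resid_fn(p)
    J <- matrix(0, length(f0), length(p))
    for (k in seq_along(p)) {
      h <- pmax(1e-6, 1e-6 * abs(p[k]))
      pk <- p; pk[k] <- pk[k] + h
      J[, k] <- (resid_fn(pk) - f0) / h
    }
    J
  }
  J0 <- jac(unname(free))
  sv0 <- svd(J0)$d
  if (min(sv0) == 0 || max(sv0) / max(min(sv0), .Machine$double.xmin) > 1e10) {
    abort("Requested free-parameter set is not identifiable (degenerate Jacobian).",
          class = "sprgamma_identifiability_error")
  }
  fit <- minpack.lm::nls.lm(
    par = unname(free), fn = resid_fn,
    lower = unname(lower[names(free)]), upper = unname(upper[names(free)]),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- fit$par
  names(est) <- names(free)
  J <- jac(est)
  sv <- svd(J)$d
  identifiable <- max(sv) / max(min(sv), .Machine$double.xmin) < 1e6
  # near-perfect parameter correlation (e.g. a thin layer's permittivity
  # against its thickness) is flagged even when the point estimate converges
  if (identifiable && length(est) > 1) {
    JtJ <- crossprod(J)
    corr <- stats::cov2cor(solve(JtJ))
    if (max(abs(corr[upper.tri(corr)])) > 0.999) identifiable <- FALSE
  }
  dof <- max(length(obs) - length(est), 1)
  sigma2 <- sum(fit$fvec^2) / dof
  covariance <- tryCatch(sigma2 * solve(crossprod(J)),
                         error = function(e) {
                           identifiable <<- FALSE
                           sigma2 * MASS_ginv(crossprod(J))
                         })
  se <- sqrt(pmax(diag(covariance), 0))
  structure(
    list(parameters = tibble(term = names(free), estimate = unname(est),
                             std.error = unname(se)),
         residual = sqrt(mean(fit$fvec^2)),
         covariance = covariance,
         identifiable = identifiable,
         converged = fit$info %in% 1:4,
         stack = .apply_params(stack, as.list(est))),
    class = "spr_curve_fit")
}

# Moore-Penrose pseudoinverse via SVD (used only when the normal equations
# are singular, to still report an inflated covariance).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.spr_curve_fit <- function(x, ...) {
  cat("Full-curve SPR fit: RMS residual", format(x$residual, digits = 4), "\n")
  if (nrow(x$parameters)) print(x$parameters)
  if (!x$identifiable) cat("  [warning] parameters poorly identifiable\n")
  invisible(x)
}

#' Tidy an interfacial fit
#' @param x An `interfacial_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted quantity.
#' @method tidy interfacial_fit
#' @export
tidy.interfacial_fit <- function(x, ...) {
  tibble(term = c("eps_bulk", "eps_interf"),
         estimate = c(x$eps_bulk, x$eps_interf))
}

#' Glance at an interfacial fit
#' @param x An `interfacial_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fit summaries.
#' @method glance interfacial_fit
#' @export
glance.interfacial_fit <- function(x, ...) {
  tibble(residual = x$residual, converged = x$converged, mode = x$mode,
         assumed_thickness = x$assumed_thickness)
}

#' Tidy a full-curve fit
#' @param x An `spr_curve_fit`.
#' @param ... Unused.
#' @return Tibble of parameter estimates and standard errors.
#' @method tidy spr_curve_fit
#' @export
tidy.spr_curve_fit <- function(x, ...) x$parameters

#' Glance at a full-curve fit
#' @param x An `spr_curve_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fit summaries.
#' @export
glance.spr_curve_fit <- function(x, ...) {
  tibble(residual = x$residual, converged = x$converged,
         identifiable = x$identifiable, n_free = nrow(x$parameters))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
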