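test_that("Clausius-Mossotti fraction matches direct arithmetic and limits", {
  expect_equal(cm_fraction(1), 0)
  expect_equal(cm_fraction(2.1070), 1.1070 / 4.1070, tolerance = 1e-12)
  expect_equal(cm_fraction(1e9), 1, tolerance = 1e-8)
  expect_error(cm_fraction(-1), class = "sprgamma_domain_error")
  expect_error(cm_fraction(0), class = "sprgamma_domain_error")
  # strictly increasing
  e <- seq(1, 3, by = 0.01)
  expect_true(all(diff(cm_fraction(e)) > 0))
})

test_that("solution density interpolates its table and honours the endpoints", {
  tab <- glycine_density_table()
  expect_equal(density_of_solution(0), 0.9977, tolerance = 1e-6)
  expect_equal(density_of_solution(1), 1.607, tolerance = 0.01 / 1.6)
  # interpolation identity at every tabulated point
  expect_equal(density_of_solution(tab$x_gly), tab$density_g_cm3,
               tolerance = 1e-10)
  # monotone over the full range and within the physical bounds
  x <- seq(0, 1, by = 0.005)
  rho <- density_of_solution(x)
  expect_true(all(diff(rho) > 0))
  expect_true(all(rho >= 0.9977 - 1e-9 & rho <= 1.607 + 1e-9))
  expect_error(density_of_solution(-0.1), class = "sprgamma_domain_error")
  expect_error(density_of_solution(1.2), class = "sprgamma_domain_error")
})

test_that("refraction calibration solves the water point in closed form", {
  calib <- calibrate_refractions(
    water_point = list(eps = 1.7770, rho = 0.9977),
    solution_points = glycine_calibration()$points)
  expect_equal(calib$r_water, cm_fraction(1.7770) / 0.9977, tolerance = 1e-12)
  expect_equal(calib$r_water, 0.2062, tolerance = 1e-4 / 0.206)
  # duplicate solution points change nothing
  one <- calib$points[1, ]
  c1 <- calibrate_refractions(list(eps = 1.7770, rho = 0.9977), one)
  c2 <- calibrate_refractions(list(eps = 1.7770, rho = 0.9977),
                              dplyr::bind_rows(one, one, one))
  expect_equal(c1$r_gly, c2$r_gly, tolerance = 1e-12)
  expect_error(calibrate_refractions(
    list(eps = 1.7770, rho = 0.9977),
    tibble::tibble(eps = 1.7770, x_gly = 0, rho = 0.9977)),
    class = "sprgamma_calibration_error")
})

test_that("a synthetic solution point returns its generating refraction", {
  r_w <- cm_fraction(1.7770) / 0.9977
  r_g_true <- 0.2200
  x <- 0.12
  rho <- density_of_solution(x)
  A <- rho * (x * r_g_true + (1 - x) * r_w)
  eps <- (1 + 2 * A) / (1 - A)
  calib <- calibrate_refractions(list(eps = 1.7770, rho = 0.9977),
                                 tibble::tibble(eps = eps, x_gly = x, rho = rho))
  expect_equal(calib$r_gly, r_g_true, tolerance = 1e-6 / 0.22)
})

test_that("the default calibration reproduces its own points", {
  calib <- glycine_calibration()
  for (i in seq_len(nrow(calib$points))) {
    p <- calib$points[i, ]
    A <- p$rho * (p$x_gly * calib$r_gly + (1 - p$x_gly) * calib$r_water)
    eps_back <- (1 + 2 * A) / (1 - A)
    expect_lt(abs(eps_back - p$eps), 1e-4)
    # inversion self-consistency in x
    expect_lt(abs(eps_to_massfraction(p$eps, calib)$x_gly - p$x_gly), 1e-4)
  }
})

test_that("permittivity inversion round-trips and matches the grid oracle", {
  calib <- glycine_calibration()
  tab <- glycine_density_table()
  # round trip x -> eps -> x
  xs <- seq(0, 0.7, by = 0.05)
  eps_fwd <- sprgamma:::massfraction_to_eps(xs, calib)
  x_back <- eps_to_massfraction(eps_fwd, calib)$x_gly
  expect_equal(x_back, xs, tolerance = 1e-8)
  # monotone in eps
  expect_true(all(diff(eps_to_massfraction(seq(1.78, 2.4, by = 0.01),
                                           calib)$x_gly) > 0))
  # dense-grid oracle: forward model evaluated at 1e-6 steps
  xg <- seq(0, 1, by = 1e-6)
  Fg <- cm_forward_grid(xg, calib, tab)
  expect_true(all(diff(Fg) > 0))
  set.seed(99)
  eps_r <- runif(100, 1.80, 2.35)
  x_root <- eps_to_massfraction(eps_r, calib)$x_gly
  idx <- findInterval(cm_fraction(eps_r), Fg)
  x_grid <- xg[pmax(1, idx)]
  expect_lt(max(abs(x_root - x_grid)), 2e-6)
  # below-water permittivities flag rather than error
  low <- eps_to_massfraction(1.70, calib)
  expect_identical(low$x_gly, 0)
  expect_true(low$below_water)
})

test_that("number-density and unit conversions reproduce the printed arithmetic", {
  expect_equal(mass_to_number_density(1.6), 12.8, tolerance = 0.01)
  expect_equal(mass_to_number_density(0), 0)
  expect_equal(mass_to_number_density(0.5), 4.0, tolerance = 0.01)
  expect_error(mass_to_number_density(1, molar_mass = -5),
               class = "sprgamma_domain_error")
  expect_error(mass_to_number_density(-1), class = "sprgamma_domain_error")
  expect_equal(convert_gamma_units(50), 5e-13)
  expect_equal(convert_gamma_units(0), 0)
  expect_equal(convert_gamma_units(1e14), 1)
})

test_that("the bulk solution at 250 g/kg holds ~1.7 glycine molecules per nm^3", {
  x <- 250 / 1250
  n <- mass_to_number_density(density_of_solution(x) * x)
  expect_equal(round(n, 1), 1.7)
})

test_that("gamma is zero without contrast, signed, monotone and in the printed band", {
  g0 <- gamma_excess(1.8489, 1.8489, 1)
  expect_equal(g0$gamma_ng_cm2, 0, tolerance = 1e-9)
  # sign follows the permittivity contrast
  expect_gt(gamma_excess(1.90, 1.8489, 1)$gamma_ng_cm2, 0)
  expect_lt(gamma_excess(1.80, 1.8489, 1)$gamma_ng_cm2, 0)
  # monotone in eps_interf at fixed bulk and t
  gs <- vapply(c(1.9, 2.0, 2.1, 2.2), function(e) {
    gamma_excess(e, 1.8489, 1)$gamma_ng_cm2
  }, numeric(1))
  expect_true(all(diff(gs) > 0))
  # the averaged interfacial permittivity at 176 g/kg on gold
  g <- gamma_excess(2.0717, 1.8489, 1)
  expect_gte(g$gamma_ng_cm2, 40)
  expect_lte(g$gamma_ng_cm2, 60)
  expect_equal(g$gamma_ng_nm2, g$gamma_ng_cm2 * 1e-14)
})

test_that("gamma from fits of one scan is invariant to the assumed thickness", {
  chip <- default_chip()
  sc <- default_scan(eps_bulk = 1.8489, layer = c(2.1070, 1))
  G <- vapply(c(0.5, 1, 2), function(t) {
    f <- fit_interfacial_eps(sc, chip, 1.8489, t_nm = t)
    gamma_excess(f$eps_interf, f$eps_bulk, t)$gamma_ng_cm2
  }, numeric(1))
  expect_lt((max(G) - min(G)) / mean(G), 0.05)
})
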