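test_that("no index contrast means no reflection, lossless TIR means total reflection", {
  same <- layer_stack(tibble::tibble(
    label = c("prism", "bulk"), eps = c(1.8489, 1.8489),
    thickness_nm = NA_real_))
  for (a in c(10, 45, 70, 89)) {
    expect_equal(reflectivity_tm(same, a), 0, tolerance = 1e-12)
  }
  pair <- layer_stack(tibble::tibble(
    label = c("prism", "bulk"), eps = c(3.1948, 1.7770),
    thickness_nm = NA_real_))
  crit <- tir_angle_analytic(3.1948, 1.7770)
  beyond <- reflectivity_tm(pair, seq(crit + 0.5, 85, by = 5))
  expect_true(all(abs(beyond - 1) <= 1e-9))
  below <- reflectivity_tm(pair, seq(5, crit - 0.5, by = 5))
  expect_true(all(below < 1))
})

test_that("transfer matrix matches the Airy two-interface closed form", {
  cc <- chip_constants()
  grid <- seq(40, 80, by = 0.5)
  st <- default_chip()
  tm <- reflectivity_tm(st, grid)
  airy <- vapply(grid, function(a) {
    airy_reflectivity(cc$eps_prism, cc$eps_metal, 1.8489 + 0i,
                      cc$d_metal_nm, cc$wavelength_nm, a)
  }, numeric(1))
  expect_true(max(abs(tm - airy)) <= 1e-12)

  # random 3-layer stacks
  set.seed(11)
  for (i in 1:25) {
    e1 <- runif(1, 2, 4)
    e2 <- complex(real = runif(1, -12, 3), imaginary = runif(1, 0, 3))
    e3 <- runif(1, 1, 2.5)
    d <- runif(1, 2, 120)
    st <- layer_stack(tibble::tibble(
      label = c("prism", "film", "bulk"), eps = c(e1, e2, e3),
      thickness_nm = c(NA, d, NA)), wavelength_nm = 632.8)
    a <- runif(1, 5, 85)
    expect_equal(reflectivity_tm(st, a),
                 airy_reflectivity(e1 + 0i, e2, e3 + 0i, d, 632.8, a),
                 tolerance = 1e-12)
  }
})

test_that("reflectivity respects the energy bound on random absorbing stacks", {
  set.seed(21)
  for (i in 1:40) {
    st <- random_valid_stack()
    R <- reflectivity_tm(st, runif(5, 1, 89))
    expect_true(all(R >= 0 & R <= 1 + 1e-12))
  }
})

test_that("splitting an internal layer into sublayers leaves R unchanged", {
  set.seed(31)
  for (i in 1:10) {
    e2 <- complex(real = runif(1, -12, 3), imaginary = runif(1, 0, 2))
    d <- runif(1, 10, 80)
    f <- runif(1, 0.1, 0.9)
    whole <- layer_stack(tibble::tibble(
      label = c("p", "m", "b"), eps = c(3.2, e2, 1.8),
      thickness_nm = c(NA, d, NA)))
    split <- layer_stack(tibble::tibble(
      label = c("p", "m1", "m2", "b"), eps = c(3.2, e2, e2, 1.8),
      thickness_nm = c(NA, f * d, (1 - f) * d, NA)))
    a <- runif(4, 5, 85)
    expect_equal(reflectivity_tm(whole, a), reflectivity_tm(split, a),
                 tolerance = 1e-12)
  }
})

test_that("R + T = 1 for lossless dielectric stacks below the critical angle", {
  st <- layer_stack(tibble::tibble(
    label = c("prism", "a", "b", "bulk"),
    eps = c(3.2, 2.5, 2.0, 1.9),
    thickness_nm = c(NA, 100, 50, NA)))
  ang <- seq(5, 45, by = 2.5)  # below the bulk critical angle ~50.4 deg
  total <- reflectivity_tm(st, ang) + transmittance_tm(st, ang)
  expect_true(all(abs(total - 1) <= 1e-9))
})

test_that("analytic TIR angle handles anchors, limits and error cases", {
  expect_equal(tir_angle_analytic(4, 1), 30, tolerance = 1e-12)
  # any prism whose bulk is eps_prism * sin^2(49.53 deg) gives 49.53 deg
  for (ep in c(2.5, 3.1947, 4)) {
    expect_equal(tir_angle_analytic(ep, ep * sin(49.53 * pi / 180)^2), 49.53,
                 tolerance = 1e-10)
  }
  expect_gt(tir_angle_analytic(3.2, 3.2 * (1 - 1e-10)), 89.99)
  expect_error(tir_angle_analytic(1.8, 1.9), class = "sprgamma_no_tir_error")
  expect_error(tir_angle_analytic(2, -1), class = "sprgamma_domain_error")
})

test_that("simulated scans carry provenance and reproduce analytic features", {
  same <- layer_stack(tibble::tibble(
    label = c("prism", "bulk"), eps = c(2.0, 2.0), thickness_nm = NA_real_))
  sc <- simulate_scan(same, seq(40, 60, by = 1))
  expect_s3_class(sc, "angle_scan")
  expect_identical(scan_metadata(sc)$source, "synthetic")
  expect_true(all(sc$reflectivity == 0))

  # metal-coated stack: extracted edge equals the analytic critical angle
  cc <- chip_constants()
  sc2 <- default_scan(eps_bulk = 1.8489)
  edge <- find_tir_edge(sc2)
  expect_equal(as.numeric(edge),
               tir_angle_analytic(cc$eps_prism, 1.8489), tolerance = 0.01)

  # a 1 nm high-permittivity layer shifts the minimum to larger angles
  sc3 <- default_scan(eps_bulk = 1.8489, layer = c(2.1070, 1))
  expect_gt(as.numeric(find_spr_minimum(sc3)),
            as.numeric(find_spr_minimum(sc2)))
})

test_that("invalid stacks and angles are rejected", {
  expect_error(layer_stack(tibble::tibble(
    label = "one", eps = 2 + 0i, thickness_nm = NA_real_)),
    class = "sprgamma_config_error")
  expect_error(layer_stack(tibble::tibble(
    label = c("p", "m", "b"), eps = c(3.2, -11 - 1i, 1.8),
    thickness_nm = c(NA, 40, NA))), class = "sprgamma_config_error")
  expect_error(layer_stack(tibble::tibble(
    label = c("p", "m", "b"), eps = c(3.2, -11 + 1i, 1.8),
    thickness_nm = c(NA, -5, NA))), class = "sprgamma_config_error")
  st <- default_chip()
  expect_error(reflectivity_tm(st, 0), class = "sprgamma_domain_error")
  expect_error(reflectivity_tm(st, 95), class = "sprgamma_domain_error")
  expect_error(simulate_scan(st, c(50, 49, 51)),
               class = "sprgamma_domain_error")
})
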