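test_that("a uniform slab bins to its closed-form density and conserves mass", {
  set.seed(5)
  N <- 4000
  L <- 5
  area <- 16
  M <- 18.015
  frames <- tibble::tibble(frame = 1L, z_nm = runif(N, 0, L),
                           species = "solvent", mass_g_mol = M)
  prof <- bin_density_profile(frames, area_nm2 = area, bin_width_nm = 0.05,
                              z_max_nm = L)
  # conservation: sum(density x bin volume) equals the inserted mass exactly
  total <- sum(prof$density_g_cm3) * area * 0.05 * 1e-21 * 6.02214076e23
  expect_equal(total, N * M, tolerance = 1e-12)
  # interior bins fluctuate around the closed-form uniform density
  rho_exact <- M * N / (area * L * 1e-21 * 6.02214076e23)
  expect_equal(mean(prof$density_g_cm3), rho_exact, tolerance = 0.01)
})

test_that("binning validates its inputs", {
  f <- tibble::tibble(z_nm = 1, species = "solvent", mass_g_mol = 18)
  expect_error(bin_density_profile(f[0, ], area_nm2 = 10),
               class = "sprgamma_domain_error")
  expect_error(bin_density_profile(f, area_nm2 = -1),
               class = "sprgamma_domain_error")
  expect_error(
    bin_density_profile(dplyr::mutate(f, z_nm = -0.2), area_nm2 = 10),
    class = "sprgamma_domain_error")
})

test_that("particles sampled from a target profile reproduce it within counting error", {
  parts <- synth_profile(8.80, as_particles = TRUE, n_frames = 20, seed = 17,
                         area_nm2 = 25)
  prof <- bin_density_profile(parts, area_nm2 = attr(parts, "area_nm2"))
  target <- synth_profile(8.80, area_nm2 = 25)
  joined <- dplyr::inner_join(
    as.data.frame(prof), as.data.frame(target),
    by = c("z_nm", "species"), suffix = c("_hat", "_true"))
  # binomial sampling error per bin: sd ~ rho_true / sqrt(count in bin)
  n_frames <- 20
  count <- joined$density_g_cm3_true * 25 * 0.05 * 1e-21 * 6.02214076e23 /
    ifelse(joined$species == "solute", 75.07, 18.015) * n_frames
  tol <- 5 * joined$density_g_cm3_true / sqrt(pmax(count, 1)) + 0.02
  expect_true(all(abs(joined$density_g_cm3_hat - joined$density_g_cm3_true) <=
                    tol))
})

test_that("film width recovers the generating widths of the film family", {
  for (w in c(2.55, 4.65, 8.80, 12.95)) {
    prof <- synth_profile(w)
    expect_equal(film_width(prof), w, tolerance = 0.05 / w)
  }
  # monotone in film size
  widths <- vapply(c(2.55, 4.65, 8.80, 12.95),
                   function(w) film_width(synth_profile(w)), numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("film width handles degenerate profiles with flags", {
  z <- seq(0.025, 5, by = 0.05)
  zero <- density_profile(
    tibble::tibble(z_nm = z, species = "solvent", density_g_cm3 = 0))
  expect_equal(film_width(zero), 0)
  # threshold above the plateau
  low <- density_profile(
    tibble::tibble(z_nm = z, species = "solvent", density_g_cm3 = 0.15))
  w <- film_width(low, solvent_threshold = 0.5)
  expect_equal(as.numeric(w), 0)
  expect_identical(attr(w, "flag"), "threshold_above_bulk")
  # solvent never below threshold: full extent, flagged
  full <- density_profile(
    tibble::tibble(z_nm = z, species = "solvent", density_g_cm3 = 1))
  w2 <- film_width(full)
  expect_equal(as.numeric(w2), 5, tolerance = 1e-9)
  expect_identical(attr(w2, "flag"), "no_edge")
})

test_that("interfacial averages weight bins by overlap", {
  z <- seq(0.025, 3, by = 0.05)
  flat <- density_profile(
    tibble::tibble(z_nm = z, species = "solute", density_g_cm3 = 0.7))
  expect_equal(interfacial_average(flat, "solute", c(0, 1)), 0.7)
  expect_equal(interfacial_average(flat, "solute", c(0.31, 2.47)), 0.7)
  # a single-bin window returns that bin's density
  ramp <- density_profile(
    tibble::tibble(z_nm = z, species = "solute", density_g_cm3 = z))
  expect_equal(interfacial_average(ramp, "solute", c(0.05, 0.10)), 0.075)
  expect_error(interfacial_average(ramp, "solute", c(2.5, 3.5)),
               class = "sprgamma_domain_error")
})

test_that("the calibrated thick film averages 1.0 g/cm^3 over the first nm", {
  prof <- synth_profile(12.95, interfacial_target = 1.0)
  expect_equal(interfacial_average(prof, "solute", c(0, 1)), 1.0,
               tolerance = 0.01)
})

test_that("surface excess matches closed forms and the quadrature oracle", {
  z <- seq(0.025, 6, by = 0.05)
  flat <- density_profile(
    tibble::tibble(z_nm = z, species = "solute", density_g_cm3 = 0.4))
  expect_equal(profile_surface_excess(flat, "solute", c(3, 5)), 0,
               tolerance = 1e-12)
  # rectangular excess of height 0.5 over the first 1 nm above a 0.2 bulk
  rect <- density_profile(
    tibble::tibble(z_nm = z, species = "solute",
                   density_g_cm3 = ifelse(z < 1, 0.7, 0.2)))
  expect_equal(profile_surface_excess(rect, "solute", c(3, 5)),
               0.5 * 1 * 100, tolerance = 1e-9)
  # synthetic film vs the independent direct-sum oracle
  prof <- synth_profile(12.95)
  sub <- prof[prof$species == "solute", ]
  expect_equal(
    profile_surface_excess(prof, "solute", c(4, 8)),
    surface_excess_oracle(sub$z_nm, sub$density_g_cm3, 0.05, 4, 8),
    tolerance = 1e-10)
  expect_error(profile_surface_excess(prof, "solute", c(12, 15)),
               class = "sprgamma_domain_error")
})

test_that("surface excess is insensitive to the bulk-region choice on a plateau", {
  prof <- synth_profile(12.95)
  g1 <- profile_surface_excess(prof, "solute", c(3, 6))
  g2 <- profile_surface_excess(prof, "solute", c(5, 9))
  expect_lt(abs(g1 - g2) / abs(g1), 0.02)
})

test_that("halving the bin width barely moves the interfacial average", {
  coarse <- synth_profile(8.80, bin_width_nm = 0.05)
  fine <- synth_profile(8.80, bin_width_nm = 0.025)
  expect_lt(abs(interfacial_average(coarse, "solute", c(0, 1)) -
                  interfacial_average(fine, "solute", c(0, 1))), 0.005)
})
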