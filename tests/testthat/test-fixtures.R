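test_that("synthetic fields are seed-deterministic", {
  spec <- synthetic_field_spec(list(c(2, 0, 1)), noise_sd = 0.05, seed = 7,
                               sample_density = 500)
  f1 <- make_displacement_with_known_aberration(spec)
  f2 <- make_displacement_with_known_aberration(spec)
  expect_identical(f1$displacements, f2$displacements)
  f3 <- make_displacement_with_known_aberration(
    synthetic_field_spec(list(c(2, 0, 1)), noise_sd = 0.05, seed = 8,
                         sample_density = 500))
  expect_false(identical(f1$displacements, f3$displacements))
})

test_that("known-aberration generator round-trips through the pipeline", {
  modes <- list(c(2, 0, 1.0), c(3, -1, 0.25), c(4, 0, 0.4), c(5, 5, -0.1))
  spec <- synthetic_field_spec(modes, sample_density = 1500, noise_sd = 0)
  f <- make_displacement_with_known_aberration(spec)
  sp <- fit_zernike(field_to_wavefront(f, surface_sphere(spec$base_radius),
                                       spec$pupil_radius, spec$delta_n))
  for (m in modes) expect_equal(zcoef(sp, m[1], m[2]), m[3], tolerance = 1e-6)
  injected <- vapply(modes, function(m) sprintf("Z(%d,%d)", m[1], m[2]), "")
  rest <- sp$coefficients[!names(sp$coefficients) %in% injected]
  expect_lt(max(abs(rest)), 1e-6)
  # empty mode list -> zero field -> zero spectrum
  f0 <- make_displacement_with_known_aberration(
    synthetic_field_spec(sample_density = 400))
  sp0 <- fit_zernike(field_to_wavefront(f0, surface_sphere(7.7), 3, 0.376))
  expect_lt(max(abs(sp0$coefficients)), 1e-12)
})

test_that("noisy recovery stays within propagated standard errors", {
  # Monte-Carlo standard-error oracle over many seeds
  modes <- list(c(4, 0, 0.3), c(3, -1, 0.1))
  nseed <- 120
  rec <- matrix(NA_real_, nseed, 2)
  for (s in seq_len(nseed)) {
    f <- make_displacement_with_known_aberration(
      synthetic_field_spec(modes, sample_density = 1200, noise_sd = 0.01,
                           seed = s))
    sp <- fit_zernike(field_to_wavefront(f, surface_sphere(7.7), 3, 0.376))
    rec[s, ] <- c(zcoef(sp, 4, 0), zcoef(sp, 3, -1))
  }
  se <- apply(rec, 2, sd)
  bias <- colMeans(rec) - c(0.3, 0.1)
  # unbiased to within Monte-Carlo error, and a single draw sits within 3 SE
  expect_true(all(abs(bias) < 4 * se / sqrt(nseed)))
  expect_lt(abs(rec[1, 1] - 0.3), 3 * se[1])
  expect_lt(abs(rec[1, 2] - 0.1), 3 * se[2])
})

test_that("shell meshes are watertight with convergent wall volume", {
  # chord-faceted spheres underestimate the wall volume; the deficit is set
  # by the angular resolution and must shrink under refinement
  vol_exact <- 4 / 3 * pi * (7.7^3 - 7.2^3)
  errs <- vapply(1:3, function(r) {
    sh <- make_shell_mesh(7.2, 0.5, r)
    check_watertight(sh)
    abs(mesh_volume(sh) / vol_exact - 1)
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[1], 0.06)
  expect_lt(errs[2], 0.03)
  expect_lt(errs[3], 0.015)
  expect_error(make_shell_mesh(5, 6), "thickness")
  expect_error(make_shell_mesh(-1, 0.5), "positive")
})

test_that("radial inflation field has the analytic near-defocus spectrum", {
  f0 <- make_radial_inflation_field(7.7, 0, 500)
  expect_equal(max(abs(f0$displacements)), 0)
  # at the exact apex the radial step is purely axial: D = delta
  expect_equal(axial_sag_displacement(c(0, 0, 7.7), c(0, 0, 0.01), 7.7),
               0.01)
  # the sampled node closest to the apex is a whisker off-axis
  f <- make_radial_inflation_field(7.7, 0.01, 2000)
  apex <- which.min(rowSums(f$node_coords[, 1:2]^2))
  D <- axial_sag_displacement(f$node_coords[apex, ], f$displacements[apex, ],
                              7.7)
  expect_equal(D, 0.01, tolerance = 1e-4)
  sp <- fit_zernike(field_to_wavefront(f, surface_sphere(7.7), 3, 0.376))
  # piston and defocus dominate; defocus sign fixed by the geometry:
  # the sag correction R/sqrt(R^2-rho^2) grows off-axis, so OPD increases
  # with rho and the defocus coefficient is positive
  expect_gt(zcoef(sp, 2, 0), 0)
  pd <- abs(c(zcoef(sp, 0, 0), zcoef(sp, 2, 0)))
  rest <- sqrt(sum(sp$coefficients^2) - sum(pd^2))
  expect_lt(rest, 0.05 * sqrt(sum(pd^2)))
  expect_error(make_radial_inflation_field(7.7, 3), "small")
})
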