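test_that("Zernike basis is orthonormal over the unit disk", {
  modes <- zernike_modes(5)
  expect_equal(nrow(modes), 21)
  expect_equal(modes$j, 0:20)
  # quadrature on a fine polar grid (area-weighted inner product)
  nr <- 200; nt <- 256
  r <- sqrt((seq_len(nr) - 0.5) / nr)
  t <- 2 * pi * (seq_len(nt) - 0.5) / nt
  g <- expand.grid(r = r, t = t)
  x <- g$r * cos(g$t); y <- g$r * sin(g$t)
  pick <- c(1, 5, 13, 18, 21)  # piston, defocus, SA, a coma, a pentafoil
  Z <- vapply(pick, function(i) zernike_eval(modes$n[i], modes$m[i], x, y),
              numeric(length(x)))
  G <- crossprod(Z) / length(x)
  expect_equal(G, diag(length(pick)), tolerance = 1e-3)
})

test_that("axial sag displacement collapses and evaluates exactly", {
  # purely axial motion
  expect_equal(axial_sag_displacement(c(1, 0.5, 7.6), c(0, 0, 0.02), 7.7),
               0.02)
  # apex point with axial delta
  expect_equal(axial_sag_displacement(c(0, 0, 7.7), c(0, 0, 0.005), 7.7),
               0.005)
  # frozen oracle: direct evaluation of the sag-difference formula
  expect_equal(
    axial_sag_displacement(c(2, 0, sqrt(7.7^2 - 4)), c(0.01, 0, 0.005), 7.7),
    0.0076969311, tolerance = 1e-8)
  expect_error(axial_sag_displacement(c(8, 0, 0), c(0, 0, 0), 7.7),
               "outside")
})

test_that("OPD conversion is the index step times displacement in um", {
  expect_equal(opd_from_displacement(0, 0.376), 0)
  expect_equal(opd_from_displacement(0.01, 0.376), 3.76)
  expect_equal(opd_from_displacement(0.01, 0.040), 0.40)
})

test_that("Zernike fitting recovers injected modes to machine precision", {
  pts <- eyefem:::sunflower_disk(600, 2.5)
  xs <- pts[, 1] / 2.5; ys <- pts[, 2] / 2.5
  w <- 0.7 * zernike_eval(3, -1, xs, ys)
  sp <- fit_zernike(wavefront_map(pts, w, 2.5))
  expect_equal(zcoef(sp, 3, -1), 0.7, tolerance = 1e-9)
  others <- sp$coefficients[!(sp$n == 3 & sp$m == -1)]
  expect_lt(max(abs(others)), 1e-9)
  # zero map
  sp0 <- fit_zernike(wavefront_map(pts, numeric(nrow(pts)), 2.5))
  expect_lt(max(abs(sp0$coefficients)), 1e-12)
  # rho^2 map: piston 1/2, defocus 1/(2 sqrt(3)), analytic inner products
  sp2 <- fit_zernike(wavefront_map(pts, xs^2 + ys^2, 2.5))
  expect_equal(zcoef(sp2, 0, 0), 0.5, tolerance = 1e-6)
  expect_equal(zcoef(sp2, 2, 0), 1 / (2 * sqrt(3)), tolerance = 1e-6)
  expect_lt(max(abs(sp2$coefficients[-c(1, 5)])), 1e-6)
  # under-sampled designs are refused
  expect_error(fit_zernike(wavefront_map(pts[1:30, ], numeric(30), 2.5)),
               "sample")
})

test_that("induced aberration is a guarded coefficient-wise difference", {
  pts <- eyefem:::sunflower_disk(300, 3)
  w1 <- zernike_eval(2, 0, pts[, 1] / 3, pts[, 2] / 3)
  s1 <- fit_zernike(wavefront_map(pts, w1, 3))
  s2 <- fit_zernike(wavefront_map(pts, 2 * w1, 3))
  d <- induced_aberration(s2, s1)
  expect_equal(zcoef(d, 2, 0), 1, tolerance = 1e-9)
  # post = pre -> zero
  expect_lt(max(abs(induced_aberration(s1, s1)$coefficients)), 1e-12)
  # mismatched pupils refuse silently rescaling
  pts2 <- eyefem:::sunflower_disk(300, 3.5)
  s3 <- fit_zernike(wavefront_map(
    pts2, zernike_eval(2, 0, pts2[, 1] / 3.5, pts2[, 2] / 3.5), 3.5))
  expect_error(induced_aberration(s3, s1), "pupil")
})

test_that("defocus-to-diopter conversion has the right scale and sign", {
  expect_equal(defocus_to_diopters(0, 3), 0)
  # arithmetic: -4 sqrt(3) * (-1.146) / 9
  expect_equal(defocus_to_diopters(-1.146, 3), 0.8821912, tolerance = 1e-6)
  # negative induced defocus is a hyperopic (positive) shift
  expect_gt(defocus_to_diopters(-0.5, 3), 0)
})

test_that("RMS is the root-sum-square over selected orders", {
  sp <- zernike_spectrum(c(9, 0.5, 3, 4), n = c(0, 2, 3, 4),
                         m = c(0, 0, 1, 0), pupil_radius = 3)
  expect_equal(rms_of(sp, orders = 2), 0.5)
  expect_equal(rms_of(sp, orders = 3:4), 5)   # 3-4-5 triangle
  expect_equal(rms_of(sp, orders = integer(0)), 0)
  # piston excluded by default
  expect_equal(rms_of(sp), sqrt(0.25 + 9 + 16))
})

test_that("the displacement-to-spectrum pipeline is linear in the field", {
  spec <- synthetic_field_spec(list(c(2, 0, 0.8), c(3, -1, 0.3),
                                    c(4, 0, -0.2)),
                               sample_density = 800)
  f <- make_displacement_with_known_aberration(spec)
  s1 <- fit_zernike(field_to_wavefront(f, surface_sphere(7.7), 3, 0.376))
  f2 <- f
  f2$displacements <- f$displacements * 0.37
  s2 <- fit_zernike(field_to_wavefront(f2, surface_sphere(7.7), 3, 0.376))
  expect_equal(s2$coefficients, 0.37 * s1$coefficients, tolerance = 1e-6)
})

test_that("rotating the field permutes coefficients per Zernike rules", {
  spec <- synthetic_field_spec(list(c(3, 1, 0.5)), sample_density = 900)
  f <- make_displacement_with_known_aberration(spec)
  # rotate sample positions by +90 degrees about the optical axis
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  f_rot <- f
  f_rot$node_coords <- f$node_coords %*% t(R90)
  f_rot$displacements <- f$displacements %*% t(R90)
  s <- fit_zernike(field_to_wavefront(f_rot, surface_sphere(7.7), 3, 0.376))
  # cos(theta) coma rotated by 90 degrees becomes sin(theta) coma
  expect_equal(zcoef(s, 3, -1), 0.5, tolerance = 1e-6)
  expect_lt(abs(zcoef(s, 3, 1)), 1e-6)
})

test_that("spectra round-trip through JSON serialisation", {
  pts <- eyefem:::sunflower_disk(400, 3)
  w <- 0.8 * zernike_eval(4, 0, pts[, 1] / 3, pts[, 2] / 3)
  sp <- fit_zernike(wavefront_map(pts, w, 3))
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_spectrum(sp, tf)
  back <- read_spectrum(tf)
  expect_equal(back$coefficients, sp$coefficients, tolerance = 1e-12)
  expect_equal(back$pupil_radius, sp$pupil_radius)
  expect_identical(back$normalization, sp$normalization)
})
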