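test_that("strain energy evaluates the Ogden potential correctly", {
  corn <- baseline_cornea()
  # reference state carries no energy
  expect_equal(strain_energy(corn, c(1, 1, 1)), 0)
  # frozen scalar oracle: equibiaxial 1% stretch of the fitted cornea
  expect_equal(strain_energy(corn, c(1.01, 1.01, 1.01^-2)),
               1.865143e-4, tolerance = 1e-5)
  # hand arithmetic for a one-term material at large uniaxial stretch:
  # (2/2) * (4 + 0.5 + 0.5 - 3) = 2
  nh <- ogden_material(mu = 2, alpha = 2)
  expect_equal(strain_energy(nh, c(2, 1 / sqrt(2), 1 / sqrt(2))), 2)
  expect_error(strain_energy(corn, c(-1, 1, 1)), "positive")
  expect_error(strain_energy(corn, c(1.1, 1, 1)), "J = 1")
  expect_error(strain_energy(corn, c(1, 1, 1), J = 1.1), "product")
  # compressible variant: a pure dilation carries only volumetric energy
  cm <- ogden_material(mu = 2, alpha = 2, d1 = 0.5)
  lam <- 1.1^(1 / 3)
  expect_equal(strain_energy(cm, c(lam, lam, lam)),
               (1 / 0.5) * 0.1^2, tolerance = 1e-9)
})

test_that("strain energy is positive away from the reference state", {
  set.seed(42)
  for (mat in list(baseline_cornea(), baseline_sclera(),
                   material_cases(1)$cornea, material_cases(4)$sclera)) {
    for (i in 1:25) {
      l1 <- runif(1, 0.8, 1.25)
      l2 <- runif(1, 0.8, 1.25)
      l3 <- 1 / (l1 * l2)
      if (max(abs(c(l1, l2, l3) - 1)) < 1e-6) next
      expect_gt(strain_energy(mat, c(l1, l2, l3)), 0)
    }
  }
})

test_that("initial moduli match the closed-form definitions", {
  expect_equal(initial_shear_modulus(baseline_cornea()), 0.3660846,
               tolerance = 1e-6)
  expect_equal(initial_shear_modulus(baseline_sclera()), 2.761416,
               tolerance = 1e-6)
  expect_equal(initial_shear_modulus(ogden_material(2, 2)), 2)
  expect_identical(initial_bulk_modulus(baseline_cornea()), Inf)
  expect_equal(initial_bulk_modulus(ogden_material(2, 2, d1 = 0.5)), 4)
  expect_equal(initial_bulk_modulus(ogden_material(2, 2, d1 = 2)), 1)
})

test_that("uniaxial stress matches hand arithmetic and stiffens strongly", {
  nh <- ogden_material(mu = 1, alpha = 2)
  expect_equal(uniaxial_stress(nh, 1), 0)
  expect_equal(uniaxial_stress(nh, 1.1), 0.3009091, tolerance = 1e-6)
  corn <- baseline_cornea()
  # alpha ~ 103: doubling the strain more than triples the stress
  # (exponential stiffening; a linear material would give a factor ~2)
  expect_gt(uniaxial_stress(corn, 1.02) / uniaxial_stress(corn, 1.01), 3)
  # small-strain limit: sigma / eps -> 3 mu
  eps <- 1e-6
  expect_equal(uniaxial_stress(corn, 1 + eps) / eps,
               3 * initial_shear_modulus(corn), tolerance = 1e-3)
  expect_error(uniaxial_stress(ogden_material(1, 2, d1 = 1), 1.1),
               "incompressible")
})

test_that("operating-point tangent modulus behaves like a stiffening solid", {
  m3 <- material_cases(3)$cornea
  # zero pressure reduces to the small-strain Young modulus 3 mu
  expect_equal(tangent_modulus_at_iop(m3, 7.7, 0.5, 0),
               3 * initial_shear_modulus(m3), tolerance = 1e-9)
  # tangent at pressure exceeds the initial modulus (strain stiffening)
  expect_gt(tangent_modulus_at_iop(m3, 7.7, 0.5, 15),
            3 * initial_shear_modulus(m3))
  # increasing alpha at fixed mu*alpha stiffens the operating point
  ref <- 0.012 * 88.684
  Es <- vapply(c(50, 100, 200, 400), function(a) {
    tangent_modulus_at_iop(ogden_material(ref / a, a), 7.7, 0.5, 15)
  }, 0)
  expect_true(all(diff(Es) > 0))
})

test_that("bundled stiffness cases load, validate and round-trip", {
  cs <- material_cases()
  expect_length(cs, 8)
  c3 <- material_cases(3)
  expect_equal(c3$cornea$mu, 0.0120)
  expect_equal(c3$cornea$alpha, 88.684)
  expect_equal(c3$sclera$mu, 0.0302)
  expect_equal(c3$sclera$alpha, 182.73)
  expect_equal(c3$nominal_E_cornea, 0.974)
  # sclera held constant across cases 5-8
  for (k in 6:8) {
    expect_identical(material_cases(k)$sclera$mu, cs[["5"]]$sclera$mu)
    expect_identical(material_cases(k)$sclera$alpha, cs[["5"]]$sclera$alpha)
  }
  # every case is a valid incompressible material
  for (k in 1:8) {
    expect_true(all(cs[[as.character(k)]]$cornea$mu *
                      cs[[as.character(k)]]$cornea$alpha > 0))
    expect_identical(cs[[as.character(k)]]$cornea$d1, 0)
  }
  expect_error(material_cases(9), "unknown")
  # serialisation round trip is bit-exact
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  plain <- lapply(cs, function(x) {
    list(cornea = unclass(x$cornea)[c("mu", "alpha", "d1")],
         sclera = unclass(x$sclera)[c("mu", "alpha", "d1")])
  })
  jsonlite::write_json(plain, tf, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(tf, simplifyVector = FALSE)
  for (k in 1:8) {
    expect_identical(as.numeric(unlist(back[[k]]$cornea$mu)),
                     cs[[as.character(k)]]$cornea$mu)
    expect_identical(as.numeric(unlist(back[[k]]$cornea$alpha)),
                     cs[[as.character(k)]]$cornea$alpha)
  }
})

test_that("material constructor rejects inconsistent parameters", {
  expect_error(ogden_material(c(1, 2), 2), "length")
  expect_error(ogden_material(1, -2), "positive stiffness")
  expect_error(ogden_material(1, 2, d1 = -1), "non-negative")
})
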