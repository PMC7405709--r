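test_that("closed-form shell inflation has the correct limits", {
  mat <- baseline_cornea()
  expect_equal(as.numeric(closed_form_sphere_inflation(mat, 7.2, 7.7, 0)), 1)
  # thin-shell small-strain asymptote: equibiaxial membrane modulus 6 mu
  # gives lambda - 1 ~ P r / (12 t mu)
  nh <- ogden_material(0.5, 2)
  P <- 1e-4
  lam <- as.numeric(closed_form_sphere_inflation(nh, 10, 10.1, P))
  est <- P * 10.05 / (12 * 0.1 * 0.5)
  expect_lt(abs((lam - 1) / est - 1), 0.05)
  # inner stretch strictly increases with pressure
  lams <- vapply(seq(1e-5, 6e-4, length.out = 8), function(p) {
    as.numeric(closed_form_sphere_inflation(nh, 10, 10.1, p))
  }, 0)
  expect_true(all(diff(lams) > 0))
  expect_error(closed_form_sphere_inflation(ogden_material(1, 2, d1 = 1),
                                            7, 8, 1e-4), "incompressible")
})

test_that("zero pressure yields the unloaded equilibrium", {
  sh <- make_shell_mesh(5, 0.5, 1)
  sol <- solve_inflation(sh, baseline_cornea(), baseline_sclera(),
                         solve_config(iop = 0, load_steps = 1))
  expect_lt(max(abs(sol$u)), 1e-12)
})

test_that("the assembled tangent matches a directional derivative", {
  sh <- make_shell_mesh(3, 0.6, 1)
  mat <- list(mu = baseline_cornea()$mu, alpha = baseline_cornea()$alpha,
              kappa = 100)
  n <- nrow(sh$nodes)
  set.seed(11)
  u <- rnorm(3 * n, sd = 1e-3)
  d <- rnorm(3 * n); d <- d / sqrt(sum(d^2))
  ep <- matrix(integer(0), 0, 2); en <- matrix(0, 0, 3)
  asm <- eyefem:::fem_assemble(sh$nodes, sh$elems, sh$elem_region, u,
                               list(mat, mat), sh$cavity_facets, 0.001,
                               ep, en, numeric(0), 0L, TRUE, 1e-6)
  K <- Matrix::sparseMatrix(i = asm$ti, j = asm$tj, x = asm$tx,
                            dims = c(3 * n, 3 * n))
  h <- 1e-6
  rp <- with(eyefem:::fem_assemble(sh$nodes, sh$elems, sh$elem_region,
                                   u + h * d, list(mat, mat),
                                   sh$cavity_facets, 0.001, ep, en,
                                   numeric(0), 0L, FALSE, 1e-6),
             fext - fint)
  rm_ <- with(eyefem:::fem_assemble(sh$nodes, sh$elems, sh$elem_region,
                                    u - h * d, list(mat, mat),
                                    sh$cavity_facets, 0.001, ep, en,
                                    numeric(0), 0L, FALSE, 1e-6),
              fext - fint)
  jd_fd <- (rp - rm_) / (2 * h)
  jd_K <- -as.numeric(K %*% d)   # K approximates -d(residual)/du
  expect_lt(sqrt(sum((jd_fd - jd_K)^2)) / sqrt(sum(jd_fd^2)), 1e-4)
})

test_that("FEM shell inflation matches the closed-form oracle", {
  # production-resolution comparison of the fitted radius change, plus
  # refinement behaviour (coarse error already small, finer smaller)
  st1 <- shell_oracle_state(1)
  st2 <- shell_oracle_state(2)
  u_ref <- attr(st1$oracle, "u_outer")
  e1 <- abs(shell_radius_change(st1) / u_ref - 1)
  e2 <- abs(shell_radius_change(st2) / u_ref - 1)
  expect_lt(e1, 0.03)
  expect_lt(e2, 0.01)
  expect_lt(e2, e1)
})

test_that("an intact shell inflates axisymmetrically", {
  st <- shell_oracle_state(1)
  sh <- st$mesh
  keep <- which(sh$node_layer == 0)
  X <- sh$nodes[keep, ]
  r <- sqrt(rowSums(X^2))
  th <- acos(pmin(pmax(X[, 3] / r, -1), 1))
  ur <- rowSums(st$sol$u[keep, ] * X) / r
  # azimuthal variation within a latitude band far from the fixed patch
  band <- th > 0.2 & th < 0.5
  expect_lt(stats::sd(ur[band]) / abs(mean(ur[band])), 0.01)
})

test_that("incompressibility is enforced to a fraction of a percent", {
  st <- shell_oracle_state(1)
  sh <- st$mesh
  v0 <- sum(eyefem:::hex_volumes(sh$nodes, sh$elems))
  v1 <- sum(eyefem:::hex_volumes(sh$nodes + st$sol$u, sh$elems))
  expect_lt(abs(v1 / v0 - 1), 0.005)
})

test_that("the converged state is independent of the load stepping", {
  sh <- make_shell_mesh(3, 0.45, 1)
  mat <- baseline_cornea()
  s5 <- solve_inflation(sh, mat, mat, solve_config(iop = 15, load_steps = 5))
  s20 <- solve_inflation(sh, mat, mat, solve_config(iop = 15, load_steps = 20))
  apex <- which(sh$node_layer == 0 & sh$nodes[, 3] > 0.99 * max(sh$nodes[, 3]))
  u5 <- max(abs(s5$u[apex, 3]))
  u20 <- max(abs(s20$u[apex, 3]))
  expect_lt(abs(u5 / u20 - 1), 1e-3)
})

test_that("surface displacement extraction respects the tags", {
  st <- shell_oracle_state(1)
  f <- extract_surface_displacement(st$sol, "anterior")
  expect_equal(nrow(f$node_coords), length(st$mesh$anterior_nodes))
  fp <- extract_surface_displacement(st$sol, "posterior")
  expect_equal(nrow(fp$node_coords), length(st$mesh$posterior_nodes))
  expect_error(extract_surface_displacement(st$sol, "equator"), "unknown")
})

test_that("displacement magnitudes stay physiological", {
  st <- shell_oracle_state(1)
  expect_lt(max(sqrt(rowSums(st$sol$u^2))), 0.5)
})
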