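# Shared solve cache so expensive finite-element states are computed once
# per test run and reused across test files (testthat sources all helpers
# into one session).
.case_cache <- new.env(parent = emptyenv())
.preop_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.case_cache[[key]])) .case_cache[[key]] <- fn()
  .case_cache[[key]]
}

# one surgery case at the coarse (or stated) profile, both surfaces,
# 6 and 7 mm pupils; returns the run_surgery_case() result
solve_case <- function(Ds, iop = 15, case = NULL, dx = 0, resolution = 1) {
  key <- paste("case", Ds, iop, case %||% "base", dx, resolution, sep = "_")
  cached(key, function() {
    mats <- if (is.null(case)) {
      list(cornea = baseline_cornea(), sclera = baseline_sclera())
    } else {
      mc <- material_cases(case)
      list(cornea = mc$cornea, sclera = mc$sclera)
    }
    run_surgery_case(
      Ds = Ds, iop = iop, cornea = mats$cornea, sclera = mats$sclera,
      decenter = c(dx, 0), pupil_radii = c(3, 3.5), resolution = resolution,
      scfg = solve_config(iop = iop, load_steps = 5),
      cache = .preop_cache
    )
  })
}

induced_of <- function(cs, surface = "anterior", pupil_mm = 6) {
  cs$induced[[surface]][[as.character(pupil_mm)]]
}

shell_oracle_state <- function(resolution) {
  key <- paste0("shell_", resolution)
  cached(key, function() {
    mat <- baseline_cornea()
    sh <- make_shell_mesh(7.2, 0.5, resolution)
    sol <- solve_inflation(sh, mat, mat, solve_config(iop = 15, load_steps = 5))
    list(mesh = sh, sol = sol,
         oracle = closed_form_sphere_inflation(mat, 7.2, 7.7,
                                               iop_mmhg_to_mpa(15)))
  })
}

# fitted outer radius change of a deformed shell, excluding the fixed patch
shell_radius_change <- function(st, polar_max = 2.0) {
  sh <- st$mesh
  keep <- which(sh$node_layer == 0)
  X <- sh$nodes[keep, ]
  th <- acos(pmin(pmax(X[, 3] / sqrt(rowSums(X^2)), -1), 1))
  sel <- th < polar_max
  Y <- X[sel, ] + st$sol$u[keep, ][sel, ]
  A <- cbind(2 * Y, 1)
  co <- qr.solve(A, rowSums(Y^2))
  sqrt(co[4] + sum(co[1:3]^2)) - max(sqrt(rowSums(X^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
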