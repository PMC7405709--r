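#' Solver configuration for the inflation problem
#'
#' @param iop Intraocular pressure in mm Hg (0 to 35; 15 is the
#'   physiological default).
#' @param load_steps Number of proportional load increments (failed
#'   increments are bisected adaptively).
#' @param newton_tol Relative residual tolerance of the Newton loop.
#' @param max_iters Maximum Newton iterations per load step.
#' @param flap_interface_mode How duplicated crack faces interact:
#'   `"no-separation"` (default: faces transmit normal tractions in both
#'   directions but slide freely in the tangent plane - a repositioned flap
#'   adhering to the bed before healing), `"frictionless-contact"` (faces
#'   may separate but not interpenetrate; an unsupported flap can rotate
#'   off the bed about its hinge), `"bonded"` (all components tied) or
#'   `"free-crack"` (no interaction).
#' @param penalty_bulk_factor Volumetric penalty bulk modulus as a multiple
#'   of each material's initial shear modulus (incompressibility
#'   enforcement; >= 1000 recommended).
#' @param contact_stiffness Crack-face penalty stiffness per unit area
#'   (MPa/mm).
#' @return A `solve_config` object.
#' @export
solve_config <- function(iop = 15, load_steps = 10, newton_tol = 1e-6,
                         max_iters = 30,
                         flap_interface_mode = c("no-separation",
                                                 "frictionless-contact",
                                                 "bonded", "free-crack"),
                         penalty_bulk_factor = 1000,
                         contact_stiffness = 1000) {
  flap_interface_mode <- match.arg(flap_interface_mode)
  if (iop < 0 || iop > 35) stop("iop must lie in [0, 35] mm Hg")
  if (newton_tol <= 0 || load_steps < 1 || max_iters < 1) {
    stop("tolerances and iteration counts must be positive")
  }
  structure(list(iop = iop, load_steps = as.integer(load_steps),
                 newton_tol = newton_tol, max_iters = as.integer(max_iters),
                 flap_interface_mode = flap_interface_mode,
                 penalty_bulk_factor = penalty_bulk_factor,
                 contact_stiffness = contact_stiffness),
            class = "solve_config")
}

# one Newton solve at fixed pressure; returns the converged state or a
# failure flag so the caller can cut the load increment
newton_attempt <- function(u0, p, free, assemble, cfg, ndof) {
  u <- u0
  hist <- numeric(0)
  stag <- 0L
  rel <- Inf
  for (it in seq_len(cfg$max_iters)) {
    asm <- tryCatch(assemble(u, p, TRUE), error = function(e) NULL)
    if (is.null(asm)) {
      return(list(u = u0, hist = hist, iters = it, converged = FALSE,
                  rel = rel))
    }
    r <- asm$fext - asm$fint
    rf <- r[free]
    rn <- sqrt(sum(rf^2))
    ref <- max(sqrt(sum(asm$fext[free]^2)), 1e-12)
    rel <- rn / ref
    hist <- c(hist, rn)
    if (rel < cfg$newton_tol || rn < 1e-12) {
      return(list(u = u, hist = hist, iters = it, converged = TRUE,
                  rel = rel))
    }
    # stagnation at the finite-difference accuracy floor: accept if the
    # residual is already far below engineering relevance
    if (it > 1 && rn > 0.9 * hist[it - 1]) stag <- stag + 1L else stag <- 0L
    if (stag >= 3L && rel < 1e-4) {
      return(list(u = u, hist = hist, iters = it, converged = TRUE,
                  rel = rel))
    }
    if ((stag >= 5L) || (it == cfg$max_iters) ||
        (it > 12L && rn > 0.5 * hist[1])) {
      return(list(u = u0, hist = hist, iters = it, converged = FALSE,
                  rel = rel))
    }
    K <- Matrix::sparseMatrix(i = asm$ti, j = asm$tj, x = asm$tx,
                              dims = c(ndof, ndof))
    Kff <- K[free, free, drop = FALSE]
    # the tangent is symmetric up to finite-difference noise and the small
    # skew part of the follower-load stiffness; factor the symmetric part
    # (sparse supernodal Cholesky), shifting the diagonal if a tiny bending
    # pivot goes negative, with unsymmetric LU as the last resort
    Ks <- Matrix::symmpart(Kff)
    dmax <- max(abs(Matrix::diag(Ks)))
    duf <- NULL
    for (shift in c(0, 1e-8, 1e-6, 1e-4)) {
      ch <- tryCatch(
        Matrix::Cholesky(Ks + shift * dmax * Matrix::Diagonal(length(free)),
                         LDL = FALSE, super = TRUE),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(ch)) {
        duf <- as.numeric(Matrix::solve(ch, rf))
        break
      }
    }
    if (is.null(duf)) duf <- as.numeric(Matrix::solve(Kff, rf))
    du <- numeric(ndof)
    du[free] <- duf
    # backtracking line search on the force residual; keep the best trial
    best_u <- NULL
    best_rt <- rn
    alpha <- 1
    for (ls in 1:6) {
      u_try <- u + alpha * du
      ft <- tryCatch(assemble(u_try, p, FALSE), error = function(e) NULL)
      if (!is.null(ft)) {
        rt <- sqrt(sum((ft$fext - ft$fint)[free]^2))
        if (rt < best_rt) {
          best_rt <- rt
          best_u <- u_try
          if (rt < 0.5 * rn) break
        }
      }
      alpha <- alpha / 2
    }
    if (is.null(best_u)) {
      # no step reduces the residual: give up and let the caller cut
      return(list(u = u0, hist = hist, iters = it, converged = FALSE,
                  rel = rel))
    }
    u <- best_u
  }
  list(u = u0, hist = hist, iters = cfg$max_iters, converged = FALSE,
       rel = rel)
}

#' Quasi-static inflation solve of the (post-operative) eye
#'
#' Solves the nonlinear equilibrium of the meshed globe under intraocular
#' pressure: incompressible Ogden materials for cornea and sclera (penalty
#' enforcement with selective reduced integration), follower pressure on
#' every inner-cavity facet, the posterior fixation patch fully constrained,
#' and crack faces of a cut flap treated per the configured interface mode.
#' Newton's method with backtracking line search under an adaptive
#' proportional load ramp with a secant predictor.
#'
#' @param mesh An `eye_mesh` (intact or post-operative).
#' @param cornea,sclera Incompressible [ogden_material()] objects.
#' @param cfg A [solve_config()].
#' @param verbose Print per-step convergence summaries.
#' @return An `inflation_solution`: nodal displacement matrix `u` (mm),
#'   residual history, iteration counts, the mesh and inputs.
#' @examples
#' \donttest{
#' mesh <- build_eye_geometry(eye_geometry(), resolution = 1)
#' sol <- solve_inflation(mesh, cfg = solve_config(iop = 15, load_steps = 5))
#' sol
#' }
#' @export
solve_inflation <- function(mesh, cornea = baseline_cornea(),
                            sclera = baseline_sclera(),
                            cfg = solve_config(), verbose = FALSE) {
  stopifnot(inherits(mesh, "eye_mesh"), inherits(cfg, "solve_config"))
  if (cornea$d1 != 0 || sclera$d1 != 0) {
    stop("the solver enforces incompressibility; supply d1 = 0 materials")
  }
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  fixed <- sort(unique(as.vector(outer(3L * (as.integer(mesh$fixed_nodes) - 1L),
                                       1:3, `+`))))
  free <- setdiff(seq_len(ndof), fixed)

  mats <- list(
    list(mu = cornea$mu, alpha = cornea$alpha,
         kappa = cfg$penalty_bulk_factor * initial_shear_modulus(cornea)),
    list(mu = sclera$mu, alpha = sclera$alpha,
         kappa = cfg$penalty_bulk_factor * initial_shear_modulus(sclera))
  )

  if (!is.null(mesh$flap) && nrow(mesh$flap$pairs) > 0) {
    pairs <- mesh$flap$pairs
    normals <- mesh$flap$normals
    pair_k <- cfg$contact_stiffness * pmax(mesh$flap$trib_area, 1e-6)
    cmode <- switch(cfg$flap_interface_mode,
                    "free-crack" = 0L, "frictionless-contact" = 1L,
                    "bonded" = 2L, "no-separation" = 3L)
  } else {
    pairs <- matrix(integer(0), 0, 2)
    normals <- matrix(numeric(0), 0, 3)
    pair_k <- numeric(0)
    cmode <- 0L
  }

  p_full <- iop_mmhg_to_mpa(cfg$iop)

  assemble <- function(u, p, tangent) {
    fem_assemble(mesh$nodes, mesh$elems, mesh$elem_region, u, mats,
                 mesh$cavity_facets, p, pairs, normals, pair_k, cmode,
                 tangent, 1e-6)
  }

  if (p_full == 0) {
    return(structure(list(
      u = matrix(0, n, 3), mesh = mesh, cornea = cornea, sclera = sclera,
      cfg = cfg, iterations = 0L, residual_history = list(),
      converged = TRUE
    ), class = "inflation_solution"))
  }

  res_hist <- list()
  iters <- integer(0)
  # quadratic load ramp: strain-stiffening materials are softest near the
  # unloaded state, so early increments are kept small; failed increments
  # are bisected
  targets <- p_full * (seq_len(cfg$load_steps) / cfg$load_steps)^2
  u_last <- numeric(ndof)
  p_last <- 0
  u_prev <- u_last
  p_prev <- NA_real_
  cuts <- 0L
  s <- 0L
  while (length(targets) > 0) {
    p <- targets[1]
    # secant predictor from the two last converged states; fall back to the
    # unpredicted state if it lands on an invalid configuration
    u0 <- u_last
    if (!is.na(p_prev) && p_last > p_prev) {
      u_try <- u_last + (u_last - u_prev) * (p - p_last) / (p_last - p_prev)
      ok <- tryCatch({
        assemble(u_try, p, FALSE)
        TRUE
      }, error = function(e) FALSE)
      if (ok) u0 <- u_try
    }
    att <- newton_attempt(u0, p, free, assemble, cfg, ndof)
    if (att$converged) {
      s <- s + 1L
      iters[s] <- att$iters
      res_hist[[s]] <- att$hist
      u_prev <- u_last
      p_prev <- p_last
      u_last <- att$u
      p_last <- p
      targets <- targets[-1]
      if (verbose) {
        message(sprintf(
          "load step %d: p = %.4g MPa, %d iterations, residual %.3e",
          s, p, att$iters, att$hist[length(att$hist)]))
      }
    } else {
      cuts <- cuts + 1L
      if (cuts > 12L || (p - p_last) < p_full * 1e-3) {
        stop(sprintf(
          "Newton did not converge at p = %.4g MPa (relative residual %.3e) despite increment cutting; history: %s",
          p, att$rel, paste(signif(att$hist, 3), collapse = " ")))
      }
      targets <- c((p_last + p) / 2, targets)
      if (verbose) {
        message(sprintf("cutting increment: retrying at p = %.4g MPa",
                        targets[1]))
      }
    }
  }

  structure(list(
    u = matrix(u_last, ncol = 3, byrow = TRUE),
    mesh = mesh, cornea = cornea, sclera = sclera, cfg = cfg,
    iterations = iters, residual_history = res_hist,
    converged = TRUE
  ), class = "inflation_solution")
}

#' @export
print.inflation_solution <- function(x, ...) {
  um <- sqrt(rowSums(x$u^2))
  cat(sprintf(
    "Inflation solution at %g mm Hg: %d nodes, %s flap interface\n",
    x$cfg$iop, nrow(x$u),
    if (is.null(x$mesh$flap)) "no" else x$cfg$flap_interface_mode))
  cat(sprintf("  max |u| = %.4g mm, total Newton iterations %d\n",
              max(um), sum(x$iterations)))
  invisible(x)
}

#' Extract the displacement field on a tagged corneal surface
#'
#' @param solution An `inflation_solution`.
#' @param tag `"anterior"` or `"posterior"` corneal surface.
#' @return A `surface_displacement_field` with reference coordinates
#'   `node_coords` and `displacements`, both in mm.
#' @export
extract_surface_displacement <- function(solution, tag = "anterior") {
  stopifnot(inherits(solution, "inflation_solution"))
  mesh <- solution$mesh
  ids <- switch(tag,
                anterior = mesh$anterior_nodes,
                posterior = mesh$posterior_nodes,
                stop("unknown surface tag: ", tag))
  structure(list(
    surface_tag = tag,
    node_ids = ids,
    node_coords = mesh$nodes[ids, , drop = FALSE],
    displacements = solution$u[ids, , drop = FALSE]
  ), class = "surface_displacement_field")
}

#' @export
print.surface_displacement_field <- function(x, ...) {
  mag <- sqrt(rowSums(x$displacements^2))
  cat(sprintf(
    "Surface displacement field (%s): %d nodes, |u| in [%.3g, %.3g] mm\n",
    x$surface_tag, length(x$node_ids), min(mag), max(mag)))
  invisible(x)
}

#' Closed-form inflation of an incompressible Ogden spherical shell
#'
#' Classical thick-walled-sphere solution: with incompressibility the
#' circumferential stretch profile follows from volume conservation,
#' `r^3 = R^3 + a^3 - A^3`, and the internal pressure balancing an inner
#' stretch `lambda_a = a/A` is the quadrature
#' `P = int_{lambda_b}^{lambda_a} W'(lambda) / (lambda^3 - 1) d lambda`,
#' where `W(lambda)` is the strain energy along the equibiaxial path
#' `(lambda, lambda, lambda^-2)`. The inner stretch for a given pressure is
#' found by root bracketing. Serves as the independent oracle for the
#' finite-element solver.
#'
#' @param mat An incompressible [ogden_material()].
#' @param inner_radius,outer_radius Shell radii A < B (mm).
#' @param pressure Internal pressure in MPa.
#' @return The inner-surface circumferential stretch `lambda_a`
#'   (dimensionless), with attributes `lambda_b`, `u_inner` and `u_outer`
#'   (radial displacements in mm).
#' @examples
#' lam <- closed_form_sphere_inflation(baseline_cornea(), 7.2, 7.7,
#'                                     iop_mmhg_to_mpa(15))
#' attr(lam, "u_outer")
#' @export
closed_form_sphere_inflation <- function(mat, inner_radius, outer_radius,
                                         pressure) {
  stopifnot(inherits(mat, "ogden_material"))
  if (mat$d1 != 0) stop("closed form requires an incompressible material")
  A <- inner_radius
  B <- outer_radius
  if (!(A > 0 && B > A)) stop("need 0 < inner_radius < outer_radius")
  if (pressure < 0) stop("pressure must be non-negative")
  if (pressure == 0) {
    out <- 1
    attr(out, "lambda_b") <- 1
    attr(out, "u_inner") <- 0
    attr(out, "u_outer") <- 0
    return(out)
  }
  wprime <- function(lam) {
    out <- numeric(length(lam))
    for (i in seq_along(lam)) {
      out[i] <- 2 * sum(mat$mu * (lam[i]^(mat$alpha - 1) -
                                    lam[i]^(-2 * mat$alpha - 1)))
    }
    out
  }
  mu0 <- initial_shear_modulus(mat)
  integrand <- function(lam) {
    out <- wprime(lam) / (lam^3 - 1)
    near <- abs(lam - 1) < 1e-9
    out[near] <- 4 * mu0  # limit of the 0/0 form at lambda = 1
    out
  }
  p_of_la <- function(la) {
    lb <- ((B^3 + (la^3 - 1) * A^3) / B^3)^(1 / 3)
    if (la - lb < 1e-14) {
      return(integrand((la + lb) / 2) * (la - lb))
    }
    stats::integrate(integrand, lb, la, rel.tol = 1e-10)$value
  }
  f <- function(la) p_of_la(la) - pressure
  hi <- 1.0005
  while (f(hi) < 0 && hi < 3) hi <- 1 + (hi - 1) * 2
  if (f(hi) < 0) stop("no inner stretch found in bracket (pressure too high?)")
  la <- stats::uniroot(f, c(1 + 1e-12, hi), tol = 1e-13)$root
  lb <- ((B^3 + (la^3 - 1) * A^3) / B^3)^(1 / 3)
  out <- la
  attr(out, "lambda_b") <- lb
  attr(out, "u_inner") <- (la - 1) * A
  attr(out, "u_outer") <- (lb - 1) * B
  out
}
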