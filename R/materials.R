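#' @useDynLib eyefem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# unit conversion: 1 mm Hg in MPa (mm-MPa-N unit system used throughout)
MMHG_TO_MPA <- 1.333e-4

#' Convert intraocular pressure from mm Hg to MPa
#'
#' @param iop_mmhg Pressure in mm Hg.
#' @return Pressure in MPa (1 mm Hg = 1.333e-4 MPa).
#' @export
iop_mmhg_to_mpa <- function(iop_mmhg) iop_mmhg * MMHG_TO_MPA

#' Ogden hyperelastic material
#'
#' An N-term Ogden strain-energy material for corneal or scleral tissue.
#' The strain energy density is
#' `W = sum_i mu_i/alpha_i (lb1^alpha_i + lb2^alpha_i + lb3^alpha_i - 3) + (1/d1)(J-1)^2`,
#' where `lb_p = J^(-1/3) lambda_p` are deviatoric principal stretches.
#' `d1 = 0` declares the tissue fully incompressible (the volumetric term is
#' dropped and enforced by constraint/penalty instead).
#'
#' @param mu Numeric vector of shear-like moduli `mu_i` (MPa).
#' @param alpha Numeric vector of dimensionless exponents `alpha_i`.
#' @param d1 Compressibility parameter (1/MPa); 0 means incompressible.
#' @param label Optional human-readable tissue label.
#' @return An object of class `ogden_material`.
#' @examples
#' baseline_cornea()
#' ogden_material(mu = 0.0120, alpha = 88.684)
#' @export
ogden_material <- function(mu, alpha, d1 = 0, label = NULL) {
  stopifnot(is.numeric(mu), is.numeric(alpha), length(mu) == length(alpha),
            length(mu) >= 1L)
  if (any(mu * alpha <= 0)) {
    stop("each term must have mu_i * alpha_i > 0 (positive stiffness)")
  }
  if (d1 < 0) stop("d1 must be non-negative")
  structure(
    list(N = length(mu), mu = as.numeric(mu), alpha = as.numeric(alpha),
         d1 = as.numeric(d1), label = label),
    class = "ogden_material"
  )
}

#' @export
print.ogden_material <- function(x, ...) {
  cat(sprintf("Ogden material (%d term%s%s)\n", x$N,
              if (x$N > 1) "s" else "",
              if (!is.null(x$label)) paste0(", ", x$label) else ""))
  for (i in seq_len(x$N)) {
    cat(sprintf("  mu_%d = %g MPa, alpha_%d = %g\n", i, x$mu[i], i, x$alpha[i]))
  }
  cat(sprintf("  d1 = %g (%s), initial shear modulus %.4f MPa\n",
              x$d1, if (x$d1 == 0) "incompressible" else "compressible",
              initial_shear_modulus(x)))
  invisible(x)
}

#' Baseline fitted corneal material
#'
#' Two-term Ogden constants fitted to whole-cornea inflation behaviour:
#' mu1 = mu2 = 0.003535 MPa, alpha1 = 103.51, alpha2 = 103.61,
#' incompressible. The two terms are deliberately kept distinct even though
#' their constants are nearly identical.
#'
#' @return An `ogden_material`.
#' @export
baseline_cornea <- function() {
  ogden_material(mu = c(0.003535, 0.003535), alpha = c(103.51, 103.61),
                 d1 = 0, label = "cornea (baseline fit)")
}

#' Baseline fitted scleral material
#'
#' One-term Ogden constants for the sclera: mu1 = 0.030224 MPa,
#' alpha1 = 182.73, incompressible.
#'
#' @return An `ogden_material`.
#' @export
baseline_sclera <- function() {
  ogden_material(mu = 0.030224, alpha = 182.73, d1 = 0,
                 label = "sclera (baseline fit)")
}

#' Ogden strain energy density
#'
#' Evaluates the strain-energy potential at a principal-stretch state.
#'
#' @param mat An [ogden_material()].
#' @param stretches Length-3 vector of principal stretches `lambda_p` (> 0).
#' @param J Volume ratio; defaults to (and must equal) the product of the
#'   principal stretches. For an incompressible material (`d1 = 0`) it must
#'   equal 1.
#' @return Energy density in MPa (= mJ/mm^3).
#' @examples
#' strain_energy(baseline_cornea(), c(1.01, 1.01, 1.01^-2))
#' @export
strain_energy <- function(mat, stretches, J = prod(stretches)) {
  stopifnot(inherits(mat, "ogden_material"), length(stretches) == 3L)
  if (any(stretches <= 0)) stop("principal stretches must be positive")
  if (J <= 0) stop("J must be positive")
  if (abs(J / prod(stretches) - 1) > 1e-9) {
    stop("J must equal the product of the principal stretches")
  }
  if (mat$d1 == 0 && abs(J - 1) > 1e-9) {
    stop("incompressible material (d1 = 0) requires J = 1")
  }
  lb <- J^(-1 / 3) * stretches
  W <- sum(mat$mu / mat$alpha *
             (lb[1]^mat$alpha + lb[2]^mat$alpha + lb[3]^mat$alpha - 3))
  if (mat$d1 > 0) W <- W + (1 / mat$d1) * (J - 1)^2
  W
}

#' Initial shear modulus of an Ogden material
#'
#' `mu = 1/2 sum_i alpha_i mu_i`, the small-strain shear modulus.
#'
#' @param mat An [ogden_material()].
#' @return Shear modulus in MPa.
#' @examples
#' initial_shear_modulus(baseline_cornea())  # 0.3661 MPa
#' initial_shear_modulus(baseline_sclera())  # 2.7614 MPa
#' @export
initial_shear_modulus <- function(mat) {
  stopifnot(inherits(mat, "ogden_material"))
  0.5 * sum(mat$alpha * mat$mu)
}

#' Initial bulk modulus of an Ogden material
#'
#' `k = 2 / d1`. For a fully incompressible material (`d1 = 0`) the bulk
#' modulus is unbounded and `Inf` is returned.
#'
#' @param mat An [ogden_material()].
#' @return Bulk modulus in MPa, or `Inf` when incompressible.
#' @export
initial_bulk_modulus <- function(mat) {
  stopifnot(inherits(mat, "ogden_material"))
  if (mat$d1 < 0) stop("d1 must be non-negative")
  if (mat$d1 == 0) Inf else 2 / mat$d1
}

#' Uniaxial Cauchy stress of an incompressible Ogden material
#'
#' Closed-form uniaxial tension response
#' `sigma = sum_i mu_i (lambda^alpha_i - lambda^(-alpha_i/2))`,
#' used as an analytic oracle for the finite-element solver.
#'
#' @param mat An incompressible [ogden_material()].
#' @param lambda Axial stretch(es), positive. Vectorised.
#' @return Cauchy stress in MPa.
#' @export
uniaxial_stress <- function(mat, lambda) {
  stopifnot(inherits(mat, "ogden_material"))
  if (mat$d1 != 0) stop("uniaxial_stress supports incompressible materials only")
  if (any(lambda <= 0)) stop("stretch must be positive")
  vapply(lambda, function(l) {
    sum(mat$mu * (l^mat$alpha - l^(-mat$alpha / 2)))
  }, numeric(1))
}

# equibiaxial membrane Cauchy stress of an incompressible Ogden sheet
equibiaxial_stress <- function(mat, lambda) {
  vapply(lambda, function(l) {
    sum(mat$mu * (l^mat$alpha - l^(-2 * mat$alpha)))
  }, numeric(1))
}

#' Operating-point tangent Young modulus under intraocular pressure
#'
#' Estimates the effective Young modulus of a pressurised thin spherical
#' tissue shell at its operating point. The Laplace membrane stress
#' `sigma = P r / (2 t)` is computed from the pressure, the equibiaxial
#' stretch that carries that stress is solved from the incompressible Ogden
#' membrane response, and the uniaxial tangent slope `d sigma_u / d lambda`
#' is evaluated at that stretch. At `P = 0` this reduces to the
#' small-strain Young modulus `3 mu` of an incompressible solid.
#'
#' Note this operating-point definition does not reproduce the nominal
#' per-case "elasticity at 15 mm Hg" labels carried by the bundled stiffness
#' cases (see [material_cases()]); those labels are treated as descriptive
#' metadata, not as derivable quantities.
#'
#' @param mat An incompressible [ogden_material()].
#' @param radius Shell mid-surface radius (mm).
#' @param thickness Shell thickness (mm).
#' @param iop Intraocular pressure (mm Hg).
#' @return Tangent Young modulus in MPa.
#' @export
tangent_modulus_at_iop <- function(mat, radius, thickness, iop) {
  stopifnot(inherits(mat, "ogden_material"))
  if (mat$d1 != 0) stop("supported for incompressible materials only")
  if (radius <= 0 || thickness <= 0 || iop < 0) {
    stop("radius, thickness must be positive and iop non-negative")
  }
  sigma <- iop_mmhg_to_mpa(iop) * radius / (2 * thickness)
  if (sigma == 0) {
    lam <- 1
  } else {
    f <- function(l) equibiaxial_stress(mat, l) - sigma
    upper <- 1.5
    if (f(upper) < 0) stop("no equibiaxial stretch carries the membrane stress")
    lam <- stats::uniroot(f, c(1, upper), tol = 1e-12)$root
  }
  # uniaxial tangent d sigma_u / d lambda at the operating stretch
  sum(mat$mu * (mat$alpha * lam^(mat$alpha - 1) +
                  (mat$alpha / 2) * lam^(-mat$alpha / 2 - 1)))
}

#' Bundled ocular-tissue stiffness cases
#'
#' Eight one-term Ogden parameter cases spanning the physiological range of
#' corneal and scleral stiffness (nominal corneal Young modulus roughly 0.1
#' to 3.9 MPa at 15 mm Hg). Cases 1-4 stiffen cornea and sclera together;
#' cases 5-8 vary the cornea while the sclera is held at the case-5
#' parameters. The table ships as a plain-JSON data file under
#' `inst/extdata/material_cases.json` and round-trips losslessly.
#'
#' @param case Optional case label (integer 1-8). If omitted, all cases are
#'   returned as a list.
#' @return A single case (list with elements `label`, `cornea`, `sclera`,
#'   `nominal_E_cornea`, `nominal_E_sclera`) or a list of all eight.
#' @examples
#' material_cases(3)$cornea
#' @export
material_cases <- function(case = NULL) {
  path <- system.file("extdata", "material_cases.json", package = "eyefem")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cases <- lapply(raw$cases, function(cs) {
    list(
      label = cs$label,
      cornea = ogden_material(
        mu = as.numeric(unlist(cs$cornea$mu)),
        alpha = as.numeric(unlist(cs$cornea$alpha)),
        d1 = cs$cornea$d1,
        label = sprintf("cornea (case %d)", cs$label)
      ),
      sclera = ogden_material(
        mu = as.numeric(unlist(cs$sclera$mu)),
        alpha = as.numeric(unlist(cs$sclera$alpha)),
        d1 = cs$sclera$d1,
        label = sprintf("sclera (case %d)", cs$label)
      ),
      nominal_E_cornea = cs$nominal_E_cornea,
      nominal_E_sclera = cs$nominal_E_sclera
    )
  })
  names(cases) <- vapply(cases, function(c) as.character(c$label), "")
  if (is.null(case)) return(cases)
  key <- as.character(case)
  if (!key %in% names(cases)) stop("unknown material case: ", case)
  cases[[key]]
}
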