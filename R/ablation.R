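#' Munnerlyn ablation specification
#'
#' Bundles the parameters of a myopic photoablation: the spherical
#' correction, the pre-operative anterior corneal radius, the optical zone
#' diameter, the corneal refractive index and an optional treatment
#' decentration.
#'
#' @param Ds Spherical correction in diopters. Negative for myopia; 0 is the
#'   identity (no tissue removed). Myopic corrections between -15 and -1 D
#'   are the exercised range.
#' @param R1 Pre-operative anterior corneal radius of curvature (mm).
#' @param O Optical zone diameter (mm); the full correction is achieved
#'   inside a disk of diameter `O` centred on the treatment axis.
#' @param n Corneal refractive index (default 1.376).
#' @param decenter Length-2 numeric, (dx, dy) offset of the treatment centre
#'   from the corneal apex in mm.
#'
#' @return An object of class `ablation_spec`.
#' @examples
#' ablation_spec(Ds = -5)
#' @export
ablation_spec <- function(Ds, R1 = 7.7, O = 6, n = 1.376, decenter = c(0, 0)) {
  stopifnot(is.numeric(Ds), length(Ds) == 1L, is.finite(Ds))
  if (R1 <= 0) stop("R1 must be positive")
  if (O <= 0 || O / 2 >= R1) stop("optical zone must satisfy 0 < O/2 < R1")
  if (n <= 1) stop("refractive index must exceed 1")
  if (Ds > 0) stop("only myopic (Ds < 0) or null corrections are supported")
  if (Ds < -15) stop("Ds below -15 D is outside the supported range")
  stopifnot(length(decenter) == 2L, all(is.finite(decenter)))
  structure(
    list(Ds = Ds, R1 = R1, O = O, n = n, decenter = as.numeric(decenter)),
    class = "ablation_spec"
  )
}

#' @export
print.ablation_spec <- function(x, ...) {
  cat(sprintf(
    "Munnerlyn ablation: Ds = %g D, R1 = %g mm -> Rf = %.4f mm, zone %g mm, n = %g\n",
    x$Ds, x$R1, post_op_radius(x$R1, x$n, x$Ds), x$O, x$n
  ))
  if (any(x$decenter != 0)) {
    cat(sprintf("  decentred by (%g, %g) mm\n", x$decenter[1], x$decenter[2]))
  }
  cat(sprintf("  central depth %.1f um\n", 1000 * ablation_depth(0, x)))
  invisible(x)
}

#' Post-operative anterior corneal radius
#'
#' Converts a target spherical correction into the post-operative anterior
#' radius of curvature using keratometric vergence arithmetic: the corneal
#' surface power in diopters is `1000 (n - 1) / R` with `R` in mm, and the
#' correction adds `Ds` to that power, so
#' `Rf = 1000 (n - 1) R1 / (1000 (n - 1) + Ds R1)`.
#'
#' @param R1 Pre-operative anterior radius (mm).
#' @param n Corneal refractive index.
#' @param Ds Spherical correction in diopters (negative for myopia).
#' @return Post-operative radius of curvature `Rf` in mm.
#' @examples
#' post_op_radius(7.7, 1.376, -5)
#' @export
post_op_radius <- function(R1, n = 1.376, Ds = 0) {
  if (R1 <= 0) stop("R1 must be positive")
  power_pre <- 1000 * (n - 1) / R1
  power_post <- power_pre + Ds
  if (power_post <= 0) {
    stop("post-operative corneal power would be non-positive")
  }
  1000 * (n - 1) / power_post
}

#' Munnerlyn ablation depth at a radial position
#'
#' Depth of tissue removed at transverse distance `d` from the treatment
#' centre for a myopic correction:
#' `l(d) = sqrt(R1^2 - d^2) - sqrt(Rf^2 - d^2) + sqrt(Rf^2 - (O/2)^2) - sqrt(R1^2 - (O/2)^2)`.
#' The profile is zero at the optical-zone edge `d = O/2` and maximal on the
#' axis; outside the zone it is zero (no transition zone is modelled).
#'
#' @param d Transverse distance(s) from the treatment centre (mm),
#'   non-negative. Vectorised.
#' @param spec An [ablation_spec()].
#' @return Ablation depth(s) in mm.
#' @examples
#' ablation_depth(0, ablation_spec(-5))    # central depth, ~0.067 mm
#' ablation_depth(3, ablation_spec(-5))    # zone edge: 0
#' @export
ablation_depth <- function(d, spec) {
  stopifnot(inherits(spec, "ablation_spec"))
  if (any(d < 0)) stop("d must be non-negative")
  if (any(d > spec$R1)) stop("d exceeds the anterior radius of curvature")
  Rf <- post_op_radius(spec$R1, spec$n, spec$Ds)
  h <- spec$O / 2
  l <- numeric(length(d))
  inside <- d < h
  if (any(inside)) {
    di <- d[inside]
    l[inside] <- sqrt(spec$R1^2 - di^2) - sqrt(Rf^2 - di^2) +
      sqrt(Rf^2 - h^2) - sqrt(spec$R1^2 - h^2)
  }
  pmax(l, 0)
}

#' Ablation depth at a decentred evaluation point
#'
#' Evaluates the (possibly decentred) Munnerlyn profile at Cartesian corneal
#' coordinates: the centred profile applied about the shifted treatment
#' centre `spec$decenter`.
#'
#' @param x,y Transverse evaluation coordinates (mm), vectorised.
#' @param spec An [ablation_spec()].
#' @return Ablation depth(s) in mm.
#' @export
ablation_depth_decentered <- function(x, y, spec) {
  stopifnot(inherits(spec, "ablation_spec"))
  d <- sqrt((x - spec$decenter[1])^2 + (y - spec$decenter[2])^2)
  ablation_depth(d, spec)
}

#' Radial ablation profile table
#'
#' Convenience tabulation of the ablation profile, one row per radial
#' station, for plotting or export.
#'
#' @param spec An [ablation_spec()].
#' @param n_points Number of radial stations between 0 and the zone edge.
#' @return A data.frame with columns `d_mm` and `depth_um`.
#' @export
ablation_profile_table <- function(spec, n_points = 61) {
  d <- seq(0, spec$O / 2, length.out = n_points)
  data.frame(d_mm = d, depth_um = 1000 * ablation_depth(d, spec))
}

#' Total ablated tissue volume
#'
#' Analytic integral of the centred Munnerlyn profile over the optical zone,
#' `2 pi int_0^{O/2} l(d) d dd`, by adaptive quadrature. Used as the oracle
#' for the volume removed from the meshed stromal bed.
#'
#' @param spec An [ablation_spec()].
#' @return Ablated volume in mm^3.
#' @export
ablation_volume <- function(spec) {
  if (spec$Ds == 0) return(0)
  2 * pi * stats::integrate(function(d) ablation_depth(d, spec) * d,
    0, spec$O / 2,
    rel.tol = 1e-10
  )$value
}
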