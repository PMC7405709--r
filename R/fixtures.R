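#' Synthetic displacement-field specification
#'
#' Describes an analytic corneal-surface displacement field with known
#' Zernike content: the field is constructed so that the exact
#' sag-projection/OPD pipeline recovers the requested coefficients (plus
#' optional Gaussian OPD noise). Used to validate the optical stages without
#' running the solver.
#'
#' @param mode_content List of numeric triples `c(n, m, amplitude_um)`, or a
#'   3-column matrix.
#' @param base_radius Radius of the carrier sphere (mm).
#' @param pupil_radius Pupil radius over which modes are defined (mm).
#' @param sample_density Number of sample nodes in the pupil.
#' @param noise_sd Gaussian noise standard deviation on the OPD (um).
#' @param seed RNG seed; fully determines the field.
#' @param delta_n Refractive-index step the downstream pipeline will apply.
#' @return A `synthetic_field_spec`.
#' @export
synthetic_field_spec <- function(mode_content = list(), base_radius = 7.7,
                                 pupil_radius = 3, sample_density = 2000,
                                 noise_sd = 0, seed = 1, delta_n = 0.376) {
  modes <- if (length(mode_content)) {
    do.call(rbind, lapply(mode_content, function(x) {
      stopifnot(length(x) == 3)
      as.numeric(x)
    }))
  } else {
    matrix(numeric(0), 0, 3)
  }
  if (nrow(modes) && max(abs(modes[, 3])) > 1e3 * base_radius / 50) {
    stop("mode amplitudes too large for sag-projection validity")
  }
  if (pupil_radius >= base_radius) stop("pupil must fit inside the sphere")
  structure(list(modes = modes, base_radius = base_radius,
                 pupil_radius = pupil_radius,
                 sample_density = as.integer(sample_density),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 delta_n = delta_n),
            class = "synthetic_field_spec")
}

# sunflower-spiral sampling of a disk: near-uniform, well-conditioned
sunflower_disk <- function(n, radius) {
  k <- seq_len(n)
  r <- radius * sqrt((k - 0.5) / n)
  th <- k * pi * (3 - sqrt(5))
  cbind(r * cos(th), r * sin(th))
}

#' Generate a displacement field with known Zernike content
#'
#' Samples the carrier sphere over the pupil on a sunflower spiral and sets
#' a purely axial nodal displacement `dZ` such that the exact sag-projection
#' pipeline yields an OPD equal to the requested Zernike combination (the
#' inverse construction: with `dX = dY = 0` the axial sag displacement is
#' exactly `dZ`, so `dZ = OPD / (1000 delta_n)`), plus Gaussian OPD noise.
#'
#' @param spec A [synthetic_field_spec()].
#' @return A `surface_displacement_field`.
#' @examples
#' f <- make_displacement_with_known_aberration(
#'   synthetic_field_spec(list(c(2, 0, 1))))
#' @export
make_displacement_with_known_aberration <- function(spec) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  xy <- sunflower_disk(spec$sample_density, spec$pupil_radius)
  z <- sqrt(spec$base_radius^2 - rowSums(xy^2))
  opd <- numeric(nrow(xy))
  if (nrow(spec$modes)) {
    for (i in seq_len(nrow(spec$modes))) {
      opd <- opd + spec$modes[i, 3] *
        zernike_eval(spec$modes[i, 1], spec$modes[i, 2],
                     xy[, 1] / spec$pupil_radius, xy[, 2] / spec$pupil_radius)
    }
  }
  if (spec$noise_sd > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(spec$seed)
    opd <- opd + stats::rnorm(length(opd), sd = spec$noise_sd)
  }
  dz <- opd / (1000 * spec$delta_n)
  structure(list(
    surface_tag = "anterior",
    node_ids = seq_len(nrow(xy)),
    node_coords = cbind(xy, z),
    displacements = cbind(0, 0, dz),
    spec = spec
  ), class = "surface_displacement_field")
}

#' Closed spherical-shell mesh
#'
#' Uniform-thickness spherical shell with the same hexahedral topology,
#' tagging and column structure as the eye mesh (both polar caps are square
#' cores; the wall is extruded radially). The oracle geometry for validating
#' the inflation solver against [closed_form_sphere_inflation()].
#'
#' @param inner_radius Inner (cavity) radius in mm.
#' @param thickness Wall thickness in mm.
#' @param resolution Mesh resolution level 1-3.
#' @return An `eye_mesh`.
#' @export
make_shell_mesh <- function(inner_radius, thickness, resolution = 1) {
  if (inner_radius <= 0 || thickness <= 0) stop("dimensions must be positive")
  if (thickness >= inner_radius) {
    stop("thickness must be below the inner radius")
  }
  Rout <- inner_radius + thickness
  geom <- eye_geometry(
    anterior_corneal_radius = Rout,
    posterior_corneal_radius = inner_radius,
    central_corneal_thickness = thickness,
    scleral_outer_radius = Rout,
    scleral_thickness_limbus = thickness,
    scleral_thickness_pole = thickness,
    limbus_radius = 0.49 * Rout,
    fixation_hole_diameter = min(4, 0.3 * Rout),
    flap_depth = 0.35 * thickness
  )
  build_eye_geometry(geom, resolution)
}

#' Pure radial inflation displacement field
#'
#' A uniform radial expansion of the carrier sphere by `delta`, sampled over
#' a pupil. Its exact OPD under the sag projection is analytic (a
#' near-defocus profile), giving a regression target for the optical stages.
#'
#' @param base_radius Sphere radius (mm).
#' @param delta Radial expansion (mm), small relative to `base_radius`.
#' @param sample_density Number of pupil samples.
#' @param pupil_radius Pupil radius (mm).
#' @return A `surface_displacement_field`.
#' @export
make_radial_inflation_field <- function(base_radius, delta,
                                        sample_density = 2000,
                                        pupil_radius = 3) {
  if (abs(delta) > 0.05 * base_radius) {
    stop("delta must be small relative to the base radius")
  }
  xy <- sunflower_disk(sample_density, pupil_radius)
  z <- sqrt(base_radius^2 - rowSums(xy^2))
  coords <- cbind(xy, z)
  structure(list(
    surface_tag = "anterior",
    node_ids = seq_len(nrow(xy)),
    node_coords = coords,
    displacements = coords * (delta / base_radius)
  ), class = "surface_displacement_field")
}
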