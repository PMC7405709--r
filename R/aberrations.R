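#' Zernike mode table
#'
#' Double-index (n, m) table of the orthonormal (OSA/ANSI-style) Zernike
#' modes up to a radial order, in standard single-index ordering (n
#' ascending, m from -n to n in steps of 2).
#'
#' @param max_order Maximum radial order n.
#' @return data.frame with columns `j` (0-based OSA index), `n`, `m`.
#' @export
zernike_modes <- function(max_order = 5) {
  n <- rep(0:max_order, times = 0:max_order + 1)
  m <- unlist(lapply(0:max_order, function(nn) seq(-nn, nn, by = 2)))
  j <- (n * (n + 2) + m) / 2
  data.frame(j = j, n = n, m = m)
}

# radial polynomial R_n^|m|(rho)
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  if ((n - m) %% 2 != 0) return(rho * 0)
  k <- 0:((n - m) / 2)
  coefs <- (-1)^k * factorial(n - k) /
    (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
  out <- rho * 0
  for (i in seq_along(k)) out <- out + coefs[i] * rho^(n - 2 * k[i])
  out
}

#' Evaluate an orthonormal Zernike polynomial
#'
#' Orthonormal over the unit disk with area-weighted inner product:
#' `mean(Z^2) = 1`. Normalisation `sqrt(2(n+1)/(1+delta_m0))`; `m > 0` pairs
#' with `cos(m theta)`, `m < 0` with `sin(|m| theta)`.
#'
#' @param n,m Radial and azimuthal order.
#' @param x,y Cartesian coordinates on the unit disk (vectorised).
#' @return Numeric vector of polynomial values.
#' @export
zernike_eval <- function(n, m, x, y) {
  rho <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  norm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
  rad <- zernike_radial(n, m, rho)
  if (m > 0) {
    norm * rad * cos(m * theta)
  } else if (m < 0) {
    norm * rad * sin(-m * theta)
  } else {
    norm * rad
  }
}

#' Axial sag displacement of a deformed spherical-surface point
#'
#' Given a point A = (X, Y, Z) on a sphere of radius R (apex toward +Z,
#' origin at the centre of curvature) displaced to A' = A + (dX, dY, dZ),
#' returns the axial gap D between A' and the undeformed sphere evaluated at
#' the displaced transverse position:
#' `D = dZ - (sqrt(R^2 - (X+dX)^2 - (Y+dY)^2) - sqrt(R^2 - X^2 - Y^2))`.
#' With purely axial motion (`dX = dY = 0`) this collapses to `D = dZ`.
#'
#' @param point Length-3 numeric (X, Y, Z) on the sphere (mm).
#' @param delta Length-3 numeric displacement (dX, dY, dZ) (mm).
#' @param R Sphere radius (mm).
#' @return Axial displacement D in mm.
#' @export
axial_sag_displacement <- function(point, delta, R) {
  stopifnot(length(point) == 3L, length(delta) == 3L, R > 0)
  r2_old <- point[1]^2 + point[2]^2
  r2_new <- (point[1] + delta[1])^2 + (point[2] + delta[2])^2
  if (r2_old >= R^2) stop("point lies outside the sphere's transverse domain")
  if (r2_new >= R^2) stop("displaced point leaves the sphere's transverse domain")
  unname(delta[3] - (sqrt(R^2 - r2_new) - sqrt(R^2 - r2_old)))
}

#' Optical path difference from a surface displacement
#'
#' `OPD = delta_n * D`, with the axial surface displacement `D` in mm and
#' the result converted to micrometres. For the anterior cornea the index
#' step is `n_cornea - 1 = 0.376`; for the posterior cornea the default step
#' is `n_cornea - n_aqueous = 0.040`.
#'
#' @param D Axial surface displacement(s) in mm.
#' @param delta_n Refractive-index step across the surface.
#' @return OPD in micrometres.
#' @export
opd_from_displacement <- function(D, delta_n) {
  1000 * delta_n * D
}

#' Reference optical surfaces
#'
#' Constructors for the undeformed reference surfaces used when converting
#' nodal displacements to axial sag changes: a sphere of radius `R`, or a
#' sphere with a Munnerlyn ablation profile subtracted (the post-operative
#' anterior surface). Sag values are reported relative to the centre of
#' curvature (any constant offset cancels in the displacement formula).
#'
#' @param R Sphere radius (mm).
#' @param spec For `surface_ablated_sphere`, an [ablation_spec()] applied to
#'   the sphere.
#' @return A `reference_surface` object with a `sag(x, y)` function.
#' @export
surface_sphere <- function(R) {
  stopifnot(R > 0)
  structure(list(type = "sphere", R = R,
                 sag = function(x, y) {
                   r2 <- x^2 + y^2
                   out <- rep(NA_real_, length(r2))
                   ok <- r2 < R^2
                   out[ok] <- sqrt(R^2 - r2[ok])
                   out
                 }),
            class = "reference_surface")
}

#' @rdname surface_sphere
#' @export
surface_ablated_sphere <- function(R, spec) {
  stopifnot(R > 0, inherits(spec, "ablation_spec"))
  structure(list(type = "ablated_sphere", R = R, spec = spec,
                 sag = function(x, y) {
                   r2 <- x^2 + y^2
                   out <- rep(NA_real_, length(r2))
                   ok <- r2 < R^2
                   out[ok] <- sqrt(R^2 - r2[ok]) -
                     ablation_depth_decentered(x[ok], y[ok], spec)
                   out
                 }),
            class = "reference_surface")
}

#' Wavefront map over a pupil
#'
#' Container pairing OPD samples with their pupil positions.
#'
#' @param sample_points Two-column matrix of (x, y) positions in mm.
#' @param opd_values OPD at each sample, micrometres.
#' @param pupil_radius Pupil radius in mm.
#' @param surface Label, e.g. `"anterior"` or `"posterior"`.
#' @return A `wavefront_map` object.
#' @export
wavefront_map <- function(sample_points, opd_values, pupil_radius,
                          surface = "anterior") {
  sample_points <- as.matrix(sample_points)
  stopifnot(ncol(sample_points) == 2L,
            nrow(sample_points) == length(opd_values),
            pupil_radius > 0)
  rho <- sqrt(rowSums(sample_points^2))
  if (any(rho > pupil_radius * (1 + 1e-9))) {
    stop("sample points must lie within the pupil radius")
  }
  keep <- is.finite(opd_values)
  structure(list(sample_points = sample_points[keep, , drop = FALSE],
                 opd_values = as.numeric(opd_values[keep]),
                 pupil_radius = pupil_radius, surface = surface,
                 n_masked = sum(!keep)),
            class = "wavefront_map")
}

#' Convert a surface displacement field to a wavefront map
#'
#' Applies the sag-projection and index-step conversion pointwise: for every
#' node of the field whose reference transverse position lies inside the
#' pupil, the axial surface displacement D is computed against the
#' undeformed reference surface and scaled by the index step to an OPD in
#' micrometres. Nodes whose displaced transverse position leaves the
#' reference surface domain are masked.
#'
#' @param field A `surface_displacement_field` (see
#'   [extract_surface_displacement()]) or any list with matrices
#'   `node_coords` and `displacements`.
#' @param surface A `reference_surface` ([surface_sphere()] or
#'   [surface_ablated_sphere()]).
#' @param pupil_radius Pupil radius (mm).
#' @param delta_n Refractive-index step across the surface.
#' @param pupil_center Length-2 centre of the pupil in the transverse plane
#'   (mm); the optical axis by default.
#' @return A [wavefront_map()].
#' @export
field_to_wavefront <- function(field, surface, pupil_radius,
                               delta_n = 0.376, pupil_center = c(0, 0)) {
  stopifnot(inherits(surface, "reference_surface"))
  X <- field$node_coords
  U <- field$displacements
  rel <- sweep(X[, 1:2, drop = FALSE], 2, pupil_center)
  inside <- sqrt(rowSums(rel^2)) <= pupil_radius * (1 + 1e-12)
  X <- X[inside, , drop = FALSE]
  U <- U[inside, , drop = FALSE]
  sag_old <- surface$sag(X[, 1], X[, 2])
  sag_new <- surface$sag(X[, 1] + U[, 1], X[, 2] + U[, 2])
  D <- U[, 3] - (sag_new - sag_old)
  wavefront_map(rel[inside, , drop = FALSE], opd_from_displacement(D, delta_n),
                pupil_radius, surface = surface$type)
}

#' Least-squares Zernike decomposition of a wavefront map
#'
#' Projects the OPD samples onto the orthonormal Zernike basis over the
#' pupil by linear least squares. Requires at least three samples per mode
#' and a well-conditioned design (reasonably spread samples); otherwise an
#' error advises denser sampling.
#'
#' @param map A [wavefront_map()].
#' @param max_order Maximum radial order (default 5, i.e. 21 modes).
#' @return A `zernike_spectrum`: coefficients in micrometres over the stated
#'   pupil radius, orthonormal normalisation, plus the fit residual RMS.
#' @examples
#' pts <- as.matrix(expand.grid(x = seq(-1, 1, 0.1), y = seq(-1, 1, 0.1)))
#' pts <- pts[rowSums(pts^2) <= 1, ]
#' w <- zernike_eval(2, 0, pts[, 1], pts[, 2]) * 0.5
#' fit_zernike(wavefront_map(pts, w, 1))
#' @export
fit_zernike <- function(map, max_order = 5) {
  stopifnot(inherits(map, "wavefront_map"))
  modes <- zernike_modes(max_order)
  npts <- nrow(map$sample_points)
  if (npts < 3 * nrow(modes)) {
    stop(sprintf(
      "need at least %d samples for %d modes; got %d - sample more densely",
      3 * nrow(modes), nrow(modes), npts))
  }
  xs <- map$sample_points[, 1] / map$pupil_radius
  ys <- map$sample_points[, 2] / map$pupil_radius
  A <- vapply(seq_len(nrow(modes)),
              function(i) zernike_eval(modes$n[i], modes$m[i], xs, ys),
              numeric(npts))
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    stop("rank-deficient Zernike design matrix - sample more densely")
  }
  dg <- abs(diag(qr.R(qrA)))
  if (max(dg) / min(dg) > 1e8) {
    stop("ill-conditioned Zernike design matrix - sample more densely")
  }
  coefs <- qr.coef(qrA, map$opd_values)
  resid <- map$opd_values - A %*% coefs
  zernike_spectrum(coefs, modes$n, modes$m, map$pupil_radius,
                   residual_rms = sqrt(mean(resid^2)))
}

#' Zernike coefficient spectrum
#'
#' @param coefficients Numeric vector of coefficients (micrometres).
#' @param n,m Radial/azimuthal orders, same length as `coefficients`.
#' @param pupil_radius Pupil radius (mm) over which the modes are defined.
#' @param residual_rms Optional fit residual RMS (micrometres).
#' @param normalization Convention label; only `"orthonormal"` is produced.
#' @return A `zernike_spectrum` object.
#' @export
zernike_spectrum <- function(coefficients, n, m, pupil_radius,
                             residual_rms = NA_real_,
                             normalization = "orthonormal") {
  stopifnot(length(coefficients) == length(n), length(n) == length(m),
            pupil_radius > 0)
  coefficients <- as.numeric(coefficients)
  names(coefficients) <- sprintf("Z(%d,%d)", n, m)
  structure(list(coefficients = coefficients, n = as.integer(n),
                 m = as.integer(m), pupil_radius = pupil_radius,
                 normalization = normalization, residual_rms = residual_rms),
            class = "zernike_spectrum")
}

#' Extract one Zernike coefficient
#'
#' @param spectrum A `zernike_spectrum`.
#' @param n,m Mode orders.
#' @return Coefficient in micrometres (0 if the mode is not carried).
#' @export
zcoef <- function(spectrum, n, m) {
  stopifnot(inherits(spectrum, "zernike_spectrum"))
  i <- which(spectrum$n == n & spectrum$m == m)
  if (length(i) == 0) 0 else unname(spectrum$coefficients[i])
}

#' @export
print.zernike_spectrum <- function(x, digits = 4, ...) {
  cat(sprintf("Zernike spectrum (%s), pupil radius %g mm\n",
              x$normalization, x$pupil_radius))
  big <- abs(x$coefficients) >= 10^(-digits) / 2
  if (!any(big)) {
    cat("  all coefficients below print threshold\n")
  } else {
    print(round(x$coefficients[big], digits))
  }
  if (is.finite(x$residual_rms)) {
    cat(sprintf("  fit residual RMS %.4g um\n", x$residual_rms))
  }
  invisible(x)
}

#' Induced aberration: post- minus pre-operative spectrum
#'
#' Coefficient-wise difference of two spectra with identical pupil radius
#' and normalisation; mismatched pupils are an error (no silent rescaling).
#'
#' @param post,pre `zernike_spectrum` objects.
#' @return A `zernike_spectrum` of induced coefficients.
#' @export
induced_aberration <- function(post, pre) {
  stopifnot(inherits(post, "zernike_spectrum"),
            inherits(pre, "zernike_spectrum"))
  if (abs(post$pupil_radius - pre$pupil_radius) > 1e-9) {
    stop("pupil radii differ; refit over a common pupil before differencing")
  }
  if (!identical(post$normalization, pre$normalization)) {
    stop("normalization conventions differ")
  }
  if (length(post$coefficients) != length(pre$coefficients) ||
      any(post$n != pre$n) || any(post$m != pre$m)) {
    stop("mode sets differ")
  }
  zernike_spectrum(post$coefficients - pre$coefficients, post$n, post$m,
                   post$pupil_radius)
}

#' Convert a defocus coefficient to diopters
#'
#' Standard vergence relation for the orthonormal defocus mode:
#' `Delta D = -4 sqrt(3) c20 / r^2` with `c20` in micrometres and the pupil
#' radius `r` in mm. A negative induced defocus coefficient therefore maps
#' to a positive (hyperopic) refraction shift.
#'
#' @param c20 Defocus coefficient Z(2,0) in micrometres.
#' @param pupil_radius Pupil radius in mm.
#' @return Equivalent defocus in diopters.
#' @export
defocus_to_diopters <- function(c20, pupil_radius) {
  stopifnot(pupil_radius > 0)
  -4 * sqrt(3) * c20 / pupil_radius^2
}

#' RMS wavefront error of a spectrum subset
#'
#' Root-sum-square of orthonormal coefficients over selected radial orders.
#' Piston and tilt (n < 2) are excluded by default.
#'
#' @param spectrum A `zernike_spectrum`.
#' @param orders Radial orders to include (default 2 up to the spectrum's
#'   maximum). An empty selection gives 0.
#' @return RMS in micrometres.
#' @export
rms_of <- function(spectrum, orders = NULL) {
  stopifnot(inherits(spectrum, "zernike_spectrum"))
  if (is.null(orders)) orders <- 2:max(spectrum$n)
  sel <- spectrum$n %in% orders
  if (!any(sel)) return(0)
  sqrt(sum(spectrum$coefficients[sel]^2))
}

#' Write / read a Zernike spectrum as JSON
#'
#' Serialises the coefficients keyed `"Z(n,m)"` together with the pupil
#' radius and normalisation convention.
#'
#' @param spectrum A `zernike_spectrum`.
#' @param path Output file path.
#' @return `read_spectrum` returns the `zernike_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "zernike_spectrum"))
  jsonlite::write_json(list(
    coefficients = as.list(spectrum$coefficients),
    n = spectrum$n, m = spectrum$m,
    pupil_radius = spectrum$pupil_radius,
    normalization = spectrum$normalization
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  raw <- jsonlite::fromJSON(path)
  zernike_spectrum(as.numeric(unlist(raw$coefficients)), raw$n, raw$m,
                   as.numeric(raw$pupil_radius),
                   normalization = raw$normalization)
}
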