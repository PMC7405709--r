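#' Parametric whole-eye geometry
#'
#' Describes the axisymmetric reference geometry of the globe: a spherical
#' scleral shell of outer radius `scleral_outer_radius` centred at the
#' origin, carrying a corneal cap whose anterior and posterior surfaces are
#' spheres of the stated radii. The corneal apex points toward +Z (the
#' optical axis). The limbus is the circle of transverse radius
#' `limbus_radius` where the anterior corneal sphere meets the scleral outer
#' sphere. Scleral thickness grades linearly in polar angle from
#' `scleral_thickness_limbus` at the limbus to `scleral_thickness_pole` at
#' the posterior pole. A fixation patch of diameter `fixation_hole_diameter`
#' around the posterior pole is fully constrained during solves.
#'
#' Default dimensions follow the classic Gullstrand-style schematic eye
#' (anterior corneal radius 7.7 mm, posterior 6.8 mm, central thickness
#' 0.5 mm, globe outer radius 12 mm, scleral thickness 0.5-1.0 mm).
#'
#' @param anterior_corneal_radius Anterior corneal radius of curvature (mm).
#' @param posterior_corneal_radius Posterior corneal radius (mm).
#' @param central_corneal_thickness Apical corneal thickness (mm).
#' @param scleral_outer_radius Globe outer radius (mm).
#' @param scleral_thickness_limbus,scleral_thickness_pole Scleral thickness
#'   at the limbus and at the posterior pole (mm).
#' @param limbus_radius Transverse radius of the corneoscleral junction (mm).
#' @param fixation_hole_diameter Diameter of the constrained posterior
#'   scleral patch (mm).
#' @param flap_depth Depth below the anterior surface at which the corneal
#'   mesh carries a through-layer interface (mm); must equal the thickness
#'   of any flap later cut into the mesh.
#' @return An object of class `eye_geometry`.
#' @examples
#' eye_geometry()
#' @export
eye_geometry <- function(anterior_corneal_radius = 7.7,
                         posterior_corneal_radius = 6.8,
                         central_corneal_thickness = 0.5,
                         scleral_outer_radius = 12,
                         scleral_thickness_limbus = 0.5,
                         scleral_thickness_pole = 1.0,
                         limbus_radius = 5.9,
                         fixation_hole_diameter = 4,
                         flap_depth = 0.1) {
  g <- list(R1 = anterior_corneal_radius, R2 = posterior_corneal_radius,
            cct = central_corneal_thickness, Rs = scleral_outer_radius,
            ts_limbus = scleral_thickness_limbus,
            ts_pole = scleral_thickness_pole,
            limbus_radius = limbus_radius,
            fix_diam = fixation_hole_diameter,
            flap_depth = flap_depth)
  if (any(unlist(g) <= 0)) stop("all geometry parameters must be positive")
  if (g$R2 >= g$R1) stop("posterior corneal radius must be below the anterior")
  if (g$cct >= g$R1) stop("corneal thickness must be below the anterior radius")
  if (g$limbus_radius >= g$Rs) stop("limbus radius must be below the globe radius")
  if (g$limbus_radius >= g$R1) stop("limbus radius must be below the corneal radius")
  if (g$flap_depth >= g$cct) stop("flap depth must be below the corneal thickness")
  # centres of curvature on the optical axis
  zL <- sqrt(g$Rs^2 - g$limbus_radius^2)          # limbus height
  g$z_c1 <- zL - sqrt(g$R1^2 - g$limbus_radius^2) # anterior corneal centre
  g$apex <- g$z_c1 + g$R1
  g$z_c2 <- g$apex - g$cct - g$R2                 # posterior corneal centre
  g$z_limbus <- zL
  g$theta_limbus <- atan2(g$limbus_radius, zL)
  if (g$z_c2 + g$R2 <= g$z_c1) stop("corneal shells self-intersect")
  structure(g, class = "eye_geometry")
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat(sprintf(
    paste0("Eye geometry: cornea R %g/%g mm, CCT %g mm; globe R %g mm,\n",
           "  sclera %g-%g mm thick, limbus radius %g mm, apex at z = %.3f mm\n"),
    x$R1, x$R2, x$cct, x$Rs, x$ts_limbus, x$ts_pole, x$limbus_radius, x$apex))
  invisible(x)
}

#' Hinged-flap specification
#'
#' @param thickness Flap thickness in micrometres (default 100).
#' @param diameter Flap diameter in mm (default 8).
#' @param hinge_arc Arc length of the uncut hinge along the flap edge (mm).
#' @param hinge_angle Angular position of the hinge centre in degrees,
#'   measured from +X in the corneal plane. The default 90 places the hinge
#'   superiorly (on +Y), so flap-induced asymmetries appear as vertical coma
#'   and y-trefoil and the X axis stays clean for decentration studies.
#' @return An object of class `flap_spec`.
#' @export
flap_spec <- function(thickness = 100, diameter = 8, hinge_arc = 4,
                      hinge_angle = 90) {
  if (thickness <= 0 || diameter <= 0 || hinge_arc < 0) {
    stop("flap dimensions must be positive")
  }
  if (hinge_arc > pi * diameter) {
    stop("hinge arc cannot exceed the flap circumference")
  }
  structure(list(thickness_um = thickness, diameter = diameter,
                 hinge_arc = hinge_arc, hinge_angle = hinge_angle),
            class = "flap_spec")
}

# elliptical square-to-disk mapping; square boundary maps onto the circle
square_to_disk <- function(u, v) {
  cbind(u * sqrt(1 - v^2 / 2), v * sqrt(1 - u^2 / 2))
}

# perimeter indices of an (nc+1) x (nc+1) grid, counter-clockwise from
# corner (nc, 0); idx(i, j) is the linear index of grid node (i, j)
grid_perimeter <- function(nc, idx) {
  c(idx(nc, 0:nc),                 # right edge, going up
    idx((nc - 1):0, nc),           # top edge, going left
    idx(0, (nc - 1):0),            # left edge, going down
    idx(1:(nc - 1), 0))            # bottom edge, going right
}

# cap ring radii: near-uniform from the core circle to the limbus, with the
# nearest interior rings snapped onto mandatory stations (the optical-zone
# edge and the flap radius) when those fit inside the cap
cap_ring_radii <- function(core_r, rl, nr, stations) {
  r <- seq(core_r, rl, length.out = nr + 1)[-1]
  for (s in stations) {
    if (s <= core_r * 1.3 || s >= 0.96 * rl) next
    i <- which.min(abs(r[-nr] - s))
    r[i] <- s
  }
  r <- sort(r)
  if (any(diff(c(core_r, r)) <= 1e-6)) {
    stop("mesh ring stations collide; increase the resolution")
  }
  r
}

# resolution presets (ring counts scale with level; radial stations adapt
# to the geometry)
mesh_profile <- function(resolution, geom, stations = c(3, 4)) {
  rl <- geom$limbus_radius
  Rs <- geom$Rs
  base <- if (resolution == 1) {
    list(nc = 4, core_r = min(0.9, 0.2 * rl), nr = 7, n_bands = 7,
         post_fracs = c(0.37, 0.26), n_layers = 3)
  } else if (resolution == 2) {
    list(nc = 6, core_r = min(0.8, 0.18 * rl), nr = 10, n_bands = 10,
         post_fracs = c(0.38, 0.27), n_layers = 4)
  } else if (resolution == 3) {
    list(nc = 8, core_r = min(0.7, 0.15 * rl), nr = 13, n_bands = 13,
         post_fracs = c(0.40, 0.32, 0.24), n_layers = 5)
  } else {
    stop("resolution must be 1 (coarse), 2 (fast) or 3 (production)")
  }
  post_core_r <- geom$fix_diam / 2
  post_rings <- base$post_fracs * Rs
  post_rings <- post_rings[post_rings > 1.3 * post_core_r]
  if (length(post_rings) == 0) post_rings <- 1.5 * post_core_r
  list(nc = base$nc, core_r = base$core_r,
       cap_rings = cap_ring_radii(base$core_r, rl, base$nr, stations),
       n_bands = base$n_bands, post_rings = post_rings,
       post_core_r = post_core_r, n_layers = base$n_layers)
}

# scleral thickness at polar angle theta (radians from +Z)
scleral_thickness_at <- function(geom, theta) {
  f <- (theta - geom$theta_limbus) / (pi - geom$theta_limbus)
  geom$ts_limbus + (geom$ts_pole - geom$ts_limbus) * pmin(pmax(f, 0), 1)
}

# inner endpoint of a corneal column: intersection of the inward anterior
# normal ray with the posterior corneal sphere
cornea_inner_point <- function(A, geom) {
  C1 <- c(0, 0, geom$z_c1)
  C2 <- c(0, 0, geom$z_c2)
  u <- (A - C1) / geom$R1           # outward normal
  w <- A - C2
  b <- sum(u * w)
  disc <- b^2 - (sum(w^2) - geom$R2^2)
  if (disc < 0) stop("corneal column does not reach the posterior surface")
  s <- b - sqrt(disc)
  if (s <= 0) stop("degenerate corneal column")
  list(inner = A - s * u, thickness = s, dir = -u)  # dir: into the wall
}

#' Build the tagged whole-eye hexahedral mesh
#'
#' Constructs the volume mesh of the globe from an [eye_geometry()]: an
#' all-quad surface mesh (square-core polar cap over the cornea, latitude
#' bands over the sclera, square-core cap at the posterior pole) extruded
#' through the wall thickness. Corneal columns run along the anterior
#' surface normal from the anterior to the posterior corneal sphere and
#' carry a through-layer interface at `flap_depth` below the anterior
#' surface; scleral columns run radially with linearly graded thickness.
#' Surfaces are tagged (`anterior`, `posterior` cornea, `cavity` facets with
#' outward orientation, `fixed` posterior patch).
#'
#' @param geom An [eye_geometry()].
#' @param resolution Mesh resolution level: 1 (coarse), 2 (fast),
#'   3 (production).
#' @return An object of class `eye_mesh`.
#' @examples
#' m <- build_eye_geometry(eye_geometry(), resolution = 1)
#' m
#' @export
build_eye_geometry <- function(geom = eye_geometry(), resolution = 1) {
  stopifnot(inherits(geom, "eye_geometry"))
  pf <- mesh_profile(resolution, geom)
  nc <- pf$nc
  nring <- 4 * nc

  ## ---- surface columns -------------------------------------------------
  ## cap core grid
  ij <- expand.grid(i = 0:nc, j = 0:nc)
  core_xy <- square_to_disk(2 * ij$i / nc - 1, 2 * ij$j / nc - 1) * pf$core_r
  core_idx <- function(i, j) i + (nc + 1) * j + 1L
  perim <- grid_perimeter(nc, core_idx)
  phi_ring <- atan2(core_xy[perim, 2], core_xy[perim, 1])

  cols_xy <- core_xy
  ring_ids <- list()          # column indices of each full ring, cap side
  for (r in pf$cap_rings) {
    ids <- nrow(cols_xy) + seq_len(nring)
    cols_xy <- rbind(cols_xy, r * cbind(cos(phi_ring), sin(phi_ring)))
    ring_ids[[length(ring_ids) + 1]] <- ids
  }
  n_cap <- nrow(cols_xy)
  cap_rho <- sqrt(rowSums(cols_xy^2))  # transverse radius of cap columns

  ## scleral latitude stations between limbus and posterior rings
  theta_of_rho <- function(r) pi - asin(r / geom$Rs)
  th_first_post <- theta_of_rho(pf$post_rings[1])
  th_bands <- seq(geom$theta_limbus, th_first_post,
                  length.out = pf$n_bands + 1)[-1]
  th_stations <- c(th_bands,
                   if (length(pf$post_rings) > 1)
                     theta_of_rho(pf$post_rings[-1]))
  scl_ring_ids <- list()
  scl_theta <- numeric(0)
  for (th in th_stations) {
    ids <- nrow(cols_xy) + seq_len(nring)
    r <- geom$Rs * sin(th)
    cols_xy <- rbind(cols_xy, r * cbind(cos(phi_ring), sin(phi_ring)))
    scl_ring_ids[[length(scl_ring_ids) + 1]] <- ids
    scl_theta <- c(scl_theta, rep(th, nring))
  }

  ## posterior core grid (around -Z)
  post_xy <- square_to_disk(2 * ij$i / nc - 1, 2 * ij$j / nc - 1) *
    pf$post_core_r
  post_ids <- nrow(cols_xy) + seq_len(nrow(post_xy))
  cols_xy <- rbind(cols_xy, post_xy)
  n_cols <- nrow(cols_xy)

  col_type <- c(rep("cap", n_cap),
                rep("sclera", length(th_stations) * nring),
                rep("post", nrow(post_xy)))

  ## ---- column outer points, directions, thicknesses --------------------
  outer <- matrix(NA_real_, n_cols, 3)
  dirs <- matrix(NA_real_, n_cols, 3)   # unit vector into the wall
  thick <- numeric(n_cols)
  is_cap <- col_type == "cap"
  # cornea: anterior sphere
  rho <- cap_rho
  outer[is_cap, ] <- cbind(cols_xy[is_cap, , drop = FALSE],
                           geom$z_c1 + sqrt(geom$R1^2 - rho[is_cap]^2))
  for (k in which(is_cap)) {
    ci <- cornea_inner_point(outer[k, ], geom)
    dirs[k, ] <- ci$dir
    thick[k] <- ci$thickness
  }
  # sclera bands: radial columns
  scl <- which(col_type == "sclera")
  if (length(scl)) {
    th <- scl_theta
    outer[scl, ] <- cbind(cols_xy[scl, , drop = FALSE], geom$Rs * cos(th))
    dirs[scl, ] <- -outer[scl, ] / geom$Rs
    thick[scl] <- scleral_thickness_at(geom, th)
  }
  # posterior core: radial columns around -Z
  pc <- which(col_type == "post")
  if (length(pc)) {
    rp <- sqrt(rowSums(cols_xy[pc, , drop = FALSE]^2))
    zp <- -sqrt(geom$Rs^2 - rp^2)
    outer[pc, ] <- cbind(cols_xy[pc, , drop = FALSE], zp)
    dirs[pc, ] <- -outer[pc, ] / geom$Rs
    thp <- acos(pmin(pmax(zp / geom$Rs, -1), 1))
    thick[pc] <- scleral_thickness_at(geom, thp)
  }

  ## ---- through-thickness node stations ---------------------------------
  L <- pf$n_layers
  depth_frac <- matrix(NA_real_, n_cols, L + 1)
  for (k in seq_len(n_cols)) {
    Tk <- thick[k]
    if (is_cap[k]) {
      d <- c(0, geom$flap_depth,
             geom$flap_depth + (Tk - geom$flap_depth) * seq_len(L - 1) / (L - 1))
    } else {
      d <- Tk * (0:L) / L
    }
    depth_frac[k, ] <- d
  }

  ## nodes: column-major, layer varies fastest (layer 0 = outer surface)
  node_column <- rep(seq_len(n_cols), each = L + 1)
  node_layer <- rep(0:L, times = n_cols)
  d_all <- as.vector(t(depth_frac))
  nodes <- outer[node_column, ] + dirs[node_column, ] * d_all
  node_id <- function(col, layer) (col - 1L) * (L + 1L) + layer + 1L

  ## ---- surface quads ---------------------------------------------------
  quads <- NULL
  qreg <- integer(0)  # 1 = cornea, 2 = sclera
  add_quads <- function(q, reg) {
    quads <<- rbind(quads, q)
    qreg <<- c(qreg, rep(reg, nrow(q)))
  }
  # cap core
  cq <- cbind(core_idx(ij$i[ij$i < nc & ij$j < nc], ij$j[ij$i < nc & ij$j < nc]),
              core_idx(ij$i[ij$i < nc & ij$j < nc] + 1, ij$j[ij$i < nc & ij$j < nc]),
              core_idx(ij$i[ij$i < nc & ij$j < nc] + 1, ij$j[ij$i < nc & ij$j < nc] + 1),
              core_idx(ij$i[ij$i < nc & ij$j < nc], ij$j[ij$i < nc & ij$j < nc] + 1))
  add_quads(cq, 1L)
  # ring zones (cap)
  ring_quads <- function(inner_ids, outer_ids) {
    k <- seq_len(nring)
    k2 <- c(2:nring, 1L)
    cbind(inner_ids[k], inner_ids[k2], outer_ids[k2], outer_ids[k])
  }
  prev <- perim
  for (ids in ring_ids) {
    add_quads(ring_quads(prev, ids), 1L)
    prev <- ids
  }
  # scleral bands (first connects limbus ring = last cap ring)
  for (ids in scl_ring_ids) {
    add_quads(ring_quads(prev, ids), 2L)
    prev <- ids
  }
  # last band connects to posterior core perimeter; match by azimuth
  post_perim <- post_ids[perim]
  add_quads(ring_quads(prev, post_perim), 2L)
  # posterior core quads
  pq <- cq
  pq[] <- post_ids[cq]
  add_quads(pq, 2L)

  ## ---- hexahedra -------------------------------------------------------
  nquad <- nrow(quads)
  quads <- matrix(as.integer(quads), ncol = 4)
  elems <- matrix(0L, nquad * L, 8)
  ereg <- integer(nquad * L)
  e <- 0L
  for (l in 0:(L - 1)) {
    rows <- e + seq_len(nquad)
    elems[rows, 1:4] <- as.integer(node_id(quads, l + 1L))  # deeper face
    elems[rows, 5:8] <- as.integer(node_id(quads, l))        # outer face
    ereg[rows] <- qreg
    e <- e + nquad
  }

  mesh <- structure(list(
    nodes = nodes, elems = elems, elem_region = ereg,
    node_column = node_column, node_layer = node_layer,
    n_layers = L, n_columns = n_cols,
    col_type = col_type, col_xy = cols_xy,
    col_rho = c(cap_rho, rep(NA_real_, n_cols - n_cap)),
    col_outer = outer, col_dir = dirs, col_thick = thick,
    col_depth = depth_frac,
    quads = quads, quad_region = qreg,
    geometry = geom, resolution = resolution,
    flap = NULL, ablation = NULL
  ), class = "eye_mesh")

  mesh <- orient_elements(mesh)
  mesh <- build_tags(mesh)
  mesh
}

# fix hex orientation so the reference Jacobian is positive everywhere
orient_elements <- function(mesh) {
  dj <- hex_min_detj(mesh$nodes, mesh$elems)
  bad <- dj < 0
  if (any(bad)) {
    el <- mesh$elems[bad, , drop = FALSE]
    mesh$elems[bad, ] <- el[, c(1, 4, 3, 2, 5, 8, 7, 6), drop = FALSE]
    dj <- hex_min_detj(mesh$nodes, mesh$elems)
  }
  if (any(dj <= 0)) {
    stop("mesh contains inverted (non-positive Jacobian) elements")
  }
  mesh
}

# surface tags: anterior/posterior corneal node sets, cavity facets
# (oriented away from the cavity), fixed posterior patch
build_tags <- function(mesh) {
  L <- mesh$n_layers
  geom <- mesh$geometry
  cap_cols <- which(mesh$col_type == "cap")
  nid <- function(col, layer) (col - 1L) * (L + 1L) + layer + 1L
  mesh$anterior_nodes <- nid(cap_cols, 0L)
  mesh$posterior_nodes <- nid(cap_cols, L)
  # cavity facets: deepest layer of every surface quad
  cav <- matrix(nid(mesh$quads, L), ncol = 4)
  ctr <- (mesh$nodes[cav[, 1], ] + mesh$nodes[cav[, 2], ] +
            mesh$nodes[cav[, 3], ] + mesh$nodes[cav[, 4], ]) / 4
  nrm <- quad_normals(mesh$nodes, cav)
  flip <- rowSums(nrm * ctr) < 0
  cav[flip, ] <- cav[flip, c(1, 4, 3, 2), drop = FALSE]
  mesh$cavity_facets <- cav
  # outer facets (layer 0), oriented outward
  outf <- matrix(nid(mesh$quads, 0L), ncol = 4)
  nrm <- quad_normals(mesh$nodes, outf)
  ctr <- (mesh$nodes[outf[, 1], ] + mesh$nodes[outf[, 2], ] +
            mesh$nodes[outf[, 3], ] + mesh$nodes[outf[, 4], ]) / 4
  flip <- rowSums(nrm * ctr) < 0
  outf[flip, ] <- outf[flip, c(1, 4, 3, 2), drop = FALSE]
  mesh$outer_facets <- outf
  # fixed posterior patch: every layer of columns within the hole radius
  rfix <- geom$fix_diam / 2 + 1e-6
  fix_cols <- which(sqrt(rowSums(mesh$col_xy^2)) <= rfix &
                      mesh$col_type %in% c("post", "sclera") &
                      mesh$col_outer[, 3] < 0)
  mesh$fixed_nodes <- as.vector(outer(nid(fix_cols, 0L), 0:L, `+`))
  if (length(mesh$fixed_nodes) == 0) stop("fixed patch is empty")
  mesh
}

# non-normalised quad normals (cross of the diagonals / 2 approximates the
# average normal; adequate for orientation tests and area sums)
quad_normals <- function(nodes, quads) {
  d1 <- nodes[quads[, 3], , drop = FALSE] - nodes[quads[, 1], , drop = FALSE]
  d2 <- nodes[quads[, 4], , drop = FALSE] - nodes[quads[, 2], , drop = FALSE]
  cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
        d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
        d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) / 2
}

#' @export
print.eye_mesh <- function(x, ...) {
  cat(sprintf(
    "Eye mesh: %d nodes, %d hexahedra (%d cornea, %d sclera), %d layers\n",
    nrow(x$nodes), nrow(x$elems), sum(x$elem_region == 1),
    sum(x$elem_region == 2), x$n_layers))
  if (!is.null(x$flap)) {
    cat(sprintf("  hinged flap cut: %d crack node pairs, hinge %d columns\n",
                nrow(x$flap$pairs), length(x$flap$hinge_cols)))
  }
  if (!is.null(x$ablation)) {
    cat(sprintf("  ablated: Ds = %g D over %g mm zone\n",
                x$ablation$Ds, x$ablation$O))
  }
  invisible(x)
}

#' Cut the hinged lamellar flap into the corneal mesh
#'
#' Models the flap as a crack: every node on the planar interface at flap
#' depth beneath the flap, and on the lateral cut at the flap edge, is
#' duplicated so the flap-side elements reference the copies - except along
#' the hinge arc, where the layers keep sharing nodes. The coincident pairs
#' are recorded with their contact normals (pointing from the flap side into
#' the surrounding tissue) for interface treatment during solves.
#'
#' @param mesh An uncut `eye_mesh`.
#' @param flap A [flap_spec()]. The flap thickness must match the mesh's
#'   `flap_depth` and its radius must coincide with a mesh ring.
#' @return The cut `eye_mesh`.
#' @export
cut_flap <- function(mesh, flap = flap_spec()) {
  stopifnot(inherits(mesh, "eye_mesh"), inherits(flap, "flap_spec"))
  if (!is.null(mesh$flap)) stop("mesh already carries a flap")
  geom <- mesh$geometry
  t_mm <- flap$thickness_um / 1000
  if (abs(t_mm - geom$flap_depth) > 1e-9) {
    stop(sprintf(
      "flap thickness %.3f mm does not match the mesh interface depth %.3f mm; rebuild the geometry with flap_depth = %.3f",
      t_mm, geom$flap_depth, t_mm))
  }
  rf <- flap$diameter / 2
  if (flap$hinge_arc >= pi * flap$diameter - 1e-9) {
    # limiting case: the hinge spans the whole circumference, so there is
    # no cut at all; the mesh stays topologically intact
    mesh$flap <- list(spec = flap,
                      pairs = cbind(orig = integer(0), dup = integer(0)),
                      normals = matrix(numeric(0), 0, 3),
                      trib_area = numeric(0), flap_elems = integer(0),
                      ring_cols = integer(0), hinge_cols = integer(0),
                      in_cols = integer(0))
    return(mesh)
  }
  rho <- rep(Inf, mesh$n_columns)
  capk <- mesh$col_type == "cap"
  rho[capk] <- mesh$col_rho[capk]
  tol <- 1e-6
  ring_cols <- which(abs(rho - rf) < tol)
  if (length(ring_cols) == 0) {
    stop("flap radius does not coincide with a mesh ring; use a supported diameter")
  }
  in_cols <- which(rho < rf - tol)
  if (max(mesh$col_rho[capk]) < rf) stop("flap exceeds the corneal cap")
  # hinge: ring columns within the hinge arc
  half_ang <- (flap$hinge_arc / 2) / rf
  phi <- atan2(mesh$col_xy[, 2], mesh$col_xy[, 1])
  dphi <- abs(((phi - flap$hinge_angle * pi / 180 + pi) %% (2 * pi)) - pi)
  hinge_cols <- ring_cols[dphi[ring_cols] <= half_ang + tol]

  L <- mesh$n_layers
  nid <- function(col, layer) (col - 1L) * (L + 1L) + layer + 1L

  # flap elements: layer-0 hexes whose quad lies inside the flap circle
  qin <- matrix(rho[mesh$quads] <= rf + tol, ncol = 4)
  flap_quads <- which(rowSums(qin) == 4 & mesh$quad_region == 1L)
  flap_elems <- flap_quads  # layer-0 block comes first in elems
  stopifnot(all(mesh$elem_region[flap_elems] == 1L))

  # nodes to duplicate (split set)
  interface_nodes <- nid(setdiff(c(in_cols, ring_cols), hinge_cols), 1L)
  lateral_top <- nid(setdiff(ring_cols, hinge_cols), 0L)
  split <- sort(unique(c(interface_nodes, lateral_top)))

  nnode <- nrow(mesh$nodes)
  dup_of <- integer(0)
  new_id <- setNames(nnode + seq_along(split), split)
  mesh$nodes <- rbind(mesh$nodes, mesh$nodes[split, , drop = FALSE])
  mesh$node_column <- c(mesh$node_column, mesh$node_column[split])
  mesh$node_layer <- c(mesh$node_layer, mesh$node_layer[split])

  # remap flap-element connectivity onto the duplicates
  el <- mesh$elems[flap_elems, , drop = FALSE]
  hit <- matrix(match(el, split, nomatch = 0L), ncol = 8)
  el[hit > 0] <- nnode + hit[hit > 0]
  mesh$elems[flap_elems, ] <- el

  # coincident pairs and contact normals (from flap side into counterpart)
  cols_s <- mesh$node_column[split]
  lays_s <- mesh$node_layer[split]
  normals <- matrix(NA_real_, length(split), 3)
  is_iface <- lays_s == 1L & rho[cols_s] < rf - tol
  normals[is_iface, ] <- mesh$col_dir[cols_s[is_iface], , drop = FALSE]
  lat <- !is_iface
  normals[lat, ] <- cbind(cos(phi[cols_s[lat]]), sin(phi[cols_s[lat]]), 0)

  # tributary areas from flap-quad areas
  area <- sqrt(rowSums(quad_normals(mesh$nodes,
                                    nid(mesh$quads[flap_quads, , drop = FALSE], 1L))^2))
  atrib <- numeric(mesh$n_columns)
  for (i in seq_along(flap_quads)) {
    cs <- mesh$quads[flap_quads[i], ]
    atrib[cs] <- atrib[cs] + area[i] / 4
  }

  mesh$flap <- list(
    spec = flap, pairs = cbind(orig = split, dup = unname(new_id)),
    normals = normals, trib_area = atrib[cols_s],
    flap_elems = flap_elems, ring_cols = ring_cols, hinge_cols = hinge_cols,
    in_cols = in_cols
  )
  mesh
}

#' Apply the Munnerlyn ablation to the stromal bed
#'
#' Subtracts the ablation depth from the stromal surface beneath the flap
#' and repositions the flap onto the new bed: all corneal nodes of a column
#' inside the optical zone, from the anterior surface down to the
#' flap/stroma interface, shift axially (along -Z) by the local depth
#' `l(d)`, and deeper bed nodes are re-spaced between the lowered interface
#' and the unchanged posterior surface. Outside the optical zone the mesh is
#' untouched. `Ds = 0` is the identity.
#'
#' @param mesh An `eye_mesh` with the flap already cut (unless `Ds = 0`).
#' @param spec An [ablation_spec()].
#' @return The ablated `eye_mesh`.
#' @export
apply_ablation <- function(mesh, spec) {
  stopifnot(inherits(mesh, "eye_mesh"), inherits(spec, "ablation_spec"))
  if (!is.null(mesh$ablation)) stop("mesh already ablated")
  if (spec$Ds == 0) {
    mesh$ablation <- list(Ds = 0, O = spec$O, spec = spec)
    return(mesh)
  }
  if (is.null(mesh$flap)) stop("cut the flap before ablating the stromal bed")
  rf <- mesh$flap$spec$diameter / 2
  reach <- spec$O / 2 + sqrt(sum(spec$decenter^2))
  if (reach > rf + 1e-9) {
    stop("optical zone (with decentration) extends beyond the flap")
  }
  L <- mesh$n_layers
  geom <- mesh$geometry
  nid <- function(col, layer) (col - 1L) * (L + 1L) + layer + 1L
  capk <- which(mesh$col_type == "cap")
  d <- sqrt((mesh$col_xy[capk, 1] - spec$decenter[1])^2 +
              (mesh$col_xy[capk, 2] - spec$decenter[2])^2)
  lcol <- ablation_depth(pmin(d, spec$O / 2), spec)
  lcol[d >= spec$O / 2] <- 0
  act <- which(lcol > 0)
  # perforation guard: ablation must leave stromal bed below the interface
  bed0 <- mesh$col_thick[capk] - geom$flap_depth
  if (any(lcol[act] >= bed0[act] - 1e-9)) {
    stop("ablation would perforate the residual stromal bed")
  }
  dup_lookup <- mesh$flap$pairs
  for (k in act) {
    col <- capk[k]
    l <- lcol[k]
    moved <- nid(col, 0:1)
    # include duplicated (flap-side) copies of these nodes
    moved <- c(moved, dup_lookup[dup_lookup[, "orig"] %in% moved, "dup"])
    mesh$nodes[moved, 3] <- mesh$nodes[moved, 3] - l
    # re-space deeper bed nodes between new interface and posterior node
    if (L > 2) {
      top <- mesh$nodes[nid(col, 1L), ]
      bot <- mesh$nodes[nid(col, L), ]
      d1 <- mesh$col_depth[col, 2]
      dT <- mesh$col_depth[col, L + 1]
      for (lay in 2:(L - 1)) {
        f <- (mesh$col_depth[col, lay + 1] - d1) / (dT - d1)
        mesh$nodes[nid(col, lay), ] <- top + f * (bot - top)
      }
    }
  }
  dj <- hex_min_detj(mesh$nodes, mesh$elems)
  if (any(dj <= 0)) stop("ablation inverted mesh elements")
  mesh$ablation <- list(Ds = spec$Ds, O = spec$O, spec = spec,
                        depth_by_column = lcol)
  mesh
}

#' Merge coincident crack nodes back together
#'
#' Undoes [cut_flap()]: duplicated nodes are merged onto their originals and
#' the node list is re-compacted. With no ablation applied this reproduces
#' the intact mesh node-for-node.
#'
#' @param mesh A cut `eye_mesh`.
#' @return The merged `eye_mesh`.
#' @export
merge_coincident_nodes <- function(mesh) {
  stopifnot(inherits(mesh, "eye_mesh"))
  if (is.null(mesh$flap)) return(mesh)
  pairs <- mesh$flap$pairs
  map <- seq_len(nrow(mesh$nodes))
  map[pairs[, "dup"]] <- pairs[, "orig"]
  keep <- setdiff(seq_len(nrow(mesh$nodes)), pairs[, "dup"])
  renum <- integer(nrow(mesh$nodes))
  renum[keep] <- seq_along(keep)
  mesh$elems[] <- renum[map[mesh$elems]]
  mesh$nodes <- mesh$nodes[keep, , drop = FALSE]
  mesh$node_column <- mesh$node_column[keep]
  mesh$node_layer <- mesh$node_layer[keep]
  mesh$flap <- NULL
  mesh
}

#' Total mesh volume
#'
#' Sum of hexahedral element volumes by 2x2x2 Gauss quadrature.
#'
#' @param mesh An `eye_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  sum(hex_volumes(mesh$nodes, mesh$elems))
}

#' Total pressurised (inner-cavity) facet area
#'
#' @param mesh An `eye_mesh`.
#' @return Area in mm^2.
#' @export
cavity_area <- function(mesh) {
  quad_area_sum(mesh$nodes, mesh$cavity_facets)
}

quad_area_sum <- function(nodes, quads) {
  # exact bilinear-quad area by 2x2 quadrature
  gp <- 1 / sqrt(3)
  pts <- expand.grid(xi = c(-gp, gp), eta = c(-gp, gp))
  total <- 0
  x1 <- nodes[quads[, 1], , drop = FALSE]; x2 <- nodes[quads[, 2], , drop = FALSE]
  x3 <- nodes[quads[, 3], , drop = FALSE]; x4 <- nodes[quads[, 4], , drop = FALSE]
  for (g in seq_len(4)) {
    xi <- pts$xi[g]; eta <- pts$eta[g]
    dxi <- (-(1 - eta) * x1 + (1 - eta) * x2 + (1 + eta) * x3 - (1 + eta) * x4) / 4
    det_ <- (-(1 - xi) * x1 - (1 + xi) * x2 + (1 + xi) * x3 + (1 - xi) * x4) / 4
    cr <- cbind(dxi[, 2] * det_[, 3] - dxi[, 3] * det_[, 2],
                dxi[, 3] * det_[, 1] - dxi[, 1] * det_[, 3],
                dxi[, 1] * det_[, 2] - dxi[, 2] * det_[, 1])
    total <- total + sum(sqrt(rowSums(cr^2)))
  }
  total
}

#' Semi-analytic inner-cavity surface area
#'
#' Area of the axisymmetric limit surface the cavity facets approximate
#' (posterior corneal cap joined to the graded-thickness scleral inner
#' surface), by fine surface-of-revolution quadrature along the same column
#' construction used by the mesher. Serves as the oracle for the
#' pressure-facet area invariant.
#'
#' @param geom An [eye_geometry()].
#' @param n Number of quadrature stations per segment.
#' @return Area in mm^2.
#' @export
analytic_cavity_area <- function(geom, n = 4000) {
  # corneal part: inner endpoints of columns at transverse radius rho
  rho <- seq(0, geom$limbus_radius, length.out = n)
  inner <- t(vapply(rho, function(r) {
    A <- c(r, 0, geom$z_c1 + sqrt(geom$R1^2 - r^2))
    cornea_inner_point(A, geom)$inner
  }, numeric(3)))
  area_revolution <- function(r, z) {
    dr <- diff(r); dz <- diff(z)
    ds <- sqrt(dr^2 + dz^2)
    sum(2 * pi * (r[-1] + r[-length(r)]) / 2 * ds)
  }
  a_cornea <- area_revolution(inner[, 1], inner[, 3])
  # scleral part: r(theta) = Rs - t(theta)
  th <- seq(geom$theta_limbus, pi, length.out = n)
  rr <- geom$Rs - scleral_thickness_at(geom, th)
  a_sclera <- area_revolution(rr * sin(th), rr * cos(th))
  a_cornea + a_sclera
}

#' Check that the mesh encloses the cavity watertightly
#'
#' Verifies that every element facet is either shared by exactly two
#' elements or accounted for as an outer-surface, cavity, or crack facet.
#'
#' @param mesh An `eye_mesh`.
#' @return TRUE invisibly; errors otherwise.
#' @export
check_watertight <- function(mesh) {
  faces <- rbind(
    mesh$elems[, c(1, 2, 3, 4)], mesh$elems[, c(5, 6, 7, 8)],
    mesh$elems[, c(1, 2, 6, 5)], mesh$elems[, c(2, 3, 7, 6)],
    mesh$elems[, c(3, 4, 8, 7)], mesh$elems[, c(4, 1, 5, 8)]
  )
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  cnt <- table(key)
  n_boundary <- sum(cnt == 1)
  if (any(cnt > 2)) stop("non-manifold facets present")
  n_crack <- if (!is.null(mesh$flap)) {
    # crack contributes coincident-but-distinct facet pairs, all boundary
    NA_integer_
  } else 0L
  expected <- nrow(mesh$outer_facets) + nrow(mesh$cavity_facets)
  if (is.null(mesh$flap) && n_boundary != expected) {
    stop(sprintf("boundary facet count %d != tagged %d", n_boundary, expected))
  }
  invisible(TRUE)
}

## --- pure-R hex quadrature helpers (thin wrappers over the C++ core) ----

hex_min_detj <- function(nodes, elems) {
  fem_hex_detj(nodes, elems)$min_detj
}

hex_volumes <- function(nodes, elems) {
  fem_hex_detj(nodes, elems)$volume
}
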