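test_that("eye geometry validates its invariants", {
  g <- eye_geometry()
  expect_s3_class(g, "eye_geometry")
  expect_lt(g$R2, g$R1)
  expect_error(eye_geometry(posterior_corneal_radius = 8), "posterior")
  expect_error(eye_geometry(central_corneal_thickness = -1), "positive")
  expect_error(eye_geometry(limbus_radius = 13), "limbus")
  expect_error(eye_geometry(flap_depth = 0.6), "flap depth")
})

test_that("the meshed surfaces lie on their defining spheres", {
  g <- eye_geometry()
  m <- build_eye_geometry(g, 1)
  an <- m$nodes[m$anterior_nodes, ]
  r_ant <- sqrt(an[, 1]^2 + an[, 2]^2 + (an[, 3] - g$z_c1)^2)
  expect_lt(max(abs(r_ant - g$R1)), 1e-9)
  po <- m$nodes[m$posterior_nodes, ]
  r_pos <- sqrt(po[, 1]^2 + po[, 2]^2 + (po[, 3] - g$z_c2)^2)
  expect_lt(max(abs(r_pos - g$R2)), 1e-9)
  # scleral outer nodes on the globe sphere
  scl <- which(m$node_layer == 0 & m$col_type[m$node_column] != "cap")
  expect_lt(max(abs(sqrt(rowSums(m$nodes[scl, ]^2)) - g$Rs)), 1e-9)
})

test_that("meshes are watertight with oriented, convergent cavity areas", {
  g <- eye_geometry()
  a_exact <- analytic_cavity_area(g)
  errs <- vapply(1:3, function(res) {
    m <- build_eye_geometry(g, res)
    check_watertight(m)
    expect_gt(min(hex_min_detj(m$nodes, m$elems)), 0)
    # all cavity facets oriented away from the cavity interior
    nrm <- eyefem:::quad_normals(m$nodes, m$cavity_facets)
    ctr <- (m$nodes[m$cavity_facets[, 1], ] + m$nodes[m$cavity_facets[, 2], ] +
              m$nodes[m$cavity_facets[, 3], ] + m$nodes[m$cavity_facets[, 4], ]) / 4
    expect_true(all(rowSums(nrm * ctr) > 0))
    # a closed surface has zero net area vector
    expect_lt(max(abs(colSums(nrm))), 1e-9 * cavity_area(m))
    abs(cavity_area(m) / a_exact - 1)
  }, 0)
  expect_true(all(diff(errs) < 0))            # refinement converges
  expect_lt(errs[3], 0.01)                    # within 1% at production
})

test_that("fixation patch sits on the posterior pole", {
  m <- build_eye_geometry(eye_geometry(fixation_hole_diameter = 4), 1)
  expect_gt(length(m$fixed_nodes), 0)
  fx <- m$nodes[m$fixed_nodes, ]
  expect_true(all(sqrt(fx[, 1]^2 + fx[, 2]^2) <= 2 + 1e-6))
  expect_true(all(fx[, 3] < 0))
})

test_that("flap cut duplicates the crack and preserves the hinge", {
  m <- build_eye_geometry(eye_geometry(), 2)
  mc <- cut_flap(m, flap_spec())
  fl <- mc$flap
  expect_gt(nrow(fl$pairs), 0)
  # duplicates coincide with their originals in the reference state
  expect_equal(mc$nodes[fl$pairs[, "dup"], ], mc$nodes[fl$pairs[, "orig"], ])
  # hinge shares nodes: hinge columns never appear among the pairs
  hinge_nodes <- which(mc$node_column %in% fl$hinge_cols)
  expect_false(any(fl$pairs %in% hinge_nodes))
  # shared-edge fraction approximates hinge arc / flap circumference
  frac <- length(fl$hinge_cols) / length(fl$ring_cols)
  expect_lt(abs(frac - 4 / (pi * 8)), 0.06)
  # interface pairs sit exactly at flap depth below the anterior surface
  iface <- fl$pairs[mc$node_layer[fl$pairs[, "orig"]] == 1, "orig"]
  cols <- mc$node_column[iface]
  d <- sqrt(rowSums((mc$nodes[iface, ] - mc$col_outer[cols, ])^2))
  expect_equal(d, rep(0.1, length(d)), tolerance = 1e-9)
  # mismatched thickness is refused with guidance
  expect_error(cut_flap(m, flap_spec(thickness = 150)), "rebuild")
  expect_error(cut_flap(mc, flap_spec()), "already")
})

test_that("a full-circumference hinge leaves the mesh uncut", {
  m <- build_eye_geometry(eye_geometry(), 1)
  mc <- cut_flap(m, flap_spec(hinge_arc = pi * 8))
  expect_equal(nrow(mc$nodes), nrow(m$nodes))
  expect_equal(nrow(mc$flap$pairs), 0)
})

test_that("cut + null ablation + merge reproduces the intact mesh", {
  m <- build_eye_geometry(eye_geometry(), 1)
  m2 <- merge_coincident_nodes(apply_ablation(cut_flap(m, flap_spec()),
                                              ablation_spec(0)))
  expect_identical(dim(m2$nodes), dim(m$nodes))
  expect_equal(max(abs(m2$nodes - m$nodes)), 0)
  expect_identical(m2$elems, m$elems)
})

test_that("ablation reshapes the bed by the Munnerlyn profile", {
  g <- eye_geometry()
  m <- build_eye_geometry(g, 2)
  mc <- cut_flap(m, flap_spec())
  abl <- ablation_spec(-5)
  ma <- apply_ablation(mc, abl)
  nid <- function(col, lay) (col - 1L) * (m$n_layers + 1L) + lay + 1L
  apexcol <- which.min(rowSums(m$col_xy^2))
  # bed apex lowered by l(0) = 0.0667786 mm
  drop <- m$nodes[nid(apexcol, 1), 3] - ma$nodes[nid(apexcol, 1), 3]
  expect_equal(drop, 0.066778608, tolerance = 1e-6)
  # anterior surface (repositioned flap) lowered by the same amount
  drop0 <- m$nodes[nid(apexcol, 0), 3] - ma$nodes[nid(apexcol, 0), 3]
  expect_equal(drop0, drop, tolerance = 1e-12)
  # outside the optical zone the mesh is untouched
  far <- which(m$col_rho > 3.05 & m$col_type == "cap")
  ids <- as.vector(outer(nid(far, 0L), 0:m$n_layers, `+`))
  expect_equal(ma$nodes[ids, ], m$nodes[ids, ])
  expect_error(apply_ablation(ma, abl), "already")
  expect_error(apply_ablation(m, ablation_spec(-5)), "flap")
})

test_that("ablated volume matches the analytic Munnerlyn integral", {
  m <- build_eye_geometry(eye_geometry(), 3)
  mc <- cut_flap(m, flap_spec())
  for (Ds in c(-5, -12)) {
    abl <- ablation_spec(Ds)
    ma <- apply_ablation(mc, abl)
    removed <- mesh_volume(mc) - mesh_volume(ma)
    expect_lt(abs(removed / ablation_volume(abl) - 1), 0.02)
  }
})

test_that("decentred ablation shifts the profile's centre of symmetry", {
  m <- build_eye_geometry(eye_geometry(), 2)
  mc <- cut_flap(m, flap_spec())
  ma <- apply_ablation(mc, ablation_spec(-6, decenter = c(1, 0)))
  lc <- ma$ablation$depth_by_column
  capxy <- m$col_xy[m$col_type == "cap", , drop = FALSE]
  deepest <- capxy[which.max(lc), ]
  expect_equal(unname(deepest[1]), 1, tolerance = 0.35)  # nearest column
  expect_lt(abs(deepest[2]), 0.35)
  # zone must stay within the flap
  expect_error(apply_ablation(mc, ablation_spec(-6, decenter = c(1.5, 0))),
               "beyond the flap")
})

test_that("ablation refuses to perforate the residual stroma", {
  g <- eye_geometry(central_corneal_thickness = 0.28)
  m <- build_eye_geometry(g, 1)
  mc <- cut_flap(m, flap_spec())
  expect_error(apply_ablation(mc, ablation_spec(-15)), "perforate")
})

test_that("meshes survive a VTK round trip", {
  skip_if_not_installed("xml2")
  m <- build_eye_geometry(eye_geometry(), 1)
  tf <- tempfile(fileext = ".vtu")
  on.exit(unlink(tf))
  write_vtu(m, tf, point_data = list(layer = as.numeric(m$node_layer),
                                     coords = m$nodes))
  back <- read_vtu(tf)
  expect_equal(back$nodes, m$nodes, tolerance = 1e-12)
  expect_identical(back$elems, m$elems)
  expect_equal(back$point_data$layer, as.numeric(m$node_layer))
})
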