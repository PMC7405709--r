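#' Experiment configuration
#'
#' Plain (serialisable) description of a simulation campaign: geometry,
#' materials, surgery, solver and sampling settings. All units are mm, um,
#' diopters and mm Hg as documented per field. Round-trips losslessly
#' through YAML ([write_config()] / [read_config()]).
#'
#' @param geometry Named list of [eye_geometry()] arguments (defaults used
#'   when empty).
#' @param materials List with element `case`: `NULL` for the baseline
#'   fitted cornea/sclera constants, or a bundled stiffness-case label 1-8.
#' @param surgery List: `Ds_list` (diopter sweep values), `O` (optical zone
#'   diameter, mm), `flap_thickness_um`, `flap_diameter`, `hinge_arc`,
#'   `hinge_angle`, `decenter_list` (X offsets, mm), `pupil_diameters` (mm).
#' @param solver List: `iop` (mm Hg), `iop_list` (sweep values), `load_steps`,
#'   `newton_tol`, `flap_interface_mode`.
#' @param resolution Mesh resolution level 1-3 (1 ~ minutes-scale sweeps;
#'   3 ~ convergence studies).
#' @param seed Integer seed recorded with outputs (the solver itself is
#'   deterministic; the seed governs any synthetic fixtures).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(geometry = list(),
                              materials = list(case = NULL),
                              surgery = list(),
                              solver = list(),
                              resolution = 1,
                              seed = 1) {
  s_def <- list(Ds_list = as.numeric(-(1:15)), O = 6,
                flap_thickness_um = 100, flap_diameter = 8,
                hinge_arc = 4, hinge_angle = 90,
                decenter_list = seq(0, 1, by = 0.25),
                pupil_diameters = c(6, 7))
  v_def <- list(iop = 15, iop_list = c(10, 15, 20, 25, 30, 35),
                load_steps = 5, newton_tol = 1e-6,
                flap_interface_mode = "no-separation")
  surgery <- utils::modifyList(s_def, surgery)
  solver <- utils::modifyList(v_def, solver)
  if (length(surgery$Ds_list) == 0 || length(solver$iop_list) == 0 ||
      length(surgery$decenter_list) == 0 ||
      length(surgery$pupil_diameters) == 0) {
    stop("every sweep axis must be non-empty")
  }
  cfg <- structure(list(geometry = geometry, materials = materials,
                        surgery = surgery, solver = solver,
                        resolution = resolution, seed = seed),
                   class = "experiment_config")
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "Experiment config [%s]: %d diopters, IOP %s mm Hg, resolution %d, %s materials\n",
    substr(config_hash(x), 1, 8), length(x$surgery$Ds_list),
    paste(range(x$solver$iop_list), collapse = "-"), x$resolution,
    if (is.null(x$materials$case)) "baseline" else
      paste("case", x$materials$case)))
  invisible(x)
}

#' Serialise / deserialise an experiment configuration
#'
#' @param cfg An [experiment_config()].
#' @param path File path for the YAML document.
#' @return `read_config` returns the `experiment_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  experiment_config(
    geometry = raw$geometry %||% list(),
    materials = raw$materials %||% list(case = NULL),
    surgery = raw$surgery %||% list(),
    solver = raw$solver %||% list(),
    resolution = raw$resolution %||% 1,
    seed = raw$seed %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Provenance hash of a configuration
#'
#' MD5 of the canonical JSON rendering; attached to every sweep output row.
#'
#' @param cfg An [experiment_config()].
#' @return Hex digest string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                           digits = NA, null = "null")), tf)
  unname(tools::md5sum(tf))
}

# resolve configured materials to Ogden objects
config_materials <- function(cfg) {
  if (is.null(cfg$materials$case)) {
    list(cornea = baseline_cornea(), sclera = baseline_sclera())
  } else {
    cs <- material_cases(cfg$materials$case)
    list(cornea = cs$cornea, sclera = cs$sclera)
  }
}

config_geometry <- function(cfg) do.call(eye_geometry, cfg$geometry)

config_solver <- function(cfg, iop) {
  solve_config(iop = iop, load_steps = cfg$solver$load_steps,
               newton_tol = cfg$solver$newton_tol,
               flap_interface_mode = cfg$solver$flap_interface_mode)
}

config_flap <- function(cfg) {
  flap_spec(thickness = cfg$surgery$flap_thickness_um,
            diameter = cfg$surgery$flap_diameter,
            hinge_arc = cfg$surgery$hinge_arc,
            hinge_angle = cfg$surgery$hinge_angle)
}

# pre-operative reference state, cached per (geometry/material/IOP/mesh) key
preop_state <- function(geom, resolution, cornea, sclera, scfg,
                        cache = NULL, verbose = FALSE) {
  key <- paste(resolution, scfg$iop, scfg$load_steps,
               paste(signif(unlist(geom), 10), collapse = ","),
               paste(signif(c(cornea$mu, cornea$alpha, sclera$mu,
                              sclera$alpha), 10), collapse = ","),
               sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  mesh <- build_eye_geometry(geom, resolution)
  sol <- solve_inflation(mesh, cornea, sclera, scfg, verbose = verbose)
  st <- list(mesh = mesh, sol = sol)
  if (!is.null(cache)) cache[[key]] <- st
  st
}

#' Simulate one surgery and its induced aberrations
#'
#' End-to-end run of a single case: builds the eye, solves the intact
#' (pre-operative) globe under IOP, cuts the flap, applies the Munnerlyn
#' ablation, solves the post-operative globe under the same IOP, converts
#' both anterior (and optionally posterior) surface displacement fields to
#' OPD over the pupil, fits Zernike spectra and differences them
#' (post - pre).
#'
#' @param Ds Correction in diopters (negative myopic; 0 = flap only).
#' @param iop Intraocular pressure (mm Hg).
#' @param cornea,sclera Incompressible [ogden_material()] objects.
#' @param geom An [eye_geometry()].
#' @param flap A [flap_spec()].
#' @param O Optical zone diameter (mm).
#' @param decenter Treatment decentration (dx, dy) in mm.
#' @param pupil_radii Pupil radii (mm) over which spectra are fitted.
#' @param resolution Mesh resolution level.
#' @param scfg A [solve_config()]; its `iop` is overridden by `iop`.
#' @param surfaces Which corneal surfaces to analyse.
#' @param delta_n_anterior Index step for the anterior surface (n - 1).
#' @param delta_n_posterior Index step for the posterior surface; default
#'   the cornea-aqueous step 0.040, set to 0.376 to mimic applying the
#'   anterior relation on both surfaces.
#' @param max_order Zernike radial order of the fits.
#' @param cache Optional environment for re-using pre-operative solves
#'   across cases with identical geometry/materials/IOP.
#' @param verbose Print solver progress.
#' @return List with `induced` (named list surface -> pupil -> induced
#'   `zernike_spectrum`), `rows` (tidy data.frame), and the two solutions.
#' @export
run_surgery_case <- function(Ds, iop = 15,
                             cornea = baseline_cornea(),
                             sclera = baseline_sclera(),
                             geom = eye_geometry(),
                             flap = flap_spec(), O = 6,
                             decenter = c(0, 0),
                             pupil_radii = 3, resolution = 1,
                             scfg = solve_config(iop = iop, load_steps = 5),
                             surfaces = c("anterior", "posterior"),
                             delta_n_anterior = 0.376,
                             delta_n_posterior = 0.040,
                             max_order = 5, cache = NULL, verbose = FALSE) {
  scfg$iop <- iop
  abl <- ablation_spec(Ds = Ds, R1 = geom$R1, O = O, decenter = decenter)
  pre <- preop_state(geom, resolution, cornea, sclera, scfg, cache, verbose)
  post_mesh <- apply_ablation(cut_flap(pre$mesh, flap), abl)
  post_sol <- solve_inflation(post_mesh, cornea, sclera, scfg,
                              verbose = verbose)

  surf_R <- c(anterior = geom$R1, posterior = geom$R2)
  surf_dn <- c(anterior = delta_n_anterior, posterior = delta_n_posterior)
  induced <- list()
  rows <- list()
  for (surf in surfaces) {
    pre_field <- extract_surface_displacement(pre$sol, surf)
    post_field <- extract_surface_displacement(post_sol, surf)
    ref_pre <- surface_sphere(surf_R[[surf]])
    ref_post <- if (surf == "anterior") {
      surface_ablated_sphere(geom$R1, abl)
    } else {
      ref_pre
    }
    for (rp in pupil_radii) {
      sp_pre <- fit_zernike(field_to_wavefront(pre_field, ref_pre, rp,
                                               surf_dn[[surf]]), max_order)
      sp_post <- fit_zernike(field_to_wavefront(post_field, ref_post, rp,
                                                surf_dn[[surf]]), max_order)
      ind <- induced_aberration(sp_post, sp_pre)
      induced[[surf]][[as.character(2 * rp)]] <- ind
      rows[[length(rows) + 1]] <- data.frame(
        ds = Ds, iop = iop, dx = decenter[1], dy = decenter[2],
        surface = surf, pupil_mm = 2 * rp,
        n = ind$n, m = ind$m, induced_um = unname(ind$coefficients)
      )
    }
  }
  list(induced = induced, rows = do.call(rbind, rows),
       pre = pre, post_sol = post_sol, ablation = abl)
}

sweep_rows <- function(rows_list, cfg, extra = NULL) {
  df <- do.call(rbind, rows_list)
  df$config_hash <- config_hash(cfg)
  if (!is.null(extra)) for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  rownames(df) <- NULL
  df
}

#' Diopter sweep of induced aberrations
#'
#' Runs the configured corrections at fixed IOP and reports the induced
#' anterior and posterior Zernike spectra per diopter, one row per
#' (Ds, surface, pupil, mode), with the configuration hash attached.
#'
#' @param cfg An [experiment_config()].
#' @param cache Optional environment for pre-op solve reuse.
#' @param verbose Print progress.
#' @return A tidy data.frame.
#' @export
run_diopter_sweep <- function(cfg = experiment_config(), cache = new.env(),
                              verbose = FALSE) {
  mats <- config_materials(cfg)
  geom <- config_geometry(cfg)
  rows <- list()
  for (Ds in cfg$surgery$Ds_list) {
    if (verbose) message("diopter sweep: Ds = ", Ds)
    cs <- run_surgery_case(
      Ds = Ds, iop = cfg$solver$iop, cornea = mats$cornea,
      sclera = mats$sclera, geom = geom, flap = config_flap(cfg),
      O = cfg$surgery$O, pupil_radii = cfg$surgery$pupil_diameters / 2,
      resolution = cfg$resolution,
      scfg = config_solver(cfg, cfg$solver$iop),
      cache = cache, verbose = verbose
    )
    rows[[length(rows) + 1]] <- cs$rows
  }
  sweep_rows(rows, cfg)
}

#' IOP sweep of induced aberrations at fixed correction
#'
#' @param cfg An [experiment_config()]; the first entry of
#'   `cfg$surgery$Ds_list` is the fixed correction (default use -6 D by
#'   passing `surgery = list(Ds_list = -6)`).
#' @param cache,verbose See [run_diopter_sweep()].
#' @return A tidy data.frame, rows per (IOP, surface, pupil, mode).
#' @export
run_iop_sweep <- function(cfg = experiment_config(surgery = list(Ds_list = -6)),
                          cache = new.env(), verbose = FALSE) {
  mats <- config_materials(cfg)
  geom <- config_geometry(cfg)
  Ds <- cfg$surgery$Ds_list[1]
  rows <- list()
  for (iop in cfg$solver$iop_list) {
    if (verbose) message("IOP sweep: ", iop, " mm Hg")
    cs <- run_surgery_case(
      Ds = Ds, iop = iop, cornea = mats$cornea, sclera = mats$sclera,
      geom = geom, flap = config_flap(cfg), O = cfg$surgery$O,
      pupil_radii = cfg$surgery$pupil_diameters / 2,
      resolution = cfg$resolution, scfg = config_solver(cfg, iop),
      cache = cache, verbose = verbose
    )
    rows[[length(rows) + 1]] <- cs$rows
  }
  sweep_rows(rows, cfg)
}

#' Treatment-decentration sweep
#'
#' X-axis decentrations of the ablation centre at fixed correction and IOP
#' (the pupil stays centred on the optical axis).
#'
#' @param cfg An [experiment_config()]; uses `cfg$surgery$decenter_list` and
#'   the first entry of `cfg$surgery$Ds_list`.
#' @param cache,verbose See [run_diopter_sweep()].
#' @return A tidy data.frame, rows per (dx, surface, pupil, mode).
#' @export
run_decentration_sweep <- function(cfg = experiment_config(
                                     surgery = list(Ds_list = -6)),
                                   cache = new.env(), verbose = FALSE) {
  mats <- config_materials(cfg)
  geom <- config_geometry(cfg)
  Ds <- cfg$surgery$Ds_list[1]
  rows <- list()
  for (dx in cfg$surgery$decenter_list) {
    if (verbose) message("decentration sweep: dx = ", dx)
    cs <- run_surgery_case(
      Ds = Ds, iop = cfg$solver$iop, cornea = mats$cornea,
      sclera = mats$sclera, geom = geom, flap = config_flap(cfg),
      O = cfg$surgery$O, decenter = c(dx, 0),
      pupil_radii = cfg$surgery$pupil_diameters / 2,
      resolution = cfg$resolution,
      scfg = config_solver(cfg, cfg$solver$iop),
      cache = cache, verbose = verbose
    )
    rows[[length(rows) + 1]] <- cs$rows
  }
  sweep_rows(rows, cfg)
}

#' Stiffness-case comparison
#'
#' Runs the bundled material cases at fixed correction and IOP. Each case's
#' pre-operative reference is solved with that case's own materials, so the
#' induced differences are like-for-like.
#'
#' @param cfg An [experiment_config()]; its `materials$case` is ignored.
#' @param cases Case labels to run (subset of 1-8).
#' @param cache,verbose See [run_diopter_sweep()].
#' @return A tidy data.frame, rows per (case, surface, pupil, mode).
#' @export
run_material_cases <- function(cfg = experiment_config(
                                 surgery = list(Ds_list = -6)),
                               cases = 1:8, cache = new.env(),
                               verbose = FALSE) {
  all_cases <- material_cases()
  if (!all(as.character(cases) %in% names(all_cases))) {
    stop("unknown material case label")
  }
  geom <- config_geometry(cfg)
  Ds <- cfg$surgery$Ds_list[1]
  rows <- list()
  for (lab in cases) {
    if (verbose) message("material case ", lab)
    mc <- all_cases[[as.character(lab)]]
    cs <- run_surgery_case(
      Ds = Ds, iop = cfg$solver$iop, cornea = mc$cornea,
      sclera = mc$sclera, geom = geom, flap = config_flap(cfg),
      O = cfg$surgery$O, pupil_radii = cfg$surgery$pupil_diameters / 2,
      resolution = cfg$resolution,
      scfg = config_solver(cfg, cfg$solver$iop),
      cache = cache, verbose = verbose
    )
    rows[[length(rows) + 1]] <- within(cs$rows, case <- lab)
  }
  sweep_rows(rows, cfg)
}

#' Hyperopic shift from a sweep table
#'
#' Filters the induced defocus rows Z(2,0) of a sweep table and converts
#' them to a refraction shift in diopters (positive = hyperopic).
#'
#' @param df A sweep result table.
#' @return The defocus rows with an extra `shift_D` column.
#' @export
hyperopic_shift <- function(df) {
  sel <- df$n == 2 & df$m == 0
  out <- df[sel, , drop = FALSE]
  out$shift_D <- defocus_to_diopters(out$induced_um, out$pupil_mm / 2)
  rownames(out) <- NULL
  out
}
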