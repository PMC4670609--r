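# ---------------------------------------------------------------------------
# Config-driven pathology scenarios: baseline calibration, pressure
# overload, staggered growth, unloading, and PV-compliance probing.
#
# Protocol defaults: baseline end-diastolic pressures LV 5 mmHg / RV 2 mmHg;
# overload doubles the affected chamber (LV 10 mmHg, RV 4 mmHg). The
# pressure is ramped up, held at its maximum while the ventricle grows, and
# finally removed. Concentric (transverse) growth thickens the wall and
# eventually shrinks the chamber; eccentric (longitudinal) growth dilates
# it progressively. See the methods vignette for the saturation behavior
# on free-standing idealized geometries.
# ---------------------------------------------------------------------------

#' Conversion between mmHg and kPa
#' @param p pressure in mmHg.
#' @return Pressure in kPa (1 mmHg = 0.1333224 kPa).
#' @export
mmhg_to_kpa <- function(p) p * 0.1333224

#' Scenario configuration
#'
#' @param geometry an [lv_geometry_params()] object (ignored when
#'   `mesh_path` is given).
#' @param mesh_path optional Gmsh MSH v4.1 file with a tagged mesh.
#' @param element_order 1 (linear tets, one internal variable per element)
#'   or 2 (quadratic tets).
#' @param fibers a [fiber_rule_params()] object.
#' @param material a [material_parameters()] object.
#' @param mode growth mode: `"transverse"` (concentric) or `"longitudinal"`
#'   (eccentric).
#' @param tau growth time constant (normalized time units).
#' @param dt growth time increment; 0.1 keeps the explicit staggered update
#'   stable during the fast early-growth phase.
#' @param n_steps number of staggered growth steps (default 60, i.e. six
#'   normalized time units of sustained overload).
#' @param theta_max optional growth cap (default none).
#' @param theta_stop end the growth phase once the largest growth
#'   multiplier reaches this value (default 1.4, i.e. 40% myocyte
#'   thickening or lengthening, the upper end of the hypertrophic range the
#'   model targets); set to `Inf` to always run all `n_steps`.
#' @param baseline_lv,baseline_rv,overload_lv,overload_rv chamber pressures
#'   in mmHg; the overload must not be below the baseline.
#' @param chamber overloaded side, `"left"` or `"right"` (right requires a
#'   bi-ventricular mesh with `endocardium_rv` tags).
#' @param probe_pressures pressures (mmHg) for the PV probe.
#' @param bc_mode Dirichlet mode, see [dirichlet_bc()].
#' @param settings a [solver_settings()].
#' @param out_dir optional output directory for CSV/VTU/manifest files.
#' @param vtu_every write a VTU snapshot every this many growth steps
#'   (0 = never).
#' @param seed reserved for future stochastic inputs; recorded in the run
#'   manifest.
#' @return Object of class `"scenario_config"`.
#' @export
scenario_config <- function(geometry = lv_geometry_params(),
                            mesh_path = NULL,
                            element_order = 1L,
                            fibers = fiber_rule_params(),
                            material = material_parameters(),
                            mode = c("transverse", "longitudinal"),
                            tau = 1, dt = 0.1, n_steps = 60L,
                            theta_max = Inf, theta_stop = 1.4,
                            baseline_lv = 5, baseline_rv = 2,
                            overload_lv = 10, overload_rv = 4,
                            chamber = c("left", "right"),
                            probe_pressures = c(1, 2.5, 5, 7.5, 10),
                            bc_mode = "clamped_ring",
                            settings = solver_settings(),
                            out_dir = NULL, vtu_every = 0L, seed = 1L) {
  mode <- match.arg(mode)
  chamber <- match.arg(chamber)
  probe_pressures <- as.numeric(unlist(probe_pressures))
  prs <- c(baseline_lv, baseline_rv, overload_lv, overload_rv)
  if (any(prs < 0)) stop("config error: pressures must be >= 0")
  if (overload_lv < baseline_lv || overload_rv < baseline_rv) {
    stop("config error: overload pressure must be >= baseline")
  }
  structure(list(geometry = geometry, mesh_path = mesh_path,
                 element_order = as.integer(element_order), fibers = fibers,
                 material = material, mode = mode, tau = tau, dt = dt,
                 n_steps = as.integer(n_steps), theta_max = theta_max,
                 theta_stop = theta_stop,
                 baseline_lv = baseline_lv, baseline_rv = baseline_rv,
                 overload_lv = overload_lv, overload_rv = overload_rv,
                 chamber = chamber, probe_pressures = probe_pressures,
                 bc_mode = bc_mode, settings = settings, out_dir = out_dir,
                 vtu_every = as.integer(vtu_every), seed = as.integer(seed)),
            class = "scenario_config")
}

#' Read a scenario configuration from YAML
#'
#' Top-level keys mirror the [scenario_config()] arguments; `geometry`,
#' `fibers`, `material` and `settings` are nested mappings passed to their
#' constructors.
#'
#' @param path YAML file.
#' @return A `"scenario_config"`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$geometry)) args$geometry <- do.call(lv_geometry_params, y$geometry)
  if (!is.null(y$fibers)) args$fibers <- do.call(fiber_rule_params, y$fibers)
  if (!is.null(y$material)) {
    args$material <- if (!is.null(y$material$B0)) {
      do.call(scale_weights, y$material)
    } else {
      do.call(material_parameters, y$material)
    }
  }
  if (!is.null(y$settings)) args$settings <- do.call(solver_settings, y$settings)
  do.call(scenario_config, args)
}

#' Build the FE model for a scenario
#' @param config a `"scenario_config"`.
#' @return List with `model` (an `"fe_model"`) and `bc`.
#' @export
build_scenario_model <- function(config) {
  mesh <- if (!is.null(config$mesh_path)) {
    read_msh(config$mesh_path)
  } else {
    make_ellipsoid_lv(config$geometry, order = config$element_order)
  }
  mesh <- assign_fibers(mesh, config$fibers)
  model <- fe_discretize(mesh)
  bc <- dirichlet_bc(mesh, config$bc_mode)
  list(model = model, bc = bc)
}

.scenario_pressures <- function(config, overloaded = FALSE) {
  lv <- if (overloaded && config$chamber == "left") config$overload_lv
        else config$baseline_lv
  prs <- list(endocardium_lv = mmhg_to_kpa(lv))
  if (config$chamber == "right") {
    stop("config error: right-sided overload requires a bi-ventricular ",
         "mesh with endocardium_rv tags; the built-in generator is LV-only")
  }
  prs
}

#' Baseline solve and homeostatic calibration
#'
#' Solves equilibrium at the baseline end-diastolic pressures and records
#' the converged total fiber stretch of every integration point as its
#' homeostatic threshold `lambda_crit`. An immediate growth step at the
#' baseline load then produces exactly zero growth (Macaulay bracket at
#' zero excess).
#'
#' @param config a `"scenario_config"`.
#' @param built optional result of [build_scenario_model()] to reuse.
#' @return List with `model`, `bc`, calibrated `state`, and the
#'   `lambda_crit` field (`m x nqp`).
#' @export
run_baseline_and_calibrate <- function(config, built = NULL) {
  built <- built %||% build_scenario_model(config)
  model <- built$model
  state <- fe_state(model, mode = config$mode, tau = config$tau,
                    theta_max = config$theta_max)
  loads <- list(pressures = .scenario_pressures(config, overloaded = FALSE),
                bc = built$bc)
  state <- newton_solve(model, state, config$material, loads,
                        config$settings)
  lam <- fiber_stretch_field(model, state$u)
  state$growth$lambda_crit <- calibrate_lambda_crit(lam, state$converged)
  list(model = model, bc = built$bc, state = state, lambda_crit = lam)
}

.record_row <- function(model, state, time, config) {
  mesh <- model$mesh
  th <- state$growth$theta
  gm <- model$grow_mask
  data.frame(
    time = time,
    chamber_volume_ml = chamber_volume(mesh, state$u),
    wall_volume_ml = wall_volume(mesh, state$u),
    theta_mean = mean(th[gm, ]),
    theta_max = max(th[gm, ]),
    excess_max = if (is.null(attr(state, "max_excess"))) NA_real_
                 else attr(state, "max_excess"),
    basal_perimeter_mm = basal_ring_perimeter(mesh, state$u))
}

#' Run a full overload pathology scenario
#'
#' Protocol: baseline solve and calibration, ramp to the overload pressure,
#' hold the pressure while growth evolves (`n_steps` staggered steps of
#' `dt`), then unload to zero pressure. Chamber volume, wall volume, growth
#' statistics and the basal-ring perimeter are recorded at every step;
#' pressure-volume curves are probed before and after growth.
#'
#' @param config a `"scenario_config"`.
#' @param probe_pv probe the PV relation before and after growth.
#' @param cal optional pre-computed result of [run_baseline_and_calibrate()]
#'   for this configuration.
#' @return Object of class `"scenario_result"`: `records` (one row per
#'   growth step, time 0 = end of the overload ramp), `pv_pre`/`pv_post`,
#'   `unloaded` (residual grown configuration at zero pressure),
#'   `baseline`, and the configuration.
#' @export
run_pathology <- function(config, probe_pv = TRUE, cal = NULL) {
  cal <- cal %||% run_baseline_and_calibrate(config)
  model <- cal$model
  state <- cal$state
  loads_over <- list(pressures = .scenario_pressures(config, TRUE),
                     bc = cal$bc)
  baseline <- list(
    chamber_volume_ml = chamber_volume(model$mesh, state$u),
    wall_volume_ml = wall_volume(model$mesh, state$u),
    lambda_range = range(state$growth$lambda_crit))
  pv_pre <- NULL
  if (probe_pv) {
    # probe the ungrown ventricle downward from the calibrated baseline
    pv_pre <- pv_probe(config, model, cal$state, cal$bc,
                       p_start = .scenario_pressures(config, FALSE))
  }
  # ramp from the baseline to the overload pressure
  state <- pressure_continuation(model, state, config$material,
                                 .scenario_pressures(config, FALSE),
                                 loads_over$pressures, cal$bc,
                                 config$settings)
  records <- .record_row(model, state, 0, config)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  theta_stop <- config$theta_stop %||% Inf
  for (s in seq_len(config$n_steps)) {
    state <- staggered_growth_step(model, state, config$material,
                                   loads_over, config$settings,
                                   dt = config$dt)
    records <- rbind(records, .record_row(model, state, s * config$dt, config))
    if (max(state$growth$theta[model$grow_mask, ]) >= theta_stop) break
    if (!is.null(out_dir) && config$vtu_every > 0L &&
        s %% config$vtu_every == 0L) {
      write_vtu(model$mesh, file.path(out_dir, sprintf("step_%04d.vtu", s)),
                displacement = state$u,
                cell_data = list(theta = rowMeans(state$growth$theta),
                                 lambda = rowMeans(attr(state, "lambda"))))
    }
  }
  # unload: remove pressure, keep the grown state
  state_unloaded <- pressure_continuation(model, state, config$material,
                                          loads_over$pressures,
                                          list(endocardium_lv = 0), cal$bc,
                                          config$settings)
  unloaded <- list(
    chamber_volume_ml = chamber_volume(model$mesh, state_unloaded$u),
    wall_volume_ml = wall_volume(model$mesh, state_unloaded$u),
    basal_perimeter_mm = basal_ring_perimeter(model$mesh, state_unloaded$u))
  pv_post <- NULL
  if (probe_pv) {
    # probe the grown ventricle downward from the held overload state
    pv_post <- pv_probe(config, model, state, cal$bc,
                        p_start = loads_over$pressures)
  }
  result <- structure(list(records = records, baseline = baseline,
                           unloaded = unloaded, pv_pre = pv_pre,
                           pv_post = pv_post, config = config,
                           final_state = state, model = model),
                      class = "scenario_result")
  if (!is.null(out_dir)) write_scenario_result(result, out_dir)
  result
}

#' Saturation diagnostics of a scenario result
#'
#' Concentric growth saturates: the wall-volume increment per unit
#' normalized time falls below 1% of the current wall volume and the growth
#' stimulus decays. Eccentric growth keeps a persistent stimulus. Returns
#' the relative wall-volume rate at the final step (1/time), the ratio of
#' final to peak growth stimulus, and total relative volume changes.
#'
#' @param result a `"scenario_result"`.
#' @return Named list of diagnostics.
#' @export
saturation_metrics <- function(result) {
  r <- result$records
  n <- nrow(r)
  dt <- diff(r$time[(n - 1):n])
  final_rate <- (r$wall_volume_ml[n] - r$wall_volume_ml[n - 1]) / dt /
    r$wall_volume_ml[n]
  list(final_wall_rate_per_time = final_rate,
       stimulus_final_over_peak = r$excess_max[n] / max(r$excess_max[-1]),
       wall_gain = r$wall_volume_ml[n] / r$wall_volume_ml[1] - 1,
       chamber_gain = r$chamber_volume_ml[n] / r$chamber_volume_ml[1] - 1,
       chamber_peak_time = r$time[which.max(r$chamber_volume_ml)])
}

#' Pressure-volume probe
#'
#' Quasi-static sweep of the chamber pressure through the configured probe
#' pressures, recording the deformed chamber volume of the (possibly grown)
#' state. The growth field is frozen, so residual stresses of incompatible
#' growth are retained. The sweep starts from the pressure the supplied
#' state is in equilibrium with and proceeds monotonically toward the probe
#' pressures (descending when the state sits above them), avoiding the
#' numerically delicate fully-unloaded configuration unless 0 is probed
#' explicitly.
#'
#' @param config a `"scenario_config"`.
#' @param model an `"fe_model"`.
#' @param state an `"fe_state"` carrying the growth field to probe.
#' @param bc Dirichlet conditions.
#' @param p_start named list of chamber pressures (kPa) the state is in
#'   equilibrium with; by default zero for an undisplaced state and the
#'   overload pressure for a displaced (grown) one.
#' @return `data.frame(pressure_mmhg, volume_ml)`, ascending in pressure.
#' @export
pv_probe <- function(config, model, state, bc = NULL, p_start = NULL) {
  bc <- bc %||% dirichlet_bc(model$mesh, config$bc_mode)
  p_start <- p_start %||% (if (all(state$u == 0)) {
    list(endocardium_lv = 0)
  } else {
    list(endocardium_lv = mmhg_to_kpa(config$overload_lv))
  })
  p0 <- (p_start$endocardium_lv %||% 0) / 0.1333224
  ps <- sort(unique(config$probe_pressures))
  sweep <- if (p0 >= max(ps)) rev(ps) else ps
  st <- state
  prev <- p_start
  vols <- stats::setNames(numeric(length(ps)), as.character(ps))
  for (p in sweep) {
    tgt <- list(endocardium_lv = mmhg_to_kpa(p))
    st <- pressure_continuation(model, st, config$material, prev, tgt, bc,
                                config$settings)
    prev <- tgt
    vols[as.character(p)] <- chamber_volume(model$mesh, st$u)
  }
  data.frame(pressure_mmhg = ps,
             volume_ml = unname(vols[as.character(ps)]))
}

#' Write scenario outputs (CSV time series, JSON manifest, final VTU)
#'
#' @param result a `"scenario_result"`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_scenario_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  if (!is.null(result$pv_pre)) {
    utils::write.csv(result$pv_pre, file.path(out_dir, "pv_pre.csv"),
                     row.names = FALSE)
    utils::write.csv(result$pv_post, file.path(out_dir, "pv_post.csv"),
                     row.names = FALSE)
  }
  cfg <- result$config
  manifest <- list(
    mode = cfg$mode, chamber = cfg$chamber,
    pressures_mmhg = list(baseline_lv = cfg$baseline_lv,
                          overload_lv = cfg$overload_lv),
    tau = cfg$tau, dt = cfg$dt, n_steps = cfg$n_steps,
    element_order = cfg$element_order,
    n_elements = result$model$m,
    n_nodes = nrow(result$model$mesh$nodes),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("cardiogrowth")),
    unloaded = result$unloaded, baseline = result$baseline)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  st <- result$final_state
  write_vtu(result$model$mesh, file.path(out_dir, "final.vtu"),
            displacement = st$u,
            cell_data = list(theta = rowMeans(st$growth$theta),
                             lambda_crit = rowMeans(st$growth$lambda_crit)))
  invisible(out_dir)
}
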