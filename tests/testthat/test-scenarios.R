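# Scenario layer: configuration, baseline calibration, pathology protocol,
# determinism, and the command-line interface. All runs here use a very
# coarse ventricle so the whole file stays fast; organ-scale phenotypes are
# exercised in the acceptance suite.

test_that("configuration defaults match the overload protocol", {
  cfg <- scenario_config()
  expect_equal(cfg$baseline_lv, 5)
  expect_equal(cfg$baseline_rv, 2)
  expect_equal(cfg$overload_lv, 10)    # "double" the baseline
  expect_equal(cfg$overload_rv, 4)
  expect_equal(cfg$tau, 1)
  expect_error(scenario_config(overload_lv = 4), "config error")
  expect_error(scenario_config(baseline_lv = -1), "config error")
  expect_equal(mmhg_to_kpa(1), 0.1333224)
})

test_that("YAML configuration round-trips through the constructors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "geometry: {nc: 8, nl: 4, nt: 1}",
    "material: {C0: 0.115, B0: 14.4, D0: 0.001}",
    "mode: longitudinal",
    "dt: 0.2",
    "n_steps: 5",
    "overload_lv: 12"), path)
  cfg <- read_scenario_config(path)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$geometry$nc, 8L)
  expect_equal(cfg$material$B$Bss, 5.76)
  expect_equal(cfg$mode, "longitudinal")
  expect_equal(cfg$overload_lv, 12)
})

test_that("baseline calibration is a fixed point of the growth update", {
  cfg <- tiny_scenario()
  cal <- cached("tiny_cal", run_baseline_and_calibrate(cfg))
  expect_true(cal$state$converged)
  expect_true(all(cal$state$growth$lambda_crit == cal$lambda_crit))

  loads <- list(pressures = list(endocardium_lv = mmhg_to_kpa(5)),
                bc = cal$bc)
  st <- staggered_growth_step(cal$model, cal$state, cfg$material, loads,
                              cfg$settings, dt = 0.5)
  expect_identical(attr(st, "max_dtheta"), 0)
  expect_identical(attr(st, "max_excess"), 0)
})

test_that("zero baseline pressure calibrates to the stress-free stretch", {
  cfg <- tiny_scenario(baseline_lv = 0, overload_lv = 0)
  cal <- run_baseline_and_calibrate(cfg)
  expect_equal(max(abs(cal$lambda_crit - 1)), 0, tolerance = 1e-9)
})

test_that("overload equal to baseline produces a constant time series", {
  cfg <- tiny_scenario(overload_lv = 5, n_steps = 3)
  res <- run_pathology(cfg, probe_pv = FALSE)
  r <- res$records
  expect_equal(nrow(r), 4L)
  expect_true(all(r$theta_max == 1))
  expect_equal(diff(r$chamber_volume_ml), rep(0, 3), tolerance = 1e-9)
})

test_that("pathology runs record a consistent, deterministic time series", {
  cfg <- tiny_scenario(n_steps = 3)
  res1 <- cached("tiny_run", run_pathology(cfg, probe_pv = FALSE))
  r <- res1$records
  expect_equal(nrow(r), 4L)
  expect_true(all(diff(r$time) > 0))
  expect_true(all(diff(r$theta_mean) >= 0))   # growth is irreversible
  expect_true(all(diff(r$theta_max) >= 0))
  expect_true(all(r$wall_volume_ml > 0 & r$chamber_volume_ml > 0))
  # unloaded grown configuration retains grown volume
  expect_gt(res1$unloaded$wall_volume_ml, res1$baseline$wall_volume_ml)

  res2 <- run_pathology(cfg, probe_pv = FALSE)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  utils::write.csv(res1$records, f1, row.names = FALSE)
  utils::write.csv(res2$records, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical outputs
})

test_that("growth stays inside the configured growth region", {
  cfg <- tiny_scenario(n_steps = 2)
  built <- build_scenario_model(cfg)
  # freeze the apex-most third of elements as non-growing
  mesh <- built$model$mesh
  zc <- vapply(seq_len(nrow(mesh$elems)), function(e) {
    mean(mesh$nodes[mesh$elems[e, 1:4], 3])
  }, 1)
  mesh$region[zc < stats::quantile(zc, 1 / 3)] <- "non_growing"
  built$model <- fe_discretize(mesh)
  cal <- run_baseline_and_calibrate(cfg, built)
  loads <- list(pressures = list(endocardium_lv = mmhg_to_kpa(10)),
                bc = cal$bc)
  st <- newton_solve(cal$model, cal$state, cfg$material, loads, cfg$settings)
  st <- staggered_growth_step(cal$model, st, cfg$material, loads,
                              cfg$settings, dt = 0.2)
  frozen <- !cal$model$grow_mask
  expect_true(any(frozen))
  expect_true(all(st$growth$theta[frozen, ] == 1))
  expect_gt(max(st$growth$theta[!frozen, ]), 1)
})

test_that("right-sided overload is refused on an LV-only mesh", {
  cfg <- tiny_scenario(chamber = "right")
  expect_error(run_baseline_and_calibrate(cfg), "bi-ventricular")
})

test_that("ungrown PV probe is reproducible and monotone in pressure", {
  cfg <- tiny_scenario()
  built <- cached("tiny_built", build_scenario_model(cfg))
  st <- fe_state(built$model, mode = cfg$mode)
  pv1 <- pv_probe(cfg, built$model, st, built$bc)
  pv2 <- pv_probe(cfg, built$model, st, built$bc)
  expect_identical(pv1, pv2)
  expect_true(all(diff(pv1$volume_ml) > 0))
  expect_equal(pv1$pressure_mmhg, c(2.5, 5))
})

test_that("scenario outputs are written to the run directory", {
  out <- withr::local_tempdir()
  cfg <- tiny_scenario(n_steps = 2, out_dir = out, vtu_every = 1L)
  res <- run_pathology(cfg, probe_pv = FALSE)
  expect_true(file.exists(file.path(out, "records.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "final.vtu")))
  expect_true(file.exists(file.path(out, "step_0002.vtu")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$mode, "transverse")
  expect_equal(man$pressures_mmhg$overload_lv, 10)
  rec <- utils::read.csv(file.path(out, "records.csv"))
  expect_equal(nrow(rec), 3L)
})

test_that("the command line interface handles usage and tiny runs", {
  expect_equal(suppressMessages(cg_cli(character(0))), 2L)
  expect_equal(suppressMessages(cg_cli("frobnicate")), 2L)
  expect_equal(suppressMessages(cg_cli(c("run", "--config", "/no/such.yaml"))), 2L)

  dir <- withr::local_tempdir()
  cfgp <- file.path(dir, "cfg.yaml")
  writeLines(c(
    "geometry: {nc: 8, nl: 4, nt: 1}",
    "n_steps: 1",
    "dt: 0.1",
    "probe_pressures: [2.5, 5]"), cfgp)

  meshp <- file.path(dir, "mesh.msh")
  expect_equal(suppressMessages(
    cg_cli(c("generate-mesh", "--config", cfgp, "--out", meshp))), 0L)
  expect_true(file.exists(meshp))

  rundir <- file.path(dir, "run")
  expect_equal(suppressMessages(
    cg_cli(c("run", "--config", cfgp, "--out-dir", rundir,
             "--log-level", "quiet"))), 0L)
  expect_true(file.exists(file.path(rundir, "records.csv")))

  expect_equal(suppressMessages(cg_cli(c("report", "--run-dir", rundir))), 0L)
  expect_true(file.exists(file.path(rundir, "summary.csv")))
})
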