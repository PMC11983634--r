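empty_scene <- function(geom = geometry_config()) {
  sc <- generate_scene(scenario_config("single", n_weeds = 1, seed = 1,
                                       belt_width = belt_width(geom)), geom)
  sc$weeds <- sc$weeds[0, , drop = FALSE]
  sc
}

test_that("a weed-free trial issues no commands and wets nothing", {
  log <- run_trial(empty_scene(), constant_cfg(0.5))
  expect_equal(nrow(log$commands), 0)
  expect_true(all(vapply(log$deposition, nrow, 0L) == 0L))
  expect_equal(nrow(log$edges), 0)
})

test_that("sub-d_min neighbours get one burst, separable ones two", {
  cfg <- constant_cfg(0.4)
  lane <- 3
  log1 <- run_trial(two_weed_scene(0.03, lane = lane), cfg) # gap < 0.05
  opens1 <- sum(log1$commands$action == "open" & log1$commands$nozzle == lane)
  expect_equal(opens1, 1L)
  expect_true(all(log1$weed_results$sprayed))
  log2 <- run_trial(two_weed_scene(0.08, lane = lane), cfg) # gap > 0.05
  opens2 <- sum(log2$commands$action == "open" & log2$commands$nozzle == lane)
  expect_equal(opens2, 2L)
  expect_true(all(log2$weed_results$sprayed))
})

test_that("valve commands alternate open/close and balance per nozzle", {
  sc <- generate_scene(scenario_config("mixed", n_weeds = 10, seed = 6))
  log <- run_trial(sc, sim_config(speed_interval = c(0.3, 0.4),
                                  delays = lead_delays(), seed = 6))
  for (nz in unique(log$commands$nozzle)) {
    acts <- log$commands$action[log$commands$nozzle == nz]
    expect_equal(acts, rep(c("open", "close"), length(acts) / 2))
  }
  # edges alternate per lane starting with rising
  for (ln in unique(log$edges$lane)) {
    kinds <- log$edges$kind[log$edges$lane == ln]
    expect_equal(kinds, rep(c("rising", "falling"), length(kinds) / 2))
  }
})

test_that("closed loop sprays every weed with bounded strip centring error", {
  for (v in c(0.35, 0.55)) {
    sc <- generate_scene(scenario_config("mixed", n_weeds = 8, seed = 31))
    log <- run_trial(sc, constant_cfg(v, seed = 31))
    expect_true(all(log$weed_results$sprayed))
    bound <- v * 0.1 + log$config$footprint_len / 2
    expect_true(all(abs(log$burst_results$error) <= bound))
    expect_true(all(log$burst_results$n_weeds >= 1))
  }
})

test_that("with zero delays both compensation modes coincide", {
  sc <- generate_scene(scenario_config("mixed", n_weeds = 6, seed = 12))
  cfg_a <- sim_config(speed_interval = c(0.3, 0.4), seed = 12,
                      delays = delay_config(0, 0, 0, 0, "as_printed"))
  cfg_b <- sim_config(speed_interval = c(0.3, 0.4), seed = 12,
                      delays = delay_config(0, 0, 0, 0, "lead"))
  la <- run_trial(sc, cfg_a)
  lb <- run_trial(sc, cfg_b)
  expect_equal(la$commands, lb$commands)
  expect_equal(la$deposition, lb$deposition)
  expect_true(all(la$weed_results$sprayed))
})

test_that("infeasible lead compensation is rejected before running", {
  sc <- two_weed_scene(0.2)
  cfg <- sim_config(speed_interval = c(0.5, 0.6),
                    geometry = geometry_config(L1 = 0.05),
                    delays = delay_config(0.1, 0.1, 0.1, comp_mode = "lead"))
  sc$config$belt_width <- belt_width(cfg$geometry)
  expect_error(run_trial(sc, cfg), "inconsistent config")
})

test_that("spraying rate degrades monotonically with detector miss rate", {
  rate_at <- function(miss) {
    sprayed <- 0; total <- 0
    for (tr in 1:20) {
      sc <- generate_scene(scenario_config("mixed", n_weeds = 4, seed = tr,
                                           belt_length = 4))
      log <- run_trial(sc, constant_cfg(0.4, seed = tr),
                       noise = noise_params(miss_prob = miss))
      sprayed <- sprayed + sum(log$weed_results$sprayed)
      total <- total + 4
    }
    sprayed / total
  }
  rates <- vapply(c(0, 0.3, 0.7), rate_at, 0)
  expect_equal(rates[1], 1)
  expect_true(all(diff(rates) <= 0))
  expect_lt(rates[3], rates[1])
})

test_that("spray is targeted: valve-open travel stays near the weed extent", {
  sc <- generate_scene(scenario_config("mixed", n_weeds = 8, seed = 44))
  cfg <- constant_cfg(0.4, seed = 44)
  log <- run_trial(sc, cfg)
  # total open time cannot exceed the trial duration
  open_time <- 0
  for (nz in unique(log$commands$nozzle)) {
    cc <- log$commands[log$commands$nozzle == nz, ]
    open_time <- open_time + sum(cc$t[cc$action == "close"] -
                                   cc$t[cc$action == "open"])
  }
  expect_lte(open_time, log$t_end)
  # wetted length is bounded by weed extent plus per-burst overheads
  wet_len <- sum(vapply(log$deposition, function(m)
    sum(m[, 2] - m[, 1]), 0))
  lanes <- assign_lanes(sc$weeds, cfg$geometry)
  weed_len <- sum(vapply(lanes, function(m)
    if (nrow(m)) sum(m[, 2] - m[, 1]) else 0, 0))
  n_bursts <- sum(log$commands$action == "open")
  overhead <- cfg$geometry$grid_depth + cfg$footprint_len +
    2 * (0.4 * 0.1) + 2 * cfg$response$d_min
  expect_lte(wet_len, weed_len + n_bursts * overhead)
})

test_that("per-weed readout localises the discoloration at the weed", {
  sc <- generate_scene(scenario_config("single", n_weeds = 5, seed = 13))
  log <- run_trial(sc, constant_cfg(0.35, seed = 13))
  wr <- log$weed_results
  expect_true(all(wr$sprayed))
  expect_true(all(wr$coverage_overlap == 1)) # isolated weeds fully wetted
  expect_true(all(abs(wr$error) <= 0.35 * 0.1 + 0.01))
  expect_true(all(wr$coverage_as_printed > 0 & wr$coverage_as_printed <= 1))
})

test_that("trial artefacts round-trip to a directory", {
  sc <- generate_scene(scenario_config("mixed", n_weeds = 4, seed = 2,
                                       belt_length = 4))
  log <- run_trial(sc, constant_cfg(0.4, seed = 2))
  dir <- withr::local_tempdir()
  write_trial_outputs(log, dir)
  expect_true(all(file.exists(file.path(dir, c("scene.csv", "speed.csv",
                                               "edges.csv", "commands.csv",
                                               "deposition.json",
                                               "metrics.tsv")))))
  back <- read_metrics_tsv(file.path(dir, "metrics.tsv"))
  expect_identical(back$error, log$weed_results$error)
})

test_that("sim_config YAML round-trips", {
  cfg <- sim_config(speed_interval = c(0.4, 0.5), n_weeds = 7, seed = 3,
                    geometry = geometry_config(L1 = 0.6),
                    response = response_config(d_min = 0.04),
                    delays = delay_config(0.01, 0.02, 0.03, 0.01, "lead"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$speed_interval, cfg$speed_interval)
  expect_equal(back$geometry$L1, 0.6)
  expect_equal(back$response$d_min, 0.04)
  expect_equal(back$delays$comp_mode, "lead")
  expect_equal(back$n_weeds, 7L)
})
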