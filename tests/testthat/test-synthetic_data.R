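test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_scan_table(desk_sim_cfg(), duration_min = 2, seed = 99)
  b <- simulate_scan_table(desk_sim_cfg(), duration_min = 2, seed = 99)
  expect_identical(a$scans, b$scans)
  c <- simulate_scan_table(desk_sim_cfg(), duration_min = 2, seed = 100)
  expect_false(identical(a$scans, c$scans))
})

test_that("simulated rows invert exactly to integer ion counts", {
  sim <- simulate_scan_table(desk_sim_cfg(), duration_min = 1, seed = 4)
  counts <- ions_per_scan(sim$scans$intensity, sim$scans$peakNoise,
                          sim$scans$resolution, sim$scans$microscans,
                          charge = sim$scans$charge)
  expect_equal(counts, round(counts), tolerance = 1e-9)
})

test_that("window ratios converge to configured abundances (LLN)", {
  # drift off, heavy ion load: ratio within 0.1% of the stochastic value
  cfg <- sim_config(agc_target = 3e7, transfer_efficiency = 1,
                    drift_rsd = 0, scan_period_s = 2)
  sim <- simulate_scan_table(cfg, duration_min = 15, seed = 55)
  scans <- add_ion_counts(sim$scans)
  r <- fragiso:::pair_window_ratio(scans, "F92 15N", "F92", run_config())
  expected <- stochastic_isotopologue_ratio("C6H6N", "N",
                                            natural_isotope_ratio("N"))
  expect_lt(abs(r$ratio / expected - 1), 0.001)
  r13 <- fragiso:::pair_window_ratio(scans, "F99 13C", "F99", run_config())
  exp13 <- stochastic_isotopologue_ratio("C4H7N2O", "C",
                                         natural_isotope_ratio("C"))
  expect_lt(abs(r13$ratio / exp13 - 1), 0.001)
})

test_that("a nine-block sequence yields the 5 + 4 block pattern", {
  cfg <- run_config()
  sim <- simulate_bracketed_sequence(config = desk_sim_cfg(), run_cfg = cfg,
                                     n_blocks = 9, seed = 2)
  expect_equal(sim$blocks$role,
               rep(c("reference", "sample"), length.out = 9))
  b <- segment_blocks(sim$scans, cfg)
  expect_equal(b$role, sim$blocks$role)
  expect_equal(max(sim$scans$time.min) < 162, TRUE)
})

test_that("true enrichment is recovered within the CI on a labeled run", {
  cfg <- desk_run_cfg()
  sim <- simulate_bracketed_sequence(c(F92.N = 200), config = desk_sim_cfg(),
                                     run_cfg = cfg, n_blocks = 9, seed = 17)
  res <- process_sequence(sim$scans, cfg)
  f92n <- res[res$fragment == "F92" & res$element == "N", ]
  expect_lt(abs(f92n$delta.permil - 200), f92n$ci95.permil)
  others <- res[!(res$fragment == "F92" & res$element == "N"), ]
  expect_true(all(abs(others$delta.permil) < others$ci95.permil))
})

test_that("instrument response distorts observed deltas in delta space", {
  cfg <- desk_run_cfg()
  sim <- simulate_bracketed_sequence(
    c(F99.N = 100), config = desk_sim_cfg(
      response_slope = c(F99.N = 0.8), response_intercept = c(F99.N = 2)),
    run_cfg = cfg, n_blocks = 9, seed = 23)
  res <- process_sequence(sim$scans, cfg)
  f99n <- res[res$fragment == "F99" & res$element == "N", ]
  expect_lt(abs(f99n$delta.permil - 82), f99n$ci95.permil + 3)
})

test_that("standard series obeys bulk mass balance and EA noise", {
  out <- simulate_standard_series(
    positions = list(list(fragment = "F92", element = "N")),
    spike_targets = 100, ea_sd = 0, seed = 5)
  expect_equal(out$standards$delta_bulk_shift, 100 / 3)
  expect_equal(out$standards$delta_calc, 100)
  expect_true(all(out$ea_records$delta_bulk == out$ea_records$delta_bulk[1]))

  out <- simulate_standard_series(
    positions = list(list(fragment = "F99", element = "C")),
    spike_targets = 200, ea_sd = 0, seed = 5)
  expect_equal(out$standards$delta_bulk_shift, 200 * 4 / 10)

  out <- simulate_standard_series(
    positions = list(list(fragment = "F92", element = "N"),
                     list(fragment = "F99", element = "N")),
    seed = 5)
  expect_equal(nrow(out$standards), 6L)
  expect_equal(out$standards$standard_id[1:3], c("A1", "A2", "A3"))
  expect_error(simulate_standard_series(
    positions = list(list(fragment = "F92", element = "O"))), "no O atom")
})

test_that("Rayleigh shift has its closed form", {
  expect_equal(rayleigh_shift(-10, 0.5), -10 * log(0.5))
  expect_equal(rayleigh_shift(-10, 1), 0)
  expect_error(rayleigh_shift(-10, 0))
})

test_that("degradation scenarios follow their trajectories", {
  scen <- list(timepoints = c(0, 2),
               trajectories = list(F99.N = c(2, 27), F99.C = c(-3, 4)))
  runs <- simulate_degradation(scen, config = desk_sim_cfg(),
                               run_cfg = desk_run_cfg(), n_blocks = 5,
                               seed = 9)
  expect_length(runs, 2L)
  expect_equal(runs[[2]]$truth$sample_deltas[["F99.N"]], 27)
  expect_equal(runs[[1]]$truth$sample_deltas[["F99.C"]], -3)
  # Rayleigh-driven alternative
  scen2 <- list(timepoints = c(0, 1), epsilon = list(F99.N = -10),
                remaining_f = c(1, 0.5))
  runs2 <- simulate_degradation(scen2, config = desk_sim_cfg(),
                                run_cfg = desk_run_cfg(), n_blocks = 3,
                                seed = 10)
  expect_equal(runs2[[2]]$truth$sample_deltas[["F99.N"]], -10 * log(0.5))
})

test_that("precision scales as one over sqrt of total ions", {
  scfg <- sim_config(agc_target = 3e4, scan_period_s = 4)
  est <- function(dur, seed) {
    # discard scales with duration so usable ions double exactly
    cfg <- run_config(block_duration_min = dur,
                      switch_discard_min = dur / 6)
    sim <- simulate_bracketed_sequence(config = scfg, run_cfg = cfg,
                                       n_blocks = 3, seed = seed)
    res <- process_sequence(sim$scans, cfg)
    res$delta.permil[res$fragment == "F92" & res$element == "C"]
  }
  short <- vapply(1:120, function(s) est(3, 6000 + s), numeric(1))
  long <- vapply(1:120, function(s) est(6, 9000 + s), numeric(1))
  ratio <- sd(short) / sd(long)
  expect_gt(ratio, sqrt(2) / 1.15)
  expect_lt(ratio, sqrt(2) * 1.15)
})

test_that("nitrogen CIs exceed carbon CIs at equal settings", {
  cfg <- desk_run_cfg()
  sim <- simulate_bracketed_sequence(config = desk_sim_cfg(), run_cfg = cfg,
                                     n_blocks = 9, seed = 41)
  res <- process_sequence(sim$scans, cfg)
  for (frag in c("F92", "F99")) {
    ci_n <- res$ci95.permil[res$fragment == frag & res$element == "N"]
    ci_c <- res$ci95.permil[res$fragment == frag & res$element == "C"]
    expect_gt(ci_n / ci_c, 1.5)
  }
})
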