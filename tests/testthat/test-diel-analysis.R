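# small hand-built trace: `days` days at `spd` samples/day, lights on first
toy_trace <- function(day_val, night_val, days = 3, spd = 96) {
  n <- days * spd
  time_s <- (seq_len(n) - 1) * 86400 / spd
  frac <- (seq_len(n) - 1) %% spd / spd
  a <- ifelse(frac < 0.5, day_val, night_val)
  diel_trace(time_s, a)
}

test_that("trace validation rejects gaps and non-increasing time", {
  expect_error(diel_trace(c(0, 30, 30), c(1, 2, 3)), "strictly increasing")
  t <- c(seq(0, 300, by = 30), 500)   # 170-s gap
  expect_error(diel_trace(t, seq_along(t)), "gaps")
})

test_that("phase summaries partition every sample exactly once", {
  tr <- toy_trace(8, -1)
  ps <- phase_summaries(tr)
  expect_equal(sum(ps$n_day) + sum(ps$n_night), nrow(tr))
  expect_equal(ps$day_mean, rep(8, 3))
  expect_equal(ps$night_mean, rep(-1, 3))
  expect_equal(ps$day_min, ps$day_max)
  # constant trace: both phases equal
  cps <- phase_summaries(toy_trace(5, 5))
  expect_true(all(cps$day_mean == 5 & cps$night_mean == 5))
  # min <= mean <= max on a noisy synthetic trace
  ns <- phase_summaries(simulate_diel_trace(sim_config(seed = 2, group = "control")))
  expect_true(all(ns$day_min <= ns$day_mean & ns$day_mean <= ns$day_max))
  expect_true(all(ns$night_min <= ns$night_mean & ns$night_mean <= ns$night_max))
})

test_that("CAM onset is the first night at or above threshold", {
  s <- data.frame(day_index = 1:4, night_mean = c(-1, -1, -0.05, 0.3))
  expect_identical(detect_cam_onset(s, threshold = -0.1)$onset_day, 3L)
  # all earlier days fail the criterion by construction
  expect_true(all(s$night_mean[s$day_index < 3] < -0.1))
  # never satisfied -> none
  flat <- data.frame(day_index = 1:4, night_mean = rep(-1, 4))
  expect_true(is.na(detect_cam_onset(flat)$onset_day))
  # control synthetic trace stays C3 throughout
  ps <- phase_summaries(simulate_diel_trace(sim_config(seed = 1, group = "control")))
  expect_true(is.na(detect_cam_onset(ps)$onset_day))
})

test_that("raising the onset threshold never makes onset earlier", {
  tr <- simulate_diel_trace(sim_config(seed = 13, group = "salt"))
  ps <- phase_summaries(tr)
  onsets <- vapply(c(-0.5, -0.1, 0.05, 0.2, 1),
                   function(th) {
                     d <- detect_cam_onset(ps, threshold = th)$onset_day
                     if (is.na(d)) Inf else as.numeric(d)
                   }, numeric(1))
  expect_true(all(diff(onsets) >= 0))
})

test_that("onset detection recovers the generator's transition day", {
  hits <- 0; runs <- 0
  for (nzd in 6:10) {
    for (s in 1:5) {
      runs <- runs + 1
      tr <- simulate_diel_trace(
        sim_config(seed = s, group = "salt"),
        diel_sim_params(onset_ramp_start_day = nzd - 2, night_zero_day = nzd))
      if (identical(detect_cam_onset(phase_summaries(tr))$onset_day,
                    as.integer(nzd))) hits <- hits + 1
    }
  }
  expect_gte(hits, runs - 1)
})

test_that("anticipation transients flag the CAM circadian signature", {
  # constant trace: zero deltas, no flag
  flat <- toy_trace(3, 3)
  r <- detect_anticipation(flat, 2)
  expect_equal(r$light_on_delta, 0)
  expect_equal(r$light_off_delta, 0)
  expect_false(r$cam_like)

  tr <- simulate_diel_trace(sim_config(seed = 42, group = "salt"))
  for (d in 9:12) expect_true(detect_anticipation(tr, d)$cam_like)
  # before the transition the night baseline is only ~-1, so the light-on
  # step, however large, never spans the CAM-like (-2, +2) envelope
  pre <- detect_anticipation(tr, 3)
  expect_false(pre$cam_like)
  expect_gt(pre$light_on_pre, -2)
  expect_error(detect_anticipation(tr, 99), "not in trace")
})

test_that("aperture stats compute the open proportion by count division", {
  tab <- data.frame(day = 1, timepoint = "4pm",
                    aperture_um = rep(2.0, 150))
  s <- aperture_stats(tab)
  expect_equal(s$open_proportion, 1)
  expect_equal(s$mean_um, 2)
  expect_equal(s$se_um, 0)
  half <- data.frame(day = 1, timepoint = "4am",
                     aperture_um = c(rep(2.0, 75), rep(0.9, 75)))
  expect_equal(aperture_stats(half)$open_proportion, 0.5)
  expect_error(aperture_stats(data.frame(day = 1, timepoint = "4pm",
                                         aperture_um = -1)), "positive")
  expect_error(aperture_stats(data.frame(day = 1, timepoint = "noon",
                                         aperture_um = 1)), "timepoint")
})

test_that("open proportion equals brute-force division on simulated tables", {
  tab <- simulate_stomata(sim_config(seed = 31, group = "salt"))
  s <- aperture_stats(tab, open_threshold = 1.4)
  for (i in seq_len(nrow(s))) {
    cell <- tab$aperture_um[tab$day == s$day[i] & tab$timepoint == s$timepoint[i]]
    expect_identical(s$open_proportion[i], sum(cell >= 1.4) / length(cell))
  }
})

test_that("stomatal inversion scan finds the first inverted day", {
  mk <- function(pm, am, d) data.frame(
    day = d, timepoint = c("4pm", "4am"), mean_um = c(pm, am))
  s <- rbind(mk(2.0, 0.9, 1), mk(0.9, 2.0, 2))
  expect_identical(detect_inversion(s), 2L)
  ctl <- aperture_stats(simulate_stomata(sim_config(seed = 2, group = "control")))
  expect_true(is.na(detect_inversion(ctl)))
  expect_error(detect_inversion(mk(2, 1, 1)[1, ]), "missing a timepoint")
})
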