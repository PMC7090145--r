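test_that("leaf scenes carry exact pixel-count ground truth", {
  # empty scene: reference square only
  sc0 <- render_leaf_scene(numeric(0), 50)
  expect_equal(sc0$truth$green_px, 0)
  expect_equal(sum(sc0$green_mask), 0)
  expect_equal(sc0$truth$ref_px, 2500)

  # a 1 cm^2 leaf has exactly as many pixels as the reference square
  sc1 <- render_leaf_scene(1.0, px_per_cm = 50, seed = 2)
  expect_equal(sum(sc1$green_mask), 2500)
  expect_equal(sum(sc1$reference_mask), 2500)
  expect_false(any(sc1$green_mask & sc1$reference_mask))

  # multi-blob total is round(sum(areas) * px^2), apportioned exactly
  sc <- render_leaf_scene(c(2.5, 0.7), px_per_cm = 40, seed = 1)
  expect_equal(sc$truth$green_px, 5120)
  expect_equal(sum(sc$truth$blob_px), 5120)
  expect_equal(sum(sc$green_mask), 5120)

  expect_error(render_leaf_scene(c(2.5, 0.7), 40, canvas_px = c(30, 30)),
               "too small")
})

test_that("scene rendering is seed-reproducible", {
  a <- render_leaf_scene(c(1.2, 0.4), 40, seed = 9)
  b <- render_leaf_scene(c(1.2, 0.4), 40, seed = 9)
  expect_identical(a$image, b$image)
})

test_that("growth simulation is exact at zero noise and seeded otherwise", {
  m <- study_control_model()
  t1 <- simulate_growth(m, -21:14, noise_sd = 0, seed = 1)
  t2 <- simulate_growth(m, -21:14, noise_sd = 0, seed = 999)
  expect_identical(t1, t2)                       # zero noise kills seed dependence
  expect_equal(t1$area_cm2, growth_area(m, -21:14))
  expect_equal(t1$area_cm2[1], 0)                # D = -21
  n1 <- simulate_growth(m, 0:14, noise_sd = 1, seed = 5)
  n2 <- simulate_growth(m, 0:14, noise_sd = 1, seed = 5)
  expect_identical(n1, n2)
})

test_that("noiseless diel traces equal their analytic template", {
  cfg <- sim_config(seed = 1, group = "control")
  tr <- simulate_diel_trace(cfg, diel_sim_params(noise_sd = 0))
  expect_equal(nrow(tr), cfg$samples_per_day * cfg$n_days)
  expect_true(all(tr$assimilation[!tr$light_on] == -1.0))
  expect_true(all(tr$assimilation[tr$light_on] >= 6.5))
  expect_true(all(tr$assimilation[tr$light_on] <= 10.5))
})

test_that("salt diel trace ramps its nightly means through the transition", {
  tr <- simulate_diel_trace(sim_config(seed = 42, group = "salt"))
  ps <- phase_summaries(tr)
  # nights before the ramp sit at the C3 baseline
  expect_true(all(abs(ps$night_mean[1:5] + 1) < 0.1))
  # the first night at or above -0.1 is the generator's night_zero_day
  expect_identical(detect_cam_onset(ps)$onset_day,
                   attr(tr, "truth")$night_zero_day)
  # post-transition nights are positive on average
  expect_true(all(ps$night_mean[9:14] > 0))
  # daytime means decay monotonically across the window
  expect_true(all(diff(ps$day_mean[5:9]) < 0))
})

test_that("diel traces are bit-reproducible under a fixed seed", {
  a <- simulate_diel_trace(sim_config(seed = 7, group = "salt"))
  b <- simulate_diel_trace(sim_config(seed = 7, group = "salt"))
  expect_identical(a, b)
})

test_that("stomata tables follow and invert the day/night phase pattern", {
  ctl <- simulate_stomata(sim_config(seed = 3, group = "control"))
  s <- aperture_stats(ctl)
  for (d in unique(s$day)) {
    expect_gt(s$mean_um[s$day == d & s$timepoint == "4pm"],
              s$mean_um[s$day == d & s$timepoint == "4am"])
  }
  # degenerate proportion: all stomata open during the open phase
  all_open <- simulate_stomata(
    sim_config(seed = 3, group = "control", n_days = 2),
    stomata_sim_params(open_fraction_when_open_phase = 1))
  ap <- aperture_stats(all_open)
  expect_true(all(ap$open_proportion[ap$timepoint == "4pm"] == 1))
})

test_that("physiology tables satisfy the weight ordering invariant", {
  for (g in c("control", "salt")) {
    ph <- simulate_physio(sim_config(seed = 11, group = g))
    expect_true(all(ph$tw_g > ph$fw_g))
    expect_true(all(ph$fw_g > ph$dw_g))
    expect_true(all(ph$dw_g > 0))
    expect_true(all(ph$od532 >= 0 & ph$od450 >= 0))
  }
  a <- simulate_physio(sim_config(seed = 4, group = "salt"))
  b <- simulate_physio(sim_config(seed = 4, group = "salt"))
  expect_identical(a, b)
})

test_that("control physiology starts at the study's baseline values", {
  ph <- simulate_physio(sim_config(seed = 21, group = "control"))
  d0 <- ph[ph$day == 0, ]
  expect_equal(mean(succulence(d0$fw_g, d0$area_cm2)), 0.12, tolerance = 0.05)
  expect_equal(mean(rwc(d0$fw_g, d0$dw_g, d0$tw_g)), 62.5, tolerance = 2)
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_diel_trace(sim_config(seed = 5, group = "salt")))
  invisible(simulate_stomata(sim_config(seed = 5, group = "salt")))
  invisible(simulate_physio(sim_config(seed = 5, group = "salt")))
  invisible(render_leaf_scene(1, 40, seed = 5))
  expect_identical(.Random.seed, before)
})
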