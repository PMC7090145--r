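ctrl_a1 <- 29.7391
ctrl_r1 <- 1.0830
salt_a2 <- 5.7849
salt_r2 <- 1.2998

test_that("growth model evaluates the piecewise exponential form", {
  m <- study_control_model()
  # at D = -tau the bracket vanishes
  expect_equal(growth_area(m, -21), 0)
  # direct arithmetic oracle at treatment day
  expect_equal(growth_area(m, 0), ctrl_a1 * (ctrl_r1^21 - 1))
  # a2 = 0 leaves the control branch untouched after the breakpoint
  m0 <- growth_model(ctrl_a1, ctrl_r1, a2 = 0, r2 = 1.5)
  expect_equal(growth_area(m0, 1:14), growth_area(m, 1:14))
  # printed-offset salt clocking makes the curve discontinuous and the
  # area negative within the treatment window
  mp <- study_salt_model(salt_term_offset = salt_offset("printed"))
  expect_error(growth_area(mp, 3), "negative area")
  expect_error(growth_area(m, -30), "-tau")
})

test_that("model is continuous at the breakpoint under the default clocking", {
  m <- study_salt_model()
  eps <- 1e-9
  expect_equal(growth_area(m, 0), growth_area(m, eps), tolerance = 1e-6)
})

test_that("control fit recovers generating parameters on noiseless data", {
  truth <- study_control_model()
  tab <- simulate_growth(truth, -21:14, noise_sd = 0)
  fit <- fit_growth_control(tab)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$a1 - ctrl_a1) / ctrl_a1, 1e-3)
  expect_lt(abs(fit$model$r1 - ctrl_r1) / ctrl_r1, 1e-3)
  expect_lt(fit$rss, 1e-8 * sum(tab$area_cm2^2))
})

test_that("all-zero data give a degenerate fit with a1 = 0", {
  fit <- fit_growth_control(data.frame(day = 0:5, area_cm2 = numeric(6)))
  expect_true(fit$degenerate)
  expect_equal(fit$model$a1, 0)
})

test_that("salt fit recovers the second term, fixed or jointly", {
  truth <- study_salt_model()
  tab <- simulate_growth(truth, -21:14, noise_sd = 0)
  ctrl <- study_control_model()
  fit <- fit_growth_salt(tab, ctrl, fix_control = TRUE)
  expect_lt(abs(fit$model$a2 - salt_a2) / salt_a2, 1e-3)
  expect_lt(abs(fit$model$r2 - salt_r2) / salt_r2, 1e-3)
  joint <- fit_growth_salt(tab, ctrl, fix_control = FALSE)
  expect_equal(joint$model$a2, fit$model$a2, tolerance = 1e-3)
  expect_equal(joint$model$r2, fit$model$r2, tolerance = 1e-3)
  # null salt effect is recovered as (numerically) zero
  tab0 <- simulate_growth(ctrl, -21:14, noise_sd = 0)
  fit0 <- fit_growth_salt(tab0, ctrl, fix_control = TRUE)
  expect_lt(fit0$model$a2 * (fit0$model$r2^14 - 1), 1e-4)
  # nothing after the breakpoint -> nothing to fit
  pre <- tab[tab$day <= 0, ]
  expect_error(fit_growth_salt(pre, ctrl), "nothing")
})

test_that("parameter recovery holds across the (a1, r1) design space", {
  set.seed(101)
  for (i in 1:50) {
    a1 <- stats::runif(1, 1, 100)
    r1 <- stats::runif(1, 1.01, 1.5)
    tab <- simulate_growth(growth_model(a1, r1), 0:14, noise_sd = 0)
    fit <- fit_growth_control(tab)
    expect_lt(abs(fit$model$a1 - a1) / a1, 1e-3)
    expect_lt(abs(fit$model$r1 - r1) / r1, 1e-3)
  }
})

test_that("returned optimum is never worse than the generating truth", {
  set.seed(202)
  truth <- study_control_model()
  days <- -21:14
  for (i in 1:5) {
    tab <- simulate_growth(truth, days, noise_sd = 1, seed = i)
    fit <- fit_growth_control(tab)
    rss_truth <- sum((tab$area_cm2 - growth_area(truth, days))^2)
    expect_lte(fit$rss, rss_truth + 1e-8)
  }
})

test_that("noisy-data fits recover the rate factor within 1% in the median", {
  errs <- vapply(1:20, function(s) {
    tab <- simulate_growth(study_control_model(), -21:14, noise_sd = 1, seed = s)
    fit <- fit_growth_control(tab)
    abs(fit$model$r1 - ctrl_r1) / ctrl_r1
  }, numeric(1))
  expect_lt(stats::median(errs), 0.01)
})

test_that("divergence day matches a brute-force scan of the printed curves", {
  mc <- study_control_model()
  ms <- study_salt_model()
  # independent scan by direct arithmetic
  expected <- NA_integer_
  for (D in 1:14) {
    ac <- ctrl_a1 * (ctrl_r1^(D + 21) - 1)
    as_ <- ac - salt_a2 * (salt_r2^D - 1)
    if ((ac - as_) > 0.05 * ac) { expected <- D; break }
  }
  expect_identical(growth_divergence_day(mc, ms, threshold = 0.05), expected)
  # identical models never diverge
  expect_identical(growth_divergence_day(mc, mc), NA_integer_)
  # zero threshold: any positive a2 diverges on the first post-breakpoint day
  expect_identical(growth_divergence_day(mc, ms, threshold = 0), 1L)
})
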