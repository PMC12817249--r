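test_that("the unweighted index sums relative changes against control", {
  ctrl <- c(cortisol = 100, glucose = 100, st = 33, hr = 70)
  expect_equal(compute_ssci1(ctrl, ctrl), 0)
  up10 <- ctrl * 1.1
  expect_equal(compute_ssci1(up10, ctrl), 0.4)
  mixed <- c(cortisol = 120, glucose = 90, st = 33, hr = 70)
  expect_equal(compute_ssci1(mixed, ctrl), 0.2 - 0.1)

  # scale invariance: scaling a biomarker's measure and control jointly
  ctrl2 <- ctrl
  ctrl2["cortisol"] <- 1000
  mixed2 <- mixed
  mixed2["cortisol"] <- 1200
  expect_equal(compute_ssci1(mixed2, ctrl2), compute_ssci1(mixed, ctrl))

  # additivity over included biomarkers
  expect_equal(
    compute_ssci1(mixed, ctrl, included = c("cortisol", "glucose")),
    compute_ssci1(mixed, ctrl, "cortisol") + compute_ssci1(mixed, ctrl, "glucose")
  )

  expect_error(compute_ssci1(mixed, c(cortisol = 0, glucose = 1, st = 1, hr = 1)),
    class = "stressci_degenerate_control"
  )
  expect_error(compute_ssci1(mixed[1:3], ctrl), class = "stressci_key_error")
})

test_that("temporally coupled relative deviation matches its closed form", {
  fit <- fit_baseline(make_cosinor_series(noise_sd = 0), "cosinor")
  b14 <- baseline_at(fit, 14)
  expect_equal(relative_deviation_t(b14, 14, fit), 0)
  expect_equal(relative_deviation_t(1.5 * b14, 14, fit), 0.5)
  expect_error(relative_deviation_t(1, 23, fit), class = "stressci_out_of_window")
})

test_that("weights are recovered exactly on noiseless data and CIs behave", {
  d <- make_cpt_like(n = 50, noise_sd = 0)
  w <- suppressWarnings(estimate_weights_mlr(d$deviations, d$scores)) # perfect fit
  expect_equal(unname(w$weights), unname(d$true_w), tolerance = 1e-8)
  expect_equal(w$intercept, 30, tolerance = 1e-8)
  expect_gt(w$fit_r2, 1 - 1e-10)

  dup <- d$deviations
  dup$glucose <- dup$cortisol
  expect_error(estimate_weights_mlr(dup, d$scores), class = "stressci_collinearity_error")
  expect_error(estimate_weights_mlr(d$deviations[1:4, ], d$scores[1:4]),
    class = "stressci_insufficient_data"
  )
})

test_that("lm-based weights agree with the normal-equations oracle", {
  d <- make_cpt_like(n = 80, noise_sd = 0.5, seed = 17)
  w <- estimate_weights_mlr(d$deviations, d$scores)
  oracle <- normal_equations_ols(d$deviations, d$scores)
  expect_equal(unname(c(w$intercept, w$weights)), oracle$coef, tolerance = 1e-10)
  expect_equal(unname(w$conf_int[, 1]), unname(oracle$ci[-1, 1]), tolerance = 1e-10)
  expect_equal(unname(w$conf_int[, 2]), unname(oracle$ci[-1, 2]), tolerance = 1e-10)
})

test_that("the weighted index is the dot product plus optional intercept", {
  w <- c(cortisol = 10, glucose = 5, hr = 2)
  dev <- c(cortisol = 0.2, glucose = 0.1, hr = 0.05)
  expect_equal(compute_ssci2(dev, w, with_intercept = FALSE), 2.6)
  expect_equal(compute_ssci2(dev, w, with_intercept = TRUE, intercept = 30), 32.6)
  expect_equal(compute_ssci2(c(cortisol = 0, glucose = 0, hr = 0), w, FALSE), 0)

  # ST-excluded configuration: a four-biomarker panel yields a 3-term sum
  dev4 <- c(dev, st = 0.5)
  expect_equal(compute_ssci2(dev4, w, with_intercept = FALSE), 2.6)

  expect_error(compute_ssci2(dev[1:2], w), class = "stressci_key_error")
})

test_that("acute-stress classification uses left-closed 34/44 cutpoints", {
  expect_equal(as.character(classify_as_state(30)), "NonAS")
  expect_equal(as.character(classify_as_state(40)), "LowAS")
  expect_equal(as.character(classify_as_state(44)), "HighAS")
  expect_equal(as.character(classify_as_state(43.999)), "LowAS")
  expect_equal(as.character(classify_as_state(34)), "LowAS")
  expect_equal(as.character(classify_as_state(33.999)), "NonAS")
  # piecewise-constant and monotone in score
  s <- classify_as_state(seq(20, 60, by = 0.5))
  expect_true(!is.unsorted(as.integer(s)))
  expect_error(classify_as_state(NaN), class = "stressci_invalid_parameter")
})

test_that("the warning trigger fires at the earliest crossing of the threshold", {
  r <- warning_trigger(c(0.1, 0.5, 0.85, 0.9), reference_max = 1)
  expect_true(r$triggered)
  expect_equal(r$index, 3)

  none <- warning_trigger(c(0.1, 0.2), reference_max = 1)
  expect_false(none$triggered)
  expect_true(is.na(none$index))

  exact <- warning_trigger(c(0.5, 0.99, 1.0), reference_max = 1, fraction = 1)
  expect_equal(exact$index, 3)

  tt <- warning_trigger(c(0, 0.9), reference_max = 1, times = c(10, 10.5))
  expect_equal(tt$time, 10.5)

  expect_error(warning_trigger(c(1, 2), reference_max = -1), class = "stressci_invalid_parameter")
})

test_that("the fitted predictor tracks simulated stress scores and classifies well", {
  # well-separated latent stress levels mapped through the scale generator
  withr::with_seed(99, {
    latent <- rep(c(0.4, 1.35, 2.3), each = 20)
    dev <- data.frame(
      cortisol = 0.5 * latent + rnorm(60, 0, 0.04),
      glucose = 0.3 * latent + rnorm(60, 0, 0.04),
      hr = 0.25 * latent + rnorm(60, 0, 0.04)
    )
    scores <- generate_scale_scores(latent, "STAIS", noise_sd = 2)
  })
  w <- estimate_weights_mlr(dev, scores)
  pred <- vapply(
    seq_len(60),
    function(i) compute_ssci2(dev[i, ], w, with_intercept = TRUE),
    numeric(1)
  )
  expect_gte(cor(pred, scores), 0.9)
  acc <- mean(classify_as_state(pred) == classify_as_state(scores))
  expect_gte(acc, 0.85)
})
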