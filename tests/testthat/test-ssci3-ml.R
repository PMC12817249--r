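# Shared fixtures for the chronic-stress stage (built once per file).
models <- pretrain_baselines(seed = 101)
cohort <- generate_depression_cohort(seed = 1)
split1 <- split_cohort(cohort, test_subjects = 10, seed = 1)

test_that("feature assembly adjusts only when asked and keeps length 9", {
  rec <- split1$train[1:5, ]
  raw <- assemble_features(rec, temporal = FALSE)
  expect_equal(ncol(raw), 9)
  expect_equal(raw$cortisol_adj, rec$cortisol)

  adj <- assemble_features(rec, models, temporal = TRUE)
  expect_equal(ncol(adj), 9)
  expect_false(isTRUE(all.equal(adj$cortisol_adj, rec$cortisol)))

  # a record at the benchmark time is unchanged by adjustment
  rec8 <- dplyr::mutate(rec[1, ], time = models$cortisol$benchmark_time)
  expect_equal(
    assemble_features(rec8, models, temporal = TRUE)$cortisol_adj,
    rec8$cortisol
  )

  expect_error(
    assemble_features(dplyr::select(rec, -hr), temporal = FALSE),
    class = "stressci_missing_data"
  )
})

test_that("min-max normalisation is fitted on train only and never peeks at test", {
  tr <- assemble_features(split1$train, temporal = FALSE)
  te <- assemble_features(split1$test, temporal = FALSE)
  norm <- fit_normalization(tr)
  trn <- apply_normalization(tr, norm)
  expect_equal(unname(vapply(trn, min, numeric(1))), rep(0, 9))
  expect_equal(unname(vapply(trn, max, numeric(1))), rep(1, 9))
  # test values may fall outside [0, 1]: parameters come from train alone
  ten <- apply_normalization(te, norm)
  expect_equal(
    ten$age,
    (te$age - min(tr$age)) / diff(range(tr$age))
  )
})

test_that("composite labels hit the documented anchors and class collapse rule", {
  lab_min <- label_from_scales(90, 25, 25)
  expect_equal(lab_min$composite_score, 0)
  expect_equal(as.character(lab_min$class4), "ND")
  lab_max <- label_from_scales(450, 100, 100)
  expect_equal(lab_max$composite_score, 1)
  expect_equal(as.character(lab_max$class4), "SD")
  # at a threshold the higher class is assigned
  # composite 0.33 exactly: solve for equal normalized scores x = 0.33
  s <- c(90 + 0.33 * 360, 25 + 0.33 * 75, 25 + 0.33 * 75)
  expect_equal(as.character(label_from_scales(s[1], s[2], s[3])$class4), "MD")
  # binary collapse: patient iff MD or SD
  lab <- label_from_scales(cohort$scl90, cohort$sds, cohort$sas)
  expect_true(all((lab$class2 == "patient") == (lab$class4 %in% c("MD", "SD"))))
  expect_error(label_from_scales(10, 25, 25), class = "stressci_invalid_parameter")
})

test_that("the subject-level split gives 117:30 and never leaks a subject", {
  expect_equal(nrow(split1$train), 117)
  expect_equal(nrow(split1$test), 30)
  expect_length(intersect(split1$train$subject_id, split1$test$subject_id), 0)
  expect_identical(split_cohort(cohort, 10, seed = 1), split1)
  # different seed, still no leakage
  for (s in 2:4) {
    sp <- split_cohort(cohort, 10, seed = s)
    expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  }
  expect_error(split_cohort(cohort, 49, seed = 1), class = "stressci_invalid_parameter")
})

test_that("classifiers train deterministically and RF separates the default cohort", {
  clf <- train_classifiers(split1$train, models, temporal = TRUE, seed = 1)
  clf2 <- train_classifiers(split1$train, models, temporal = TRUE, seed = 1)
  p1 <- predict(clf, split1$test)
  p2 <- predict(clf2, split1$test)
  expect_identical(p1, p2)

  ev <- evaluate_classifiers(clf, split1$test)
  expect_gte(ev$summary$accuracy4[ev$summary$algorithm == "RF"], 0.9)
  # confusion matrix rows sum to the test class counts
  truth <- label_from_scales(split1$test$scl90, split1$test$sds, split1$test$sas)$class4
  cm <- ev$per_algorithm$RF$confusion
  expect_equal(as.numeric(rowSums(cm)), as.numeric(table(factor(truth, levels = rownames(cm)))))
  # AUCs are valid probabilities-of-ranking
  expect_true(all(ev$summary$roc_auc >= 0 & ev$summary$roc_auc <= 1))

  single <- dplyr::filter(split1$train, group == "ND")
  expect_error(train_classifiers(single, models, seed = 1), class = "stressci_invalid_parameter")
})

test_that("a zero-effect cohort yields chance-level accuracy (leakage guard)", {
  null_cohort <- generate_depression_cohort(cohort_design(effect_scale = 0), seed = 5)
  sp <- split_cohort(null_cohort, 10, seed = 5)
  clf <- train_classifiers(sp$train, models, algorithms = "RF", temporal = TRUE, seed = 5)
  ev <- evaluate_classifiers(clf, sp$test)
  # 4 classes, 30 test rows: chance ~ largest class share; require well below
  # the separable-cohort level and inside a generous binomial envelope
  expect_lt(ev$summary$accuracy4, 0.7)
})

test_that("perfect and random binary scores give the textbook ROC/PR endpoints", {
  truth <- rep(c(TRUE, FALSE), each = 50)
  perfect <- ifelse(truth, 0.9, 0.1)
  roc <- pROC::roc(truth, perfect, levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  expect_equal(as.numeric(pROC::auc(roc)), 1.0)
  expect_equal(stressci:::pr_auc(perfect, truth), 1.0)
  withr::with_seed(7, {
    rand <- runif(2000)
    truth2 <- rep(c(TRUE, FALSE), 1000)
    roc2 <- pROC::roc(truth2, rand, levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    expect_equal(as.numeric(pROC::auc(roc2)), 0.5, tolerance = 0.05)
  })
})

test_that("the regression index is exact on noiseless linear labels and strong on the cohort", {
  # labels an exact linear function of features: test correlation 1
  feats <- assemble_features(split1$train, temporal = FALSE)
  synth <- split1$train
  lin <- 0.05 + 0.0008 * feats$cortisol_adj + 0.001 * feats$glucose_adj +
    0.0005 * feats$hr # kept inside (0, 1) so the scale encoding stays affine
  # encode the linear target through the scales (invert the label map):
  # use equal scales so composite = normalized value
  synth$scl90 <- 90 + 360 * pmin(pmax(lin, 0), 1)
  synth$sds <- 25 + 75 * pmin(pmax(lin, 0), 1)
  synth$sas <- 25 + 75 * pmin(pmax(lin, 0), 1)
  reg <- suppressWarnings(regress_ssci3(synth, synth, temporal = FALSE)) # perfect-fit summary warning
  expect_gt(reg$test_correlation, 1 - 1e-8)

  reg2 <- regress_ssci3(split1$train, split1$test, models, temporal = TRUE)
  expect_gte(reg2$test_correlation, 0.9)
})

test_that("temporal coupling stabilises the day-long index track of a subject", {
  reg_adj <- regress_ssci3(split1$train, split1$test, models, temporal = TRUE)
  reg_raw <- regress_ssci3(split1$train, split1$test, models, temporal = FALSE)

  # rhythmic, stress-free subject with patient-level biomarker load
  p <- subject_profile("TRACK",
    basal_cortisol = 80 * 1.8, amplitude_cortisol = 120 * 1.8,
    basal_glucose = 60 * 1.45, basal_hr = 90
  )
  wins <- vapply(1:20, function(seed) {
    day <- simulate_panel(p, seq(8.5, 21.5, length.out = 8), seed = seed)
    day <- demo_cols(day)
    stab <- stability_comparison(day, reg_adj, reg_raw)
    stab$rsd_adjusted < stab$rsd_raw
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  # out-of-window records are skipped with a warning
  day <- demo_cols(simulate_panel(p, c(7, seq(8.5, 21.5, length.out = 7)), seed = 1))
  expect_warning(stability_comparison(day, reg_adj, reg_raw), "outside the day window")

  # constant biomarkers: both streams have zero spread
  flatp <- subject_profile("FLAT", amplitude_cortisol = 0)
  flat <- simulate_panel(flatp, seq(9, 21, length.out = 6),
    noise = list(cortisol = 0, glucose = 0, st = 0, hr = 0),
    meal_times = numeric(0)
  )
  flat <- demo_cols(flat)
  stab <- stability_comparison(flat, reg_adj, reg_raw)
  expect_equal(stab$rsd_raw, 0, tolerance = 1e-8)
})

test_that("class sequences under adjustment are no more variable than raw", {
  clf_adj <- train_classifiers(split1$train, models, algorithms = "RF", temporal = TRUE, seed = 1)
  clf_raw <- train_classifiers(split1$train, models, algorithms = "RF", temporal = FALSE, seed = 1)
  reg_adj <- regress_ssci3(split1$train, split1$test, models, temporal = TRUE)
  reg_raw <- regress_ssci3(split1$train, split1$test, models, temporal = FALSE)
  p <- subject_profile("TRACK2",
    basal_cortisol = 80 * 1.8, amplitude_cortisol = 120 * 1.8,
    basal_glucose = 60 * 1.45, basal_hr = 90
  )
  fewer <- vapply(1:10, function(seed) {
    day <- demo_cols(simulate_panel(p, seq(8.5, 21.5, length.out = 8), seed = seed))
    stab <- stability_comparison(day, reg_adj, reg_raw, clf_adj, clf_raw)
    dplyr::n_distinct(stab$class_sequence_adjusted) <=
      dplyr::n_distinct(stab$class_sequence_raw)
  }, logical(1))
  expect_gte(mean(fewer), 0.8)
})
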