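SSCI3_ALGORITHMS <- c("RF", "SVM", "NaiveBayes", "XGBoost", "ANN")

# Internal: fit one classification algorithm on normalised features + label.
fit_one_classifier <- function(algorithm, X, y, seed) {
  X <- as.data.frame(X)
  withr::with_seed(seed, switch(algorithm,
    RF = randomForest::randomForest(X, y, ntree = 500),
    SVM = e1071::svm(X, y, kernel = "radial", probability = TRUE),
    NaiveBayes = e1071::naiveBayes(X, y),
    XGBoost = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = as.integer(y) - 1)
      xgboost::xgb.train(
        params = list(
          objective = "multi:softprob", num_class = nlevels(y),
          max_depth = 4, eta = 0.3, nthread = 1, seed = seed
        ),
        data = dtrain, nrounds = 60, verbose = 0
      )
    },
    ANN = nnet::nnet(X, nnet::class.ind(y),
      size = 16, decay = 1e-3, maxit = 400,
      softmax = TRUE, trace = FALSE
    ),
    abort(sprintf("Unknown algorithm '%s'.", algorithm), class = "stressci_invalid_parameter")
  ))
}

# Internal: class-probability matrix (columns = levels) on new data.
predict_proba <- function(algorithm, fit, X, levels) {
  X <- as.data.frame(X)
  p <- switch(algorithm,
    RF = predict(fit, X, type = "prob"),
    SVM = attr(predict(fit, X, probability = TRUE), "probabilities"),
    NaiveBayes = predict(fit, X, type = "raw"),
    XGBoost = {
      m <- predict(fit, xgboost::xgb.DMatrix(as.matrix(X)))
      m <- matrix(as.numeric(m), nrow = nrow(X)) # n x num_class
      colnames(m) <- levels
      m
    },
    ANN = predict(fit, X)
  )
  p <- as.matrix(p)
  colnames(p) <- colnames(p) %||% levels
  p[, levels, drop = FALSE]
}

#' Train the chronic-stress classifier suite
#'
#' Fits the five classification algorithms of the chronic-stress stage —
#' random forest, support vector machine, Gaussian naive Bayes,
#' gradient-boosted trees, and a single-hidden-layer artificial neural
#' network (16 units) — on min-max normalised features (normalisation
#' fitted on the training partition only). Each fit is seeded, so results
#' are reproducible.
#'
#' @param train Training cohort tibble (rows of [generate_depression_cohort()]
#'   output or equivalent, with scale-score columns for labelling).
#' @param models Named list of baseline models for retro-adjustment (see
#'   [assemble_features()]); required when `temporal = TRUE`.
#' @param algorithms Subset of `RF`, `SVM`, `NaiveBayes`, `XGBoost`, `ANN`.
#' @param temporal Use temporally adjusted cortisol/glucose features?
#' @param label Which label to train on: `"class4"` or `"class2"`.
#' @param seed Integer seed.
#' @return A `stressci_ssci3` object: fitted classifier map plus the
#'   normalisation, label settings and feature metadata.
#' @export
train_classifiers <- function(train, models = NULL, algorithms = SSCI3_ALGORITHMS,
                              temporal = TRUE, label = c("class4", "class2"),
                              seed = 1) {
  label <- match.arg(label)
  algorithms <- match.arg(algorithms, SSCI3_ALGORITHMS, several.ok = TRUE)
  labels <- label_from_scales(train$scl90, train$sds, train$sas)
  y <- labels[[label]]
  y <- droplevels(y)
  if (nlevels(y) < 2) {
    abort("Training set contains a single class.", class = "stressci_invalid_parameter")
  }
  feats <- assemble_features(train, models, temporal = temporal)
  norm <- fit_normalization(feats)
  Xn <- apply_normalization(feats, norm)
  fits <- purrr::imap(
    setNames(algorithms, algorithms),
    function(alg, nm) fit_one_classifier(alg, Xn, y, seed = seed + match(alg, SSCI3_ALGORITHMS))
  )
  structure(
    list(
      fits = fits, algorithms = algorithms, norm = norm, models = models,
      temporal = temporal, label = label, levels = levels(y), seed = seed
    ),
    class = "stressci_ssci3"
  )
}

#' @export
print.stressci_ssci3 <- function(x, ...) {
  cat(sprintf(
    "<stressci_ssci3> %s on %s (%s features)\n",
    toString(x$algorithms), x$label,
    if (x$temporal) "temporally adjusted" else "raw"
  ))
  invisible(x)
}

#' Predict chronic-stress classes for new records
#'
#' @param object A `stressci_ssci3` from [train_classifiers()].
#' @param newdata Cohort records.
#' @param type `"class"` for labels, `"prob"` for probability matrices.
#' @param ... Unused.
#' @return Named list (per algorithm) of factors or probability matrices.
#' @export
predict.stressci_ssci3 <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  feats <- assemble_features(newdata, object$models, temporal = object$temporal)
  Xn <- apply_normalization(feats, object$norm)
  purrr::imap(object$fits, function(fit, alg) {
    p <- predict_proba(alg, fit, Xn, object$levels)
    if (type == "prob") {
      p
    } else {
      factor(object$levels[max.col(p, ties.method = "first")], levels = object$levels)
    }
  })
}

# Area under a piecewise-linear ROC curve by trapezoid; PR AUC by the
# step-interpolated average-precision convention.
pr_curve <- function(scores, truth_pos) {
  ord <- order(-scores)
  tp <- cumsum(truth_pos[ord])
  fp <- cumsum(!truth_pos[ord])
  precision <- tp / (tp + fp)
  recall <- tp / sum(truth_pos)
  tibble(recall = c(0, recall), precision = c(1, precision))
}

pr_auc <- function(scores, truth_pos) {
  ord <- order(-scores)
  pos <- truth_pos[ord]
  tp <- cumsum(pos)
  precision <- tp / seq_along(pos)
  sum(precision[pos]) / sum(pos) # average precision
}

#' Evaluate fitted chronic-stress classifiers on a test partition
#'
#' Computes, per algorithm: the multiclass confusion matrix and accuracy on
#' the four-group label, and — after collapsing MD/SD into the patient group
#' and ND/DR into the healthy group — the binary ROC curve and AUC
#' (via pROC) and the precision-recall curve and average precision.
#'
#' @param fitted A `stressci_ssci3` trained on `class4`.
#' @param test Test cohort tibble.
#' @return A `stressci_eval` object: list with `confusion` (per algorithm),
#'   `accuracy4`, `accuracy2`, `roc_auc`, `pr_auc`, `roc_curves`,
#'   `pr_curves`, and a `summary` tibble.
#' @export
evaluate_classifiers <- function(fitted, test) {
  stopifnot(inherits(fitted, "stressci_ssci3"))
  if (!nrow(test)) abort("Empty test set.", class = "stressci_invalid_parameter")
  truth <- label_from_scales(test$scl90, test$sds, test$sas)
  probs <- predict(fitted, test, type = "prob")
  patient_levels <- intersect(c("MD", "SD", "patient"), fitted$levels)

  res <- purrr::imap(probs, function(p, alg) {
    pred4 <- factor(fitted$levels[max.col(p, ties.method = "first")], levels = fitted$levels)
    truth4 <- factor(as.character(truth$class4), levels = fitted$levels)
    confusion <- table(truth = truth4, predicted = pred4)
    score_patient <- rowSums(p[, patient_levels, drop = FALSE])
    pred2 <- factor(ifelse(score_patient >= 0.5, "patient", "healthy"),
      levels = levels(truth$class2)
    )
    is_pos <- truth$class2 == "patient"
    roc <- pROC::roc(
      response = is_pos, predictor = score_patient,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    )
    list(
      confusion = confusion,
      accuracy4 = mean(pred4 == truth4),
      accuracy2 = mean(pred2 == truth$class2),
      roc_auc = as.numeric(pROC::auc(roc)),
      pr_auc = pr_auc(score_patient, is_pos),
      roc_curve = tibble(
        fpr = 1 - roc$specificities,
        tpr = roc$sensitivities
      ),
      pr_curve = pr_curve(score_patient, is_pos)
    )
  })

  structure(
    list(
      per_algorithm = res,
      summary = purrr::imap_dfr(res, function(r, alg) {
        tibble(
          algorithm = alg, accuracy4 = r$accuracy4, accuracy2 = r$accuracy2,
          roc_auc = r$roc_auc, pr_auc = r$pr_auc
        )
      })
    ),
    class = "stressci_eval"
  )
}

#' @export
print.stressci_eval <- function(x, ...) {
  cat("<stressci_eval>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Quantitative chronic-stress index by linear regression
#'
#' Fits ordinary least squares of the composite severity score (the
#' weighted scale combination of [label_from_scales()]) on the normalised
#' feature vector, and reports the Pearson correlation between predicted
#' and true scores on the held-out test partition. The predicted score is
#' the quantitative chronic-stress index.
#'
#' @inheritParams train_classifiers
#' @param test Test cohort tibble.
#' @return List with the `lm` `fit`, `norm`, `predicted` (test), `truth`
#'   (test composite scores), `test_correlation` and `train_r2`.
#' @export
regress_ssci3 <- function(train, test, models = NULL, temporal = TRUE) {
  y_train <- label_from_scales(train$scl90, train$sds, train$sas)$composite_score
  feats <- assemble_features(train, models, temporal = temporal)
  norm <- fit_normalization(feats)
  Xn <- as.data.frame(apply_normalization(feats, norm))
  qrX <- qr(cbind(1, as.matrix(Xn)))
  if (qrX$rank < ncol(Xn) + 1) {
    abort("Feature matrix is rank deficient.", class = "stressci_collinearity_error")
  }
  df <- cbind(.score = y_train, Xn)
  fit <- lm(.score ~ ., data = df)

  y_test <- label_from_scales(test$scl90, test$sds, test$sas)$composite_score
  Xt <- as.data.frame(apply_normalization(assemble_features(test, models, temporal = temporal), norm))
  pred <- unname(predict(fit, Xt))
  list(
    fit = fit, norm = norm, models = models, temporal = temporal,
    predicted = pred, truth = y_test,
    test_correlation = if (sd(pred) > 0 && sd(y_test) > 0) stats::cor(pred, y_test) else 0,
    train_r2 = summary(fit)$r.squared
  )
}

# Internal: predict the regression index for new records.
predict_ssci3_reg <- function(reg, records) {
  Xt <- as.data.frame(apply_normalization(
    assemble_features(records, reg$models, temporal = reg$temporal), reg$norm
  ))
  unname(predict(reg$fit, Xt))
}

#' Stability of the chronic-stress index with vs without temporal coupling
#'
#' Tracks one subject across the day: at each time point the quantitative
#' index and the four-group classification are computed twice, once from
#' temporally adjusted cortisol/glucose and once from the raw values, using
#' regression/classification models trained with the corresponding feature
#' mode. Returns the relative standard deviation of both index streams and
#' both class sequences; on a rhythmic, stress-free subject the adjusted
#' stream shows the smaller variation.
#'
#' @param day_series Records of one subject at >= 5 time points within the
#'   day window (same columns as a cohort table).
#' @param reg_adjusted,reg_raw Regression fits from [regress_ssci3()] with
#'   `temporal = TRUE` and `FALSE` respectively.
#' @param clf_adjusted,clf_raw Optional `stressci_ssci3` classifier fits in
#'   the two modes; class sequences are `NULL` when omitted.
#' @return List with `rsd_adjusted`, `rsd_raw`, `ssci3_adjusted`,
#'   `ssci3_raw`, `class_sequence_adjusted`, `class_sequence_raw`.
#' @export
stability_comparison <- function(day_series, reg_adjusted, reg_raw,
                                 clf_adjusted = NULL, clf_raw = NULL) {
  window <- reg_adjusted$models$cortisol$window %||% DAY_WINDOW
  inside <- day_series$time >= window[1] & day_series$time <= window[2]
  if (any(!inside)) {
    warn(sprintf("Skipping %d record(s) outside the day window.", sum(!inside)))
    day_series <- day_series[inside, ]
  }
  if (nrow(day_series) < 5) {
    abort("Need at least 5 in-window time points.", class = "stressci_insufficient_data")
  }
  adj <- predict_ssci3_reg(reg_adjusted, day_series)
  raw <- predict_ssci3_reg(reg_raw, day_series)
  cls_adj <- if (!is.null(clf_adjusted)) predict(clf_adjusted, day_series)[[1]] else NULL
  cls_raw <- if (!is.null(clf_raw)) predict(clf_raw, day_series)[[1]] else NULL
  list(
    rsd_adjusted = if (sd(adj) == 0) 0 else rsd(adj),
    rsd_raw = if (sd(raw) == 0) 0 else rsd(raw),
    ssci3_adjusted = adj, ssci3_raw = raw,
    class_sequence_adjusted = cls_adj, class_sequence_raw = cls_raw
  )
}
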