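# Shared fixtures, built in code at test time.

# Noisy cosinor observations on the day window.
make_cosinor_series <- function(n = 14, mesor = 150, amplitude = 100,
                                acrophase = 14, noise_sd = 5, seed = 1) {
  withr::with_seed(seed, {
    t <- seq(8, 22, length.out = n)
    v <- mesor + amplitude * cos(2 * pi * (t - acrophase) / 24) +
      rnorm(n, sd = noise_sd)
    tibble::tibble(time = t, value = v)
  })
}

# Acute-stress-test-like data: latent stress per subject, biomarker relative
# deviations proportional to it, STAI-S generated from the same latent.
make_cpt_like <- function(n = 100, true_w = c(cortisol = 10, glucose = 5, hr = 2),
                          intercept = 30, noise_sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    X <- data.frame(
      cortisol = runif(n), glucose = runif(n), hr = runif(n)
    )
    y <- intercept + as.matrix(X) %*% true_w + rnorm(n, sd = noise_sd)
    list(deviations = X, scores = as.numeric(y), true_w = true_w, intercept = intercept)
  })
}

# Brute-force local-maximum scan: every strict local maximum above the
# height threshold, then greedy refractory pruning by decreasing height.
# Independent of the detect_peaks implementation.
brute_force_peaks <- function(x, sample_rate, refractory_s = 0.3, min_prominence = 0.4) {
  n <- length(x)
  thr <- min(x) + min_prominence * diff(range(x))
  idx <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1] && x[i] >= thr) idx <- c(idx, i)
  }
  keep <- integer(0)
  for (i in idx[order(-x[idx], idx)]) {
    if (!length(keep) || all(abs(keep - i) >= refractory_s * sample_rate)) {
      keep <- c(keep, i)
    }
  }
  sort((keep - 1) / sample_rate)
}

# Ordinary least squares via the normal equations, with classical 95% CIs.
# Independent oracle for estimate_weights_mlr (which goes through lm()).
normal_equations_ols <- function(X, y) {
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  XtX_inv <- solve(t(Xm) %*% Xm)
  beta <- XtX_inv %*% t(Xm) %*% y
  resid <- y - Xm %*% beta
  df <- nrow(Xm) - ncol(Xm)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(XtX_inv) * sigma2)
  tcrit <- qt(0.975, df)
  list(
    coef = as.numeric(beta), se = as.numeric(se),
    ci = cbind(as.numeric(beta) - tcrit * se, as.numeric(beta) + tcrit * se)
  )
}

demo_cols <- function(panel, gender = "female", age = 40, height = 165,
                      weight = 60, mean_bp = 92) {
  dplyr::mutate(panel,
    gender = gender, age = age, height = height,
    weight = weight, mean_bp = mean_bp
  )
}
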