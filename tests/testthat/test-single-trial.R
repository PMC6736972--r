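test_that("a single displaced sample is flagged at iteration 1", {
  set.seed(1)
  x <- rnorm(100)
  x[50] <- x[50] + 20 * mad(x)
  sp <- detect_spikes(cbind(x), mad_threshold = 10)
  expect_equal(sp$index, 50L)
  expect_equal(sp$iteration, 1L)
  expect_equal(sp$criterion, "global-mad")
})

test_that("pure Gaussian noise yields essentially no flags at 10 m.a.d.", {
  set.seed(2)
  flags <- vapply(1:50, function(i)
    nrow(detect_spikes(cbind(rnorm(200)), mad_threshold = 10)), 1L)
  expect_lte(sum(flags), 1)  # Monte-Carlo false-positive rate ~ 0
})

test_that("a masked second spike is only found by the step-down recursion", {
  x <- masked_spike_series()
  sp1 <- detect_spikes(cbind(x), mad_threshold = 10, max_iter = 1)
  expect_false(54 %in% sp1$index)
  expect_true(all(42:53 %in% sp1$index))
  sp <- detect_spikes(cbind(x), mad_threshold = 10, max_iter = 3)
  expect_true(54 %in% sp$index)
  expect_equal(sp$iteration[sp$index == 54], 2L)
  expect_true(all(sp$iteration[sp$index %in% 42:53] == 1L))
})

test_that("spike detection is idempotent after removal of flagged points", {
  x <- masked_spike_series()
  sp <- detect_spikes(cbind(x), mad_threshold = 10)
  x2 <- x[-sp$index]
  expect_equal(nrow(detect_spikes(cbind(x2), mad_threshold = 10)), 0L)
})

test_that("multichannel outliers are caught by the Mahalanobis criterion", {
  set.seed(3)
  X <- matrix(rnorm(200 * 6), 200, 6)
  # per-channel displacement too small for the global-mean criterion but
  # large jointly
  X[50, ] <- c(4, -4, 4, -4, 4, -4) * 3
  sp <- detect_spikes(X, mad_threshold = 5)
  expect_true(50 %in% sp$index)
  expect_true("mahalanobis-mad" %in% sp$criterion[sp$index == 50])
})

test_that("too few samples for Mahalanobis falls back with a warning", {
  set.seed(4)
  X <- matrix(rnorm(12 * 20), 12, 20)
  expect_warning(detect_spikes(X, mad_threshold = 10), "falling back")
  expect_error(detect_spikes(cbind(rnorm(5))), "at least 10")
})

test_that("VIF is exactly 1 for mutually orthogonal centered columns", {
  X <- cbind(intercept = 1,
             a = rep(c(-1, 1), 10),
             b = rep(c(-1, -1, 1, 1), 5),
             c = rep(c(-1, 1, 1, -1), 5))
  v <- compute_vif(X)
  expect_equal(unname(v[c("a", "b", "c")]), c(1, 1, 1), tolerance = 1e-10)
})

test_that("duplicated trial regressors blow up VIF and abort the fit", {
  X <- single_trial_design(50, c(5, 10, 15))
  Xd <- cbind(X, dup = X[, "trial2"])
  v <- compute_vif(Xd)
  expect_true(is.infinite(v["trial2"]) && is.infinite(v["dup"]))
  expect_error(fit_single_trial_glm(rnorm(50), Xd),
               "trial2.*dup|dup.*trial2")
})

test_that("single-trial GLM recovers known betas exactly without noise", {
  set.seed(5)
  X <- single_trial_design(120, c(10, 40, 70, 100),
                           nuisance = matrix(rnorm(120 * 3), 120, 3))
  beta_true <- c(2, -1, 0.5, 3)
  y <- X %*% c(1, beta_true, 0.2, -0.3, 0.1)  # intercept + trials + nuisance
  fit <- fit_single_trial_glm(y, X)
  expect_equal(drop(fit$betas), beta_true, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(fit$vif >= 1))
})

test_that("the VIF filter uses a strict cutoff and logs exclusions", {
  flt <- apply_vif_filter(1:3, c(1.0, 2.5, 2.6), threshold = 2.5,
                          subject = 7)
  expect_equal(flt$betas, 1:2)
  expect_equal(flt$log$trial, 3L)
  expect_equal(flt$log$subject, 7)
  # all below threshold: identity
  flt2 <- apply_vif_filter(1:3, c(1, 1, 2.5))
  expect_equal(flt2$betas, 1:3)
  expect_warning(apply_vif_filter(1:2, c(3, 4)), "all trials excluded")
})

test_that("SCR deconvolution recovers amplitudes exactly, even overlapping", {
  rate <- 10
  ker <- scr_kernel(rate = rate)
  amps <- c(2, 5, 1.5, 0.7)
  onsets <- c(2, 4, 5, 25)  # first three overlap heavily
  n <- 400
  s <- rep(0, n)
  for (j in seq_along(amps)) {
    i <- round(onsets[j] * rate) + 1
    span <- i:min(n, i + length(ker) - 1)
    s[span] <- s[span] + amps[j] * ker[seq_along(span)]
  }
  fit <- fit_scr_glm(s, onsets, rate)
  expect_equal(drop(fit$betas), amps, tolerance = 1e-10, ignore_attr = TRUE)

  zero <- fit_scr_glm(rep(0, n), onsets, rate)
  expect_equal(drop(zero$betas), rep(0, 4), ignore_attr = TRUE)

  expect_error(fit_scr_glm(s, c(2, 100), rate), "beyond")
})

test_that("fMRI and SCR estimators share one GLM core (common oracle)", {
  # same amplitudes, two basis functions: stick versus convolved kernel;
  # both must match the lm() oracle on their own design
  set.seed(6)
  amps <- c(1.5, -2, 0.5)
  onsets_idx <- c(10, 30, 60)
  X <- single_trial_design(100, onsets_idx)
  y <- drop(X %*% c(0, amps)) + rnorm(100, 0, 0.1)
  ours <- drop(fit_single_trial_glm(y, X)$betas)
  oracle <- unname(coef(lm(y ~ X[, -1]))[-1])
  expect_equal(ours, oracle, tolerance = 1e-10, ignore_attr = TRUE)

  rate <- 5
  ker <- scr_kernel(rate = rate)
  s <- rep(0, 200)
  for (j in 1:3) {
    i <- onsets_idx[j]
    span <- i:min(200, i + length(ker) - 1)
    s[span] <- s[span] + amps[j] * ker[seq_along(span)]
  }
  s <- s + rnorm(200, 0, 0.05)
  fit <- fit_scr_glm(s, (onsets_idx - 1) / rate, rate)
  Xs <- matrix(0, 200, 3)
  for (j in 1:3) {
    span <- onsets_idx[j]:min(200, onsets_idx[j] + length(ker) - 1)
    Xs[span, j] <- ker[seq_along(span)]
  }
  oracle2 <- unname(coef(lm(s ~ Xs))[-1])
  expect_equal(drop(fit$betas), oracle2, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("the low-pass filter attenuates fast oscillations, not slow ones", {
  rate <- 100
  t <- seq(0, 10, by = 1 / rate)
  slow <- sin(2 * pi * 0.2 * t)
  fast <- sin(2 * pi * 10 * t)
  filt <- lowpass_filter(slow + fast, rate, cutoff = 1)
  mid <- seq(200, length(t) - 200)
  expect_lt(sd(filt[mid] - slow[mid]), 0.05)
})
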