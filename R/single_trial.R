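#' Recursive outlier time-point ("spike") detection
#'
#' Flags time points whose global signal deviates from the run median by
#' more than `mad_threshold` median absolute deviations, or (for
#' multi-channel input) whose Mahalanobis distance across channel summaries
#' exceeds the same robust threshold. Detection is recursive in a step-down
#' fashion: after each iteration the flagged points are excluded and the
#' robust statistics recomputed, so that a large spike no longer masks a
#' smaller one, up to `max_iter` iterations.
#'
#' The Mahalanobis criterion operates on the supplied channel matrix
#' (e.g., slice-wise means and slice-wise spatial SDs per time point), with
#' the covariance estimated from the currently unflagged points and shrunk
#' toward its diagonal when ill-conditioned. When there are fewer unflagged
#' samples than channels the function falls back to the global criterion
#' with a warning.
#'
#' @param x numeric matrix (time x channels) or vector.
#' @param mad_threshold robust threshold in m.a.d. units (default 10).
#' @param max_iter maximum step-down iterations (default 3).
#' @param mad_constant scale constant passed to [stats::mad()];
#'   1.4826 makes the m.a.d. consistent with the SD under normality, 1 gives
#'   the raw m.a.d.
#' @return object of class `spike_report`: a data frame with columns
#'   `index`, `criterion` ("global-mad" or "mahalanobis-mad"), `iteration`;
#'   attribute `n_time` records the run length.
#' @export
detect_spikes <- function(x, mad_threshold = 10, max_iter = 3,
                          mad_constant = 1.4826) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10) stop("need at least 10 samples")
  g <- rowMeans(x)
  use_maha <- ncol(x) > 1
  flagged <- integer(0)
  crit <- character(0)
  iter <- integer(0)
  for (it in seq_len(max_iter)) {
    keep <- setdiff(seq_len(n), flagged)
    med <- stats::median(g[keep])
    s <- stats::mad(g[keep], constant = mad_constant)
    new_glob <- keep[s > 0 & abs(g[keep] - med) > mad_threshold * s]
    new_maha <- integer(0)
    if (use_maha) {
      if (length(keep) <= ncol(x)) {
        warning("fewer unflagged samples than channels; ",
                "falling back to the global criterion")
      } else {
        mu <- colMeans(x[keep, , drop = FALSE])
        S <- stats::cov(x[keep, , drop = FALSE])
        # shrink toward the diagonal if near-singular
        lam <- 0
        while (kappa(S + lam * diag(diag(S) + 1e-12, ncol(S))) > 1e10 &&
               lam < 1) {
          lam <- max(lam * 10, 1e-4)
        }
        if (lam > 0) S <- (1 - lam) * S + lam * diag(diag(S) + 1e-12, ncol(S))
        d2 <- stats::mahalanobis(x, mu, S)
        dk <- sqrt(d2[keep])
        medd <- stats::median(dk)
        sd_d <- stats::mad(dk, constant = mad_constant)
        if (sd_d > 0)
          new_maha <- keep[sqrt(d2[keep]) - medd > mad_threshold * sd_d]
      }
    }
    new_idx <- sort(union(new_glob, new_maha))
    new_idx <- setdiff(new_idx, flagged)
    if (length(new_idx) == 0) break
    crit <- c(crit, ifelse(new_idx %in% new_glob,
                           "global-mad", "mahalanobis-mad"))
    iter <- c(iter, rep(it, length(new_idx)))
    flagged <- c(flagged, new_idx)
  }
  rep_df <- data.frame(index = flagged, criterion = crit, iteration = iter)
  rep_df <- rep_df[order(rep_df$index), , drop = FALSE]
  rownames(rep_df) <- NULL
  structure(rep_df, n_time = n, class = c("spike_report", "data.frame"))
}

#' Build a single-trial design matrix
#'
#' One stick (unit impulse) regressor per trial event, optional nuisance
#' columns (e.g., the 24 motion-derived regressors), and unit spike
#' indicator columns (1 at the flagged time point, 0 elsewhere). An
#' intercept is always included.
#'
#' @param n_time run length in samples.
#' @param trial_onsets integer sample indices of trial events.
#' @param nuisance optional numeric matrix (n_time x k).
#' @param spikes integer indices of outlier time points (e.g., from
#'   [detect_spikes()]).
#' @return design matrix with attribute `trial_cols` giving the trial
#'   column indices.
#' @export
single_trial_design <- function(n_time, trial_onsets, nuisance = NULL,
                                spikes = integer(0)) {
  if (any(trial_onsets < 1 | trial_onsets > n_time))
    stop("trial onsets outside the run")
  if (inherits(spikes, "spike_report")) spikes <- spikes$index
  Xtr <- matrix(0, n_time, length(trial_onsets))
  Xtr[cbind(trial_onsets, seq_along(trial_onsets))] <- 1
  colnames(Xtr) <- paste0("trial", seq_along(trial_onsets))
  X <- cbind(intercept = 1, Xtr)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  if (length(spikes) > 0) {
    Xs <- matrix(0, n_time, length(spikes))
    Xs[cbind(spikes, seq_along(spikes))] <- 1
    colnames(Xs) <- paste0("spike", spikes)
    X <- cbind(X, Xs)
  }
  attr(X, "trial_cols") <- 1L + seq_along(trial_onsets)
  X
}

#' Variance inflation factors for design columns
#'
#' VIF_j = 1 / (1 - R2_j), where R2_j is the centered R-squared of column j
#' regressed on all other columns. Exactly collinear columns get `Inf`;
#' constant columns get `NA`. The intercept (detected as a constant column)
#' is skipped.
#'
#' @param X design matrix.
#' @return named numeric vector of VIFs (NA for constant columns).
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  out <- rep(NA_real_, p)
  names(out) <- colnames(X)
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  for (j in seq_len(p)) {
    if (const[j]) next
    fit <- stats::lm.fit(X[, -j, drop = FALSE], X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Fit a single-trial GLM
#'
#' Ordinary least squares of one or more time series on a single-trial
#' design, returning per-trial betas and per-trial-column VIFs. This is the
#' shared estimation core for fMRI stick designs and convolved SCR designs.
#'
#' @param y numeric vector or matrix (time x series).
#' @param X design from [single_trial_design()] (or any matrix with a
#'   `trial_cols` attribute; if absent, all non-intercept columns are
#'   treated as trial columns).
#' @return list with `betas` (trial betas, trials x series), `coefficients`
#'   (all columns), `vif` (per trial column), `residuals`.
#' @export
fit_single_trial_glm <- function(y, X) {
  y <- as.matrix(y)
  X <- as.matrix(X)
  if (nrow(y) != nrow(X)) stop("y and design have different lengths")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    vifs <- compute_vif(X)
    bad <- names(vifs)[!is.finite(vifs)]
    stop("design matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  cf <- qr.coef(qrX, y)
  res <- y - X %*% cf
  tc <- attr(X, "trial_cols")
  if (is.null(tc)) tc <- which(colnames(X) != "intercept")
  vif <- compute_vif(X)[tc]
  list(betas = cf[tc, , drop = FALSE], coefficients = cf,
       vif = vif, residuals = res)
}

#' Exclude trials with high variance inflation
#'
#' Trials whose design VIF exceeds the threshold (strict inequality, so a
#' VIF of exactly 2.5 is kept) are removed from all downstream analyses.
#'
#' @param betas per-trial beta matrix or vector.
#' @param vifs per-trial VIFs, aligned with `betas`.
#' @param threshold exclusion threshold (default 2.5).
#' @param subject optional subject label for the exclusion log.
#' @return list with `betas` (retained), `kept` (logical), and `log`
#'   (data frame: subject, trial, vif for each excluded trial). Warns when
#'   every trial is excluded.
#' @export
apply_vif_filter <- function(betas, vifs, threshold = 2.5, subject = NA) {
  one_dim <- is.null(dim(betas))
  b <- if (one_dim) matrix(betas, ncol = 1) else as.matrix(betas)
  if (nrow(b) != length(vifs)) stop("betas and vifs are not aligned")
  keep <- !(vifs > threshold)
  keep[is.na(keep)] <- FALSE
  log <- data.frame(subject = rep(subject, sum(!keep)),
                    trial = which(!keep),
                    vif = vifs[!keep])
  rownames(log) <- NULL
  if (!any(keep)) warning("all trials excluded by the VIF filter")
  out <- b[keep, , drop = FALSE]
  list(betas = if (one_dim) drop(out) else out, kept = keep, log = log)
}

#' Canonical skin-conductance response kernel
#'
#' Two-parameter gamma-family kernel (shape controls onset latency/rise,
#' scale controls decay), normalized to unit peak, sampled at the recording
#' rate. The contract is "known kernel in, amplitudes out": any kernel of
#' the same length can be substituted.
#'
#' @param duration kernel support in seconds.
#' @param rate sampling rate in Hz.
#' @param shape,scale gamma parameters (defaults: shape 3, scale 1.2 s).
#' @return numeric vector of kernel samples.
#' @export
scr_kernel <- function(duration = 20, rate = 25, shape = 3, scale = 1.2) {
  t <- seq(0, duration, by = 1 / rate)
  k <- stats::dgamma(t, shape = shape, scale = scale)
  k / max(k)
}

#' Zero-phase low-pass filter
#'
#' Order-4 Butterworth low-pass applied forward and backward
#' ([signal::filtfilt()]) so the filter is zero-phase; default 1 Hz cutoff
#' as used for skin-conductance preprocessing.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz.
#' @param order filter order.
#' @return filtered vector.
#' @export
lowpass_filter <- function(x, rate, cutoff = 1, order = 4) {
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Single-trial SCR amplitude estimation
#'
#' Builds one regressor per pain onset by convolving a unit stick with the
#' canonical SCR kernel and fits the whole run by OLS (through the same GLM
#' core as the fMRI single-trial estimator), yielding one amplitude beta
#' per trial. Overlapping responses are deconvolved exactly when the
#' design is full rank.
#'
#' @param scr numeric vector, the (filtered, normalized) skin-conductance
#'   time series.
#' @param onsets trial onsets in seconds.
#' @param rate sampling rate in Hz.
#' @param kernel response kernel sampled at `rate`; default [scr_kernel()].
#' @return list as returned by [fit_single_trial_glm()] with `betas` the
#'   per-trial amplitudes.
#' @export
fit_scr_glm <- function(scr, onsets, rate, kernel = scr_kernel(rate = rate)) {
  n <- length(scr)
  idx <- round(onsets * rate) + 1L
  if (any(idx < 1 | idx > n)) stop("onsets beyond the end of the run")
  X <- matrix(0, n, length(idx))
  for (j in seq_along(idx)) {
    span <- idx[j]:min(n, idx[j] + length(kernel) - 1L)
    X[span, j] <- kernel[seq_along(span)]
  }
  colnames(X) <- paste0("trial", seq_along(idx))
  X <- cbind(intercept = 1, X)
  attr(X, "trial_cols") <- 1L + seq_along(idx)
  fit_single_trial_glm(scr, X)
}
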