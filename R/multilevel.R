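#' Group-level summary of subject-level effect estimates
#'
#' One-sample t summary across subjects of per-subject OLS betas: group
#' beta (mean), t-based 95 percent CI, t statistic with n - 1 degrees of
#' freedom, two-sided p, and Cohen's d = mean / SD of the subject betas
#' (so d * sqrt(n) = t).
#'
#' @param betas numeric vector of subject-level estimates.
#' @param label predictor label.
#' @param conf confidence level.
#' @return one-row data frame: predictor, beta, ci_lo, ci_hi, t, df, p, d.
#' @export
group_effect <- function(betas, label = "effect", conf = 0.95) {
  betas <- betas[is.finite(betas)]
  n <- length(betas)
  if (n < 2) stop("need at least 2 subjects for a group test")
  m <- mean(betas)
  s <- stats::sd(betas)
  if (s == 0) {
    warning("zero between-subject variance")
    p <- if (m == 0) 1 else 0
    return(data.frame(predictor = label, beta = m, ci_lo = m, ci_hi = m,
                      t = if (m == 0) 0 else Inf * sign(m),
                      df = n - 1, p = p, d = if (m == 0) 0 else Inf * sign(m)))
  }
  se <- s / sqrt(n)
  tt <- m / se
  qt <- stats::qt(1 - (1 - conf) / 2, n - 1)
  data.frame(predictor = label, beta = m,
             ci_lo = m - qt * se, ci_hi = m + qt * se,
             t = tt, df = n - 1,
             p = 2 * stats::pt(-abs(tt), n - 1),
             d = m / s)
}

#' @noRd
subject_ols <- function(trials, outcome, predictors) {
  subjects <- sort(unique(trials$subject))
  B <- matrix(NA_real_, length(subjects), length(predictors),
              dimnames = list(subjects, predictors))
  dropped <- character(0)
  for (k in seq_along(subjects)) {
    d <- trials[trials$subject == subjects[k], , drop = FALSE]
    X <- cbind(1, as.matrix(d[, predictors, drop = FALSE]))
    y <- d[[outcome]]
    qrX <- qr(X)
    if (qrX$rank < ncol(X) || nrow(X) < ncol(X) + 1) {
      dropped <- c(dropped, as.character(subjects[k]))
      next
    }
    cf <- qr.coef(qrX, y)
    B[k, ] <- cf[-1]
  }
  if (length(dropped) > 0)
    warning("subjects excluded (unestimable betas): ",
            paste(dropped, collapse = ", "))
  B[stats::complete.cases(B), , drop = FALSE]
}

#' Two-level GLM on single-trial ratings
#'
#' The summary-statistics multilevel model used throughout the behavioral
#' analyses: an OLS fit per subject, then a one-sample t test across
#' subjects for each predictor. Predictors use the field's codings (cues
#' -1/+1, temperature -1/0/+1, time as trial counter). Significance is
#' two-sided.
#'
#' @param trials trial table.
#' @param outcome outcome column name (e.g., "pain", "expect", "scr").
#' @param predictors character vector of predictor column names.
#' @param subset optional logical expression evaluated in `trials` (e.g.,
#'   `temp == 49` to restrict cue effects to medium-temperature trials).
#' @return data frame with one [group_effect()] row per predictor;
#'   attribute `subject_betas` holds the subjects x predictors matrix.
#' @export
fit_multilevel_glm <- function(trials, outcome, predictors, subset = NULL) {
  sub <- substitute(subset)
  if (!is.null(sub)) {
    keep <- eval(sub, trials, parent.frame())
    if (is.logical(keep)) trials <- trials[keep, , drop = FALSE]
  }
  if (length(unique(trials$subject)) < 2)
    stop("need at least 2 subjects; a single-subject fit is not a group test")
  B <- subject_ols(trials, outcome, predictors)
  res <- do.call(rbind, lapply(predictors, function(p)
    group_effect(B[, p], label = p)))
  attr(res, "subject_betas") <- B
  res
}

#' Paired contrast of two sets of subject-level betas
#'
#' Equivalent to a paired t test on the per-subject beta differences;
#' used, e.g., to compare social-information and CS effect magnitudes.
#'
#' @param betas1,betas2 aligned subject-level estimates.
#' @param label contrast label.
#' @return one-row [group_effect()] data frame.
#' @export
paired_contrast <- function(betas1, betas2, label = "contrast") {
  stopifnot(length(betas1) == length(betas2))
  group_effect(betas1 - betas2, label = label)
}

#' Cue-by-time interaction model
#'
#' Per-subject OLS of an outcome on a cue, time, and their interaction,
#' summarized at the group level. "Time" defaults to the within-condition
#' trial counter (1..n within each level of the cue, matching per-condition
#' time-course axes); the absolute trial index is available as an
#' alternative. Time is mean-centered within subject so the cue main effect
#' keeps its average interpretation. A positive interaction means the cue
#' effect grows over time.
#'
#' @param trials trial table.
#' @param outcome outcome column name.
#' @param cue cue column name ("social" or "cs").
#' @param time "condition" (within-condition counter) or "absolute".
#' @param subset optional logical expression evaluated in `trials`.
#' @return data frame with group rows for the cue, time, and cue x time
#'   terms; attribute `subject_betas` as in [fit_multilevel_glm()].
#' @export
fit_time_interaction <- function(trials, outcome, cue = "social",
                                 time = c("condition", "absolute"),
                                 subset = NULL) {
  time <- match.arg(time)
  sub <- substitute(subset)
  if (!is.null(sub)) {
    keep <- eval(sub, trials, parent.frame())
    if (is.logical(keep)) trials <- trials[keep, , drop = FALSE]
  }
  tcol <- if (time == "condition") paste0("t_", cue) else "trial"
  trials$..time <- stats::ave(trials[[tcol]], trials$subject,
                              FUN = function(v) v - mean(v))
  trials$..inter <- trials[[cue]] * trials$..time
  preds <- c(cue, "..time", "..inter")
  res <- fit_multilevel_glm(trials, outcome, preds)
  res$predictor <- c(cue, "time", paste0(cue, ":time"))
  res
}

#' Per-condition trial-binned time courses with bootstrap bands
#'
#' Running means of an outcome over the within-condition trial index for
#' each social x CS condition, with bootstrapped 95 percent confidence
#' bands over subjects.
#'
#' @param trials trial table.
#' @param outcome outcome column.
#' @param window running-mean window in trials (window 1 = raw per-trial
#'   means).
#' @param n_boot bootstrap resamples for the bands.
#' @param conf band coverage.
#' @param seed RNG seed.
#' @return data frame: social, cs, t (within-condition index), mean, lo, hi.
#' @export
condition_timecourse <- function(trials, outcome, window = 4,
                                 n_boot = 1000, conf = 0.95, seed = 1L) {
  stopifnot(window >= 1)
  trials$..cond <- interaction(trials$social, trials$cs, drop = TRUE)
  trials$..tc <- stats::ave(trials$trial,
                            trials$subject, trials$..cond, FUN = seq_along)
  runmean <- function(v) {
    as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  }
  subjects <- sort(unique(trials$subject))
  conds <- levels(trials$..cond)
  out <- list()
  set.seed(as.integer(seed))
  for (cn in conds) {
    d <- trials[trials$..cond == cn, , drop = FALSE]
    tmax <- max(d$..tc)
    M <- matrix(NA_real_, length(subjects), tmax)
    for (k in seq_along(subjects)) {
      ds <- d[d$subject == subjects[k], , drop = FALSE]
      v <- rep(NA_real_, tmax)
      v[ds$..tc] <- ds[[outcome]]
      M[k, ] <- if (window > 1) runmean(v) else v
    }
    mu <- colMeans(M, na.rm = TRUE)
    if (length(subjects) > 1 && n_boot > 0) {
      bm <- matrix(NA_real_, n_boot, tmax)
      for (b in seq_len(n_boot)) {
        bm[b, ] <- colMeans(M[sample.int(nrow(M), replace = TRUE), ,
                              drop = FALSE], na.rm = TRUE)
      }
      qs <- apply(bm, 2, stats::quantile,
                  probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                  na.rm = TRUE)
    } else {
      qs <- rbind(mu, mu)
    }
    sc <- as.numeric(strsplit(cn, ".", fixed = TRUE)[[1]])
    out[[cn]] <- data.frame(social = sc[1], cs = sc[2],
                            t = seq_len(tmax), mean = mu,
                            lo = qs[1, ], hi = qs[2, ])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
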