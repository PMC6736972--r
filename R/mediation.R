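#' Subject-level three-path mediation
#'
#' Fits the three OLS regressions of single-mediator mediation on one
#' subject's trials:
#'
#'   M ~ X + covariates            (path a)
#'   Y ~ M + X + covariates        (paths b and c')
#'   Y ~ X + covariates            (path c)
#'
#' With the same covariates in all three regressions the OLS identity
#' c = c' + a*b holds to machine precision.
#'
#' @param x treatment (coded -1/+1 for cue contrasts).
#' @param m mediator (expectation rating, or one voxel's betas).
#' @param y outcome (pain rating).
#' @param covariates optional numeric matrix/vector of first-level
#'   covariates (e.g., the other cue); must not include x, m or y.
#' @return named numeric vector `c(a, b, c, cprime, ab)`.
#' @export
fit_subject_paths <- function(x, m, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  Z <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  p <- ncol(Z) + 2L  # largest model: m + x + covariates + intercept
  if (n < p + 2L) stop("too few trials for the number of regressors")
  X1 <- cbind(x, Z)
  X2 <- cbind(m, x, Z)
  q1 <- qr(X1); q2 <- qr(X2)
  if (q1$rank < ncol(X1) || q2$rank < ncol(X2))
    stop("rank-deficient subject-level design")
  a <- qr.coef(q1, m)[1]
  cf2 <- qr.coef(q2, y)
  b <- cf2[1]; cprime <- cf2[2]
  cc <- qr.coef(q1, y)[1]
  c(a = unname(a), b = unname(b), c = unname(cc),
    cprime = unname(cprime), ab = unname(a * b))
}

#' Subject-level mediation paths for a whole cohort
#'
#' Applies [fit_subject_paths()] per subject on a trial table. Subjects
#' with rank-deficient designs are excluded with a warning.
#'
#' @param trials trial table.
#' @param x,m,y column names of treatment, mediator and outcome.
#' @param covariates column names of first-level covariates.
#' @param subset optional logical expression evaluated in `trials`
#'   (default: 49 C trials, `temp_code == 0`, matching the
#'   temperature-controlled mediation models).
#' @return subjects x 5 matrix of paths (a, b, c, cprime, ab).
#' @export
subject_paths <- function(trials, x = "social", m = "expect", y = "pain",
                          covariates = "cs", subset = NULL) {
  sub <- substitute(subset)
  if (!is.null(sub)) {
    keep <- eval(sub, trials, parent.frame())
    if (is.logical(keep)) trials <- trials[keep, , drop = FALSE]
  }
  subjects <- sort(unique(trials$subject))
  P <- matrix(NA_real_, length(subjects), 5,
              dimnames = list(subjects, c("a", "b", "c", "cprime", "ab")))
  for (k in seq_along(subjects)) {
    d <- trials[trials$subject == subjects[k], , drop = FALSE]
    cv <- if (length(covariates) > 0)
      as.matrix(d[, covariates, drop = FALSE]) else NULL
    P[k, ] <- tryCatch(
      fit_subject_paths(d[[x]], d[[m]], d[[y]], cv),
      error = function(e) rep(NA_real_, 5))
  }
  bad <- !stats::complete.cases(P)
  if (any(bad))
    warning("subjects excluded from mediation: ",
            paste(rownames(P)[bad], collapse = ", "))
  P[!bad, , drop = FALSE]
}

#' @noRd
boot_index_matrix <- function(n, n_boot, seed) {
  set.seed(as.integer(seed))
  matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
}

#' Bias-corrected bootstrap p-value for a mean statistic
#'
#' Two-sided p from the bias-corrected percentile method: the smallest
#' alpha at which the BC interval excludes zero. Proportions are clamped to
#' (1/(B+1), B/(B+1)) so p-values are never exactly 0 or 1.
#' @noRd
bc_boot_p <- function(boot, est) {
  B <- length(boot)
  clamp <- function(p) pmin(pmax(p, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(clamp(mean(boot < est)))
  zl <- stats::qnorm(clamp(mean(boot <= 0))) - 2 * z0
  2 * min(stats::pnorm(zl), 1 - stats::pnorm(zl))
}

#' Group-level mediation inference
#'
#' Tests each path's subject-level estimates at the group level by
#' resampling subjects with replacement. The mediated effect ab is tested
#' as the mean of the subject-level products a_i * b_i, which carries the
#' across-subject covariance component:
#' mean(ab) = mean(a)*mean(b) + ((n-1)/n)*cov(a, b).
#'
#' The default `"bootstrap"` method is the studentized (bootstrap-t)
#' bootstrap: each resample contributes a pivot
#' `T* = (mean* - mean) / se*`, and the two-sided p-value is the fraction
#' of `|T*|` at or beyond the observed `|t|`. The studentized pivot is
#' second-order accurate, which keeps the extreme-tail p-values (the ones
#' that matter under voxelwise FDR correction) calibrated at realistic
#' subject counts. A bias-corrected percentile variant (`"bc"`) and two
#' fast fallbacks are also available: `"ttest"` (one-sample t per path)
#' and `"sobel"` (delta-method z for ab from the group means and SEs of a
#' and b, t tests for the other paths).
#'
#' @param paths subjects x paths matrix from [subject_paths()].
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed RNG seed (bootstrap is reproducible bit-for-bit).
#' @param method "bootstrap" (studentized), "bc" (bias-corrected
#'   percentile), "ttest", or "sobel".
#' @param conf CI level.
#' @return object of class `mediation_result`: data frame (path, estimate,
#'   se, ci_lo, ci_hi, p) with attributes `decomposition` (ab split into
#'   mean product and covariance components), `paths`, `method`.
#' @export
group_mediation <- function(paths, n_boot = 10000, seed = 1L,
                            method = c("bootstrap", "bc", "ttest", "sobel"),
                            conf = 0.95) {
  method <- match.arg(method)
  paths <- as.matrix(paths)
  n <- nrow(paths)
  if (n < 3) stop("need at least 3 subjects")
  est <- colMeans(paths)
  sds <- apply(paths, 2, stats::sd)
  if (any(sds == 0))
    warning("zero between-subject variance for path(s): ",
            paste(colnames(paths)[sds == 0], collapse = ", "))
  alpha <- 1 - conf
  if (method %in% c("bootstrap", "bc")) {
    idx <- boot_index_matrix(n, n_boot, seed)
    rows <- lapply(colnames(paths), function(pn) {
      v <- paths[, pn]
      if (sds[pn] == 0) {
        p <- if (est[pn] == 0) 1 else 1 / (n_boot + 1)
        return(data.frame(path = pn, estimate = est[pn], se = 0,
                          ci_lo = est[pn], ci_hi = est[pn], p = p))
      }
      bm <- matrix(v[idx], n_boot, n)
      boot <- rowMeans(bm)
      if (method == "bootstrap") {
        se_hat <- sds[pn] / sqrt(n)
        bv <- (rowMeans(bm^2) - boot^2) * n / (n - 1)
        tb <- (boot - est[pn]) / sqrt(bv / n)
        tb[!is.finite(tb)] <- Inf
        t_obs <- est[pn] / se_hat
        p <- (1 + sum(abs(tb) >= abs(t_obs))) / (n_boot + 1)
        qs <- stats::quantile(tb, c(1 - alpha / 2, alpha / 2),
                              names = FALSE)
        data.frame(path = pn, estimate = est[pn], se = stats::sd(boot),
                   ci_lo = est[pn] - qs[1] * se_hat,
                   ci_hi = est[pn] - qs[2] * se_hat, p = p)
      } else {
        z0 <- stats::qnorm(min(max(mean(boot < est[pn]), 1 / (n_boot + 1)),
                               n_boot / (n_boot + 1)))
        ql <- stats::pnorm(2 * z0 + stats::qnorm(alpha / 2))
        qu <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha / 2))
        ci <- stats::quantile(boot, c(ql, qu), names = FALSE)
        data.frame(path = pn, estimate = est[pn], se = stats::sd(boot),
                   ci_lo = ci[1], ci_hi = ci[2],
                   p = bc_boot_p(boot, est[pn]))
      }
    })
    res <- do.call(rbind, rows)
  } else {
    rows <- lapply(colnames(paths), function(pn) {
      g <- group_effect(paths[, pn], label = pn)
      data.frame(path = pn, estimate = g$beta, se = sds[pn] / sqrt(n),
                 ci_lo = g$ci_lo, ci_hi = g$ci_hi, p = g$p)
    })
    res <- do.call(rbind, rows)
    if (method == "sobel" && all(c("a", "b", "ab") %in% colnames(paths))) {
      sa <- sds["a"] / sqrt(n); sb <- sds["b"] / sqrt(n)
      se_ab <- sqrt(est["b"]^2 * sa^2 + est["a"]^2 * sb^2)
      z <- (est["a"] * est["b"]) / se_ab
      i <- which(res$path == "ab")
      res$estimate[i] <- est["a"] * est["b"]
      res$se[i] <- se_ab
      zq <- stats::qnorm(1 - alpha / 2)
      res$ci_lo[i] <- res$estimate[i] - zq * se_ab
      res$ci_hi[i] <- res$estimate[i] + zq * se_ab
      res$p[i] <- 2 * stats::pnorm(-abs(z))
    }
  }
  rownames(res) <- NULL
  decomp <- NULL
  if (all(c("a", "b", "ab") %in% colnames(paths))) {
    decomp <- c(mean_product = unname(est["a"] * est["b"]),
                covariance = unname((n - 1) / n *
                                      stats::cov(paths[, "a"], paths[, "b"])))
  }
  structure(res, decomposition = decomp, paths = paths, method = method,
            n_subjects = n, class = c("mediation_result", "data.frame"))
}

#' Full multilevel mediation on a trial table
#'
#' Convenience wrapper: [subject_paths()] followed by [group_mediation()].
#'
#' @inheritParams subject_paths
#' @inheritParams group_mediation
#' @return a `mediation_result`.
#' @export
mediate <- function(trials, x = "social", m = "expect", y = "pain",
                    covariates = "cs", subset = NULL,
                    n_boot = 10000, seed = 1L,
                    method = c("bootstrap", "bc", "ttest", "sobel")) {
  sub <- substitute(subset)
  keep <- if (is.null(sub)) NULL else eval(sub, trials, parent.frame())
  if (is.logical(keep)) trials <- trials[keep, , drop = FALSE]
  P <- subject_paths(trials, x = x, m = m, y = y, covariates = covariates)
  group_mediation(P, n_boot = n_boot, seed = seed,
                  method = match.arg(method))
}

#' Individual-difference moderation of a subject-level slope
#'
#' Second-level regression of per-subject slopes on a subject-level
#' moderator, with influence diagnostics (leverage and Cook's distance;
#' subjects more than 3 SDs from the mean on both variables, or with
#' Cook's distance above 4/n, are flagged).
#'
#' @param slopes per-subject slope estimates.
#' @param moderator per-subject moderator values (one per subject).
#' @return list: `effect` (one-row data frame: beta, se, t, df, p),
#'   `diagnostics` (per subject: leverage, cooks, flagged).
#' @export
moderated_mediation <- function(slopes, moderator) {
  stopifnot(length(slopes) == length(moderator))
  if (stats::sd(moderator) == 0) stop("constant moderator")
  fit <- stats::lm(slopes ~ moderator)
  sm <- summary(fit)$coefficients
  n <- length(slopes)
  zs <- scale(cbind(slopes, moderator))
  diag_df <- data.frame(
    subject = seq_len(n),
    leverage = stats::hatvalues(fit),
    cooks = stats::cooks.distance(fit),
    flagged = stats::cooks.distance(fit) > 4 / n |
      (abs(zs[, 1]) > 3 & abs(zs[, 2]) > 3)
  )
  list(effect = data.frame(beta = sm["moderator", "Estimate"],
                           se = sm["moderator", "Std. Error"],
                           t = sm["moderator", "t value"],
                           df = fit$df.residual,
                           p = sm["moderator", "Pr(>|t|)"]),
       diagnostics = diag_df)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Multilevel mediation (", attr(x, "method"), " inference, n = ",
      attr(x, "n_subjects"), " subjects)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  d <- attr(x, "decomposition")
  if (!is.null(d))
    cat(sprintf("ab = mean(a)*mean(b) + cov component: %.4g + %.4g\n",
                d["mean_product"], d["covariance"]))
  invisible(x)
}
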