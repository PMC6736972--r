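#' Leave-one-subject-out forced-choice classification
#'
#' Trains a linear support vector machine to separate each subject's
#' Social-contrast image from their CS-contrast image, with
#' leave-one-subject-out cross-validation: for each held-out subject the
#' classifier is trained on the remaining subjects' labeled image pairs
#' (features standardized with training-fold statistics only) and the
#' held-out pair is scored by the forced-choice rule — correct iff the
#' Social image receives the higher Social-side decision value than the CS
#' image. Accuracy is the fraction of subjects correct, its SE the
#' binomial SE across subjects, and significance a two-sided exact
#' binomial test against chance (0.5).
#'
#' The forced-choice rule compares two decision values from the same
#' model, so accuracy is invariant to any monotone transform of the
#' decision values.
#'
#' @param social,cs subjects x voxels matrices of contrast images on a
#'   common mask, rows aligned by subject.
#' @param cost SVM margin cost parameter (conventional default 1).
#' @return object of class `loso_result`: list with `accuracy`, `se`, `p`,
#'   `correct` (per-subject logical), `decision` (subjects x 2 matrix of
#'   Social-side decision values for the social and cs images).
#' @export
loso_forced_choice <- function(social, cs, cost = 1) {
  social <- as.matrix(social)
  cs <- as.matrix(cs)
  stopifnot(identical(dim(social), dim(cs)))
  n <- nrow(social)
  if (n < 3) stop("need at least 3 subjects")
  if (any(apply(social, 1, stats::sd) == 0) ||
      any(apply(cs, 1, stats::sd) == 0))
    stop("constant images cannot be classified")
  correct <- logical(n)
  dec <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("social", "cs")))
  for (i in seq_len(n)) {
    Xtr <- rbind(social[-i, , drop = FALSE], cs[-i, , drop = FALSE])
    ytr <- factor(rep(c("social", "cs"), each = n - 1),
                  levels = c("cs", "social"))
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    use <- sdv > 0
    if (!any(use)) stop("no informative features in training fold")
    std <- function(M) sweep(sweep(M[, use, drop = FALSE], 2, mu[use]),
                             2, sdv[use], "/")
    fit <- e1071::svm(std(Xtr), ytr, kernel = "linear", cost = cost,
                      scale = FALSE)
    Xte <- std(rbind(social[i, , drop = FALSE], cs[i, , drop = FALSE]))
    dv <- attr(stats::predict(fit, Xte, decision.values = TRUE),
               "decision.values")
    # orient decision values so larger = more Social-like
    sgn <- if (grepl("^social", colnames(dv)[1])) 1 else -1
    dec[i, ] <- sgn * dv[, 1]
    correct[i] <- dec[i, "social"] > dec[i, "cs"]
  }
  acc <- mean(correct)
  structure(list(accuracy = acc,
                 se = sqrt(acc * (1 - acc) / n),
                 p = stats::binom.test(sum(correct), n, 0.5)$p.value,
                 correct = correct, decision = dec, n = n),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf(
    "LOSO forced-choice: %.1f%% +/- %.1f%% (n = %d), binomial p = %.4g\n",
    100 * x$accuracy, 100 * x$se, x$n, x$p))
  invisible(x)
}
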