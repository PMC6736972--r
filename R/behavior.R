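#' Generative parameters for behavioral ratings and SCR
#'
#' Parameters of the behavioral generative model. Expectation ratings follow
#'
#'   E = alpha_i + betaS_i * g(tS) * S + betaC_i * h(tC) * C + eps_E
#'
#' where S and C are the social and CS cue codes (-1/+1), tS/tC are
#' within-condition trial counters, g() is a mildly decreasing modulation of
#' the social effect, and h() is the learning curve of the CS effect with
#' h(1) = 0 (no learning before the first reinforcement). Pain ratings follow
#'
#'   P = alphaP_i + betaT_i * temp_code + gammaE_i * E
#'       + gammaS_i * S + gammaC_i * C + eps_P
#'
#' so the mediated effect of a cue through expectation is beta_cue * gammaE
#' under the generative model. Both ratings are clipped to `[0, 100]` after
#' noise. SCR amplitudes carry a weak positive social effect and a
#' temperature effect.
#'
#' Defaults are scaled to a 0-100 rating scale and sized so that the social
#' effect on expectations is large, the CS effect smaller and emerging over
#' time, and clipping rare (< 1 percent of trials).
#'
#' @param expect_intercept,expect_intercept_sd group mean / between-subject
#'   SD of the expectation intercept (rating units).
#' @param beta_social,beta_social_sd social cue weight on expectation at
#'   t = 1 (per unit of the -1/+1 code) and its between-subject SD.
#' @param beta_cs,beta_cs_sd asymptotic CS cue weight on expectation.
#' @param gamma_expect,gamma_expect_sd expectation-to-pain weight.
#' @param beta_temp,beta_temp_sd temperature weight on pain per coded unit.
#' @param direct_social,direct_social_sd direct (unmediated) social effect
#'   on pain.
#' @param direct_cs,direct_cs_sd direct CS effect on pain.
#' @param pain_intercept,pain_intercept_sd pain intercept.
#' @param sd_expect,sd_pain within-subject residual SDs of the ratings.
#' @param scr_intercept,scr_social,scr_temp,sd_scr SCR amplitude model
#'   (microsiemens-scale arbitrary units).
#' @param g_social time modulation of the social effect; function of the
#'   within-condition trial counter, defaulting to a linear decrease from 1
#'   to 0.6 across 48 trials per condition.
#' @param h_cs CS learning curve; saturating exponential
#'   `1 - exp(-(t - 1) / tau)` with tau = 12 trials, so `h(1) = 0`.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(expect_intercept = 45, expect_intercept_sd = 10,
                            beta_social = 12, beta_social_sd = 3,
                            beta_cs = 4, beta_cs_sd = 1.5,
                            gamma_expect = 0.4, gamma_expect_sd = 0.1,
                            beta_temp = 8, beta_temp_sd = 2,
                            direct_social = 1, direct_social_sd = 1,
                            direct_cs = 0.5, direct_cs_sd = 0.5,
                            pain_intercept = 25, pain_intercept_sd = 8,
                            sd_expect = 9, sd_pain = 8,
                            scr_intercept = 0.3, scr_social = 0.05,
                            scr_temp = 0.1, sd_scr = 0.3,
                            g_social = function(t) 1 - 0.4 * (t - 1) / 47,
                            h_cs = function(t) 1 - exp(-(t - 1) / 12)) {
  p <- as.list(environment())
  sds <- p[grepl("_sd$|^sd_", names(p))]
  if (any(unlist(sds) < 0)) stop("all SDs must be non-negative")
  structure(p, class = "behavior_params")
}

#' Generate behavioral ratings and SCR for a trial table
#'
#' Fills a design table (see [generate_design()]) with expectation ratings,
#' pain ratings and single-trial SCR amplitudes under the generative model
#' documented in [behavior_params()]. Subject-level effects are drawn
#' independently per parameter (random intercepts and slopes). The pain
#' residual is retained in column `pain_eps` so that downstream brain
#' simulation can plant voxel populations that track the cue-independent
#' component of pain; `pain_raw` keeps the unclipped pain value so planted
#' brain mediators can be added before re-clipping.
#'
#' @param design trial table from [generate_design()].
#' @param params a [behavior_params()].
#' @param seed RNG seed (per-subject child seeds spawned from it).
#' @return The trial table with columns `expect`, `pain`, `pain_raw`,
#'   `pain_eps`, `scr` added. Attribute `truth` holds per-subject generative
#'   path values for the 49 C mediation models (see
#'   [behavior_ground_truth()]); attribute `clip_rate` the fraction of
#'   ratings clipped.
#' @export
generate_behavior <- function(design, params = behavior_params(), seed = 1L) {
  stopifnot(is.data.frame(design))
  subjects <- sort(unique(design$subject))
  seeds <- child_seeds(seed, length(subjects))
  out <- vector("list", length(subjects))
  truth <- vector("list", length(subjects))
  n_clipped <- 0L
  for (k in seq_along(subjects)) {
    set.seed(seeds[k])
    d <- design[design$subject == subjects[k], , drop = FALSE]
    n <- nrow(d)
    p <- params
    alphaE <- stats::rnorm(1, p$expect_intercept, p$expect_intercept_sd)
    bS <- stats::rnorm(1, p$beta_social, p$beta_social_sd)
    bC <- stats::rnorm(1, p$beta_cs, p$beta_cs_sd)
    gE <- stats::rnorm(1, p$gamma_expect, p$gamma_expect_sd)
    bT <- stats::rnorm(1, p$beta_temp, p$beta_temp_sd)
    gS <- stats::rnorm(1, p$direct_social, p$direct_social_sd)
    gC <- stats::rnorm(1, p$direct_cs, p$direct_cs_sd)
    alphaP <- stats::rnorm(1, p$pain_intercept, p$pain_intercept_sd)
    mu_e <- alphaE + bS * p$g_social(d$t_social) * d$social +
      bC * p$h_cs(d$t_cs) * d$cs
    expect <- mu_e + stats::rnorm(n, 0, p$sd_expect)
    expect_cl <- pmin(pmax(expect, 0), 100)
    eps_p <- stats::rnorm(n, 0, p$sd_pain)
    pain_raw <- alphaP + bT * d$temp_code + gE * expect_cl +
      gS * d$social + gC * d$cs + eps_p
    pain <- pmin(pmax(pain_raw, 0), 100)
    scr <- pmax(p$scr_intercept + p$scr_social * d$social +
                  p$scr_temp * d$temp_code + stats::rnorm(n, 0, p$sd_scr), 0)
    n_clipped <- n_clipped + sum(expect != expect_cl) + sum(pain != pain_raw)
    d$expect <- expect_cl
    d$pain <- pain
    d$pain_raw <- pain_raw
    d$pain_eps <- eps_p
    d$scr <- scr
    out[[k]] <- d
    # generative path values under the 49 C mediation models: project the
    # noise-free expectation onto the subject's realized cue design, so the
    # time-varying coefficient is averaged exactly as OLS would in
    # expectation
    i49 <- d$temp_code == 0
    X <- cbind(1, social = d$social[i49], cs = d$cs[i49])
    mu49 <- mu_e[i49]
    cf <- qr.coef(qr(X), mu49)
    truth[[k]] <- data.frame(
      subject = subjects[k],
      a_social = cf[["social"]], a_cs = cf[["cs"]],
      b = gE,
      cprime_social = gS, cprime_cs = gC
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  tr <- do.call(rbind, truth)
  tr$ab_social <- tr$a_social * tr$b
  tr$ab_cs <- tr$a_cs * tr$b
  attr(res, "truth") <- tr
  attr(res, "clip_rate") <- n_clipped / (2L * nrow(res))
  attr(res, "config") <- attr(design, "config")
  res
}

#' Generative ground-truth mediation paths for a synthetic cohort
#'
#' Group-level true values of paths a, b and ab for the behavioral
#' mediation models (cue -> expectation -> pain on 49 C trials), computed
#' from the per-subject generative effects stored by [generate_behavior()].
#' The group ab is `mean(a_i * b_i)`, which includes the across-subject
#' covariance component `mean(a)*mean(b) + ((n-1)/n) * cov(a, b)`.
#'
#' @param behavior a trial table from [generate_behavior()].
#' @return list with elements `social` and `cs`, each containing `a`, `b`,
#'   `ab`, and the `ab` decomposition.
#' @export
behavior_ground_truth <- function(behavior) {
  tr <- attr(behavior, "truth")
  if (is.null(tr)) stop("behavior table has no generative truth attribute")
  one <- function(a, b) {
    n <- length(a)
    list(a = mean(a), b = mean(b), ab = mean(a * b),
         ab_mean_component = mean(a) * mean(b),
         ab_cov_component = (n - 1) / n * stats::cov(a, b))
  }
  list(social = one(tr$a_social, tr$b), cs = one(tr$a_cs, tr$b),
       subjects = tr)
}
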