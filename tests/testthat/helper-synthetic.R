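# Shared small-scale fixtures, generated once per test run.

# behavior-only cohort at reduced n for fast behavioral tests
smoke_behavior <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- generate_design(design_config(n_subjects = 8, seed = 101))
      cache <<- generate_behavior(d, seed = 202)
    }
    cache
  }
})

# small full experiment (brain included) for map-level tests
smoke_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_experiment(
        config = design_config(n_subjects = 16, seed = 303),
        brain = brain_params(dim = c(12L, 12L, 12L),
                             block_dim = c(3L, 4L, 3L)),
        seed = 303)
    }
    cache
  }
})

# hand-constructed masked-spike series: a cluster of extreme points
# inflates the run median and m.a.d. enough that a moderate spike (index
# 54, value 17) only crosses the 10-m.a.d. threshold after the cluster is
# excluded by the first step-down iteration
masked_spike_series <- function() {
  c(seq(-2, 2, length.out = 41), rep(1000, 12), 17)
}

# noise-free behavior parameters implementing the exact generative chain
# (CS weight zeroed so the time-varying CS term cannot leak into the
# social path in finite samples). With sd_expect = 0 the mediator is an
# exact function of the cue, so path a and the generative pain contrast
# are exact but b is unidentifiable (mediator collinear with cue); with
# sd_expect > 0 and sd_pain = 0, paths b and c-prime are exact instead.
noiseless_params <- function(beta_social = 5, gamma_expect = 1,
                             g_social = function(t) rep(1, length(t)),
                             h_cs = function(t) 1 - exp(-(t - 1) / 12),
                             direct_social = 0, direct_cs = 0,
                             sd_expect = 0, pain_intercept = 0) {
  behavior_params(
    expect_intercept_sd = 0, beta_social = beta_social, beta_social_sd = 0,
    beta_cs = 0, beta_cs_sd = 0,
    gamma_expect = gamma_expect, gamma_expect_sd = 0,
    beta_temp_sd = 0, direct_social = direct_social, direct_social_sd = 0,
    direct_cs = direct_cs, direct_cs_sd = 0,
    pain_intercept = pain_intercept, pain_intercept_sd = 0,
    sd_expect = sd_expect, sd_pain = 0, sd_scr = 0,
    g_social = g_social, h_cs = h_cs)
}
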