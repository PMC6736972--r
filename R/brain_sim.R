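#' Parameters for the synthetic single-trial brain data
#'
#' The brain generator plants four disjoint voxel populations on a 3-D grid:
#'
#' * social mediators: per-subject latent `L_t = a_i * S_t + eta_t` driving
#'   both the voxel signal and (via `b_i * L_t`) the pain rating;
#' * CS mediators: same structure driven by the CS cue;
#' * pain-only voxels: track the cue-independent pain residual (path b
#'   without path a);
#' * null voxels: pure Gaussian noise.
#'
#' Subject-level `(a_i, b_i)` pairs are drawn from a bivariate normal with
#' configurable correlation, so the group mediation effect
#' `E[a_i b_i] = mean(a) * mean(b) + cov(a, b)` carries both a mean and a
#' covariance component, as in real multilevel mediation maps.
#'
#' Populations are contiguous rectangular blocks (so that connected-component
#' pruning and spatial-similarity analyses have realistic cluster structure);
#' the default 20 x 20 x 20 grid with 200-voxel populations keeps voxelwise
#' analyses at minute scale while leaving thousands of null voxels for FDR
#' calibration.
#'
#' @param dim grid dimensions (3 integers).
#' @param block_dim dimensions of each planted rectangular population.
#' @param a_social,a_social_sd,b_social,b_social_sd,ab_cor_social social
#'   mediator population: means/SDs of subject-level a and b and their
#'   correlation.
#' @param a_cs,a_cs_sd,b_cs,b_cs_sd,ab_cor_cs same for the CS population.
#' @param pain_gain coupling of pain-only voxels to the pain residual.
#' @param latent_sd SD of the latent mediator noise `eta`.
#' @param voxel_noise_sd SD of i.i.d. voxel noise added everywhere.
#' @return object of class `brain_params`.
#' @export
brain_params <- function(dim = c(20L, 20L, 20L),
                         block_dim = c(5L, 8L, 5L),
                         a_social = 0.5, a_social_sd = 0.2,
                         b_social = 2, b_social_sd = 0.6,
                         ab_cor_social = 0.3,
                         a_cs = 0.5, a_cs_sd = 0.2,
                         b_cs = 2, b_cs_sd = 0.6,
                         ab_cor_cs = 0.3,
                         pain_gain = 0.1,
                         latent_sd = 1, voxel_noise_sd = 1) {
  stopifnot(length(dim) == 3, length(block_dim) == 3,
            all(block_dim * c(1, 1, 3) + 2 <= dim),
            latent_sd >= 0, voxel_noise_sd >= 0)
  structure(as.list(environment()), class = "brain_params")
}

#' Ground-truth population labels for the planted grid
#'
#' @param params a [brain_params()].
#' @return integer 3-D array: 0 null, 1 social mediators, 2 CS mediators,
#'   3 pain-only voxels. Populations are disjoint by construction.
#' @export
population_labels <- function(params = brain_params()) {
  lab <- array(0L, params$dim)
  bd <- params$block_dim
  place <- function(lab, code, origin) {
    lab[origin[1] + seq_len(bd[1]) - 1,
        origin[2] + seq_len(bd[2]) - 1,
        origin[3] + seq_len(bd[3]) - 1] <- code
    lab
  }
  # stack the three blocks along z with one-voxel gaps, offset from borders
  lab <- place(lab, 1L, c(2L, 2L, 2L))
  lab <- place(lab, 2L, c(2L, 2L, 2L + bd[3] + 1L))
  lab <- place(lab, 3L, c(2L, 2L, 2L + 2L * (bd[3] + 1L)))
  lab
}

#' Generate synthetic single-trial brain volumes with planted mediators
#'
#' Produces one trials x voxels matrix per subject plus ground-truth labels,
#' and adds the planted mediator contributions (`b_i * latent`) to the pain
#' ratings in the behavior table (pain is re-clipped to `[0, 100]`), so that
#' the planted voxels genuinely mediate the cue effects on the final pain
#' outcome.
#'
#' @param behavior trial table from [generate_behavior()] (must contain the
#'   `pain_raw` and `pain_eps` columns).
#' @param params a [brain_params()].
#' @param seed RNG seed (per-subject child seeds spawned from it).
#' @return list of class `brain_data`:
#'   `datasets` (per subject, a trials x voxels matrix over in-mask voxels),
#'   `mask` (logical 3-D array, all TRUE by default),
#'   `labels` (integer 3-D truth array, see [population_labels()]),
#'   `trials` (behavior table with mediator contributions added to `pain`),
#'   `subject_effects` (per-subject planted a and b values),
#'   `params`.
#' @export
generate_brain <- function(behavior, params = brain_params(), seed = 1L) {
  stopifnot(is.data.frame(behavior),
            all(c("pain_raw", "pain_eps") %in% names(behavior)))
  lab <- population_labels(params)
  mask <- array(TRUE, params$dim)
  labv <- as.integer(lab)
  idx_soc <- which(labv == 1L)
  idx_cs <- which(labv == 2L)
  idx_pain <- which(labv == 3L)
  V <- sum(mask)
  subjects <- sort(unique(behavior$subject))
  seeds <- child_seeds(seed, length(subjects))
  mv <- function(mu, sds, rho) {
    S <- diag(sds) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sds)
    MASS::mvrnorm(1, mu, S)
  }
  datasets <- vector("list", length(subjects))
  eff <- vector("list", length(subjects))
  trials <- behavior
  for (k in seq_along(subjects)) {
    set.seed(seeds[k])
    rows <- which(trials$subject == subjects[k])
    d <- trials[rows, , drop = FALSE]
    n <- nrow(d)
    abS <- mv(c(params$a_social, params$b_social),
              c(params$a_social_sd, params$b_social_sd), params$ab_cor_social)
    abC <- mv(c(params$a_cs, params$b_cs),
              c(params$a_cs_sd, params$b_cs_sd), params$ab_cor_cs)
    L_soc <- abS[1] * d$social + stats::rnorm(n, 0, params$latent_sd)
    L_cs <- abC[1] * d$cs + stats::rnorm(n, 0, params$latent_sd)
    Y <- matrix(stats::rnorm(n * V, 0, params$voxel_noise_sd), n, V)
    Y[, idx_soc] <- Y[, idx_soc] + L_soc
    Y[, idx_cs] <- Y[, idx_cs] + L_cs
    Y[, idx_pain] <- Y[, idx_pain] + params$pain_gain * d$pain_eps
    trials$pain_raw[rows] <- d$pain_raw + abS[2] * L_soc + abC[2] * L_cs
    trials$pain[rows] <- pmin(pmax(trials$pain_raw[rows], 0), 100)
    datasets[[k]] <- Y
    eff[[k]] <- data.frame(subject = subjects[k],
                           a_social = abS[1], b_social = abS[2],
                           a_cs = abC[1], b_cs = abC[2])
  }
  structure(list(datasets = datasets, mask = mask, labels = lab,
                 trials = trials,
                 subject_effects = do.call(rbind, eff),
                 params = params),
            class = "brain_data")
}

#' Simulate a complete synthetic experiment
#'
#' Convenience wrapper chaining [generate_design()], [generate_behavior()]
#' and (optionally) [generate_brain()] under one master seed (stage seeds
#' are spawned as children so stages stay reproducible independently).
#'
#' @param config a [design_config()].
#' @param behavior a [behavior_params()].
#' @param brain a [brain_params()], or `NULL` to skip brain simulation.
#' @param seed master seed; overrides `config$seed`.
#' @return list with `trials` (behavior table; pain includes planted brain
#'   mediator contributions when brain data are generated), `brain`
#'   (`brain_data` or `NULL`), `truth` (behavioral generative truth from
#'   [behavior_ground_truth()]), and `seeds`.
#' @export
simulate_experiment <- function(config = design_config(),
                                behavior = behavior_params(),
                                brain = brain_params(),
                                seed = config$seed) {
  s <- child_seeds(seed, 3L)
  config$seed <- s[1]
  des <- generate_design(config)
  beh <- generate_behavior(des, behavior, seed = s[2])
  truth <- behavior_ground_truth(beh)
  bd <- NULL
  trials <- beh
  if (!is.null(brain)) {
    bd <- generate_brain(beh, brain, seed = s[3])
    trials <- bd$trials
    attr(trials, "truth") <- attr(beh, "truth")
  }
  list(trials = trials, brain = bd, truth = truth,
       seeds = list(master = seed, design = s[1], behavior = s[2],
                    brain = s[3]))
}
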