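#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end synthetic analysis: design,
#' behavioral and brain generative parameters, thresholds, bootstrap
#' settings and seeds. Every stochastic stage receives an explicit child
#' seed spawned from `seed`.
#'
#' @param seed master seed.
#' @param design a [design_config()].
#' @param behavior a [behavior_params()].
#' @param brain a [brain_params()], or NULL for a behavior-only run.
#' @param q FDR level.
#' @param p01,p05 display-tier thresholds.
#' @param vif_threshold single-trial VIF exclusion cutoff.
#' @param mad_threshold spike-detection threshold in m.a.d. units.
#' @param n_boot_behavior bootstrap resamples for behavioral mediation.
#' @param n_boot_maps bootstrap resamples for voxelwise group inference.
#' @param method group inference method ("bootstrap", "ttest", "sobel");
#'   the "sobel"/"ttest" profiles are fast smoke-test fallbacks.
#' @param connectivity component connectivity for display pruning.
#' @param svm_cost SVM margin cost for classification.
#' @param n_networks networks in the synthetic partition.
#' @param n_terms term maps in the synthetic decoding stack.
#' @param run_single_trial_audit run the per-run single-trial design /
#'   VIF / spike audit stage (TRUE by default).
#' @param output_dir optional directory for TSV/NIfTI/JSON artifacts.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       design = design_config(),
                       behavior = behavior_params(),
                       brain = brain_params(),
                       q = 0.05, p01 = 0.01, p05 = 0.05,
                       vif_threshold = 2.5, mad_threshold = 10,
                       n_boot_behavior = 10000, n_boot_maps = 5000,
                       method = "bootstrap", connectivity = 26,
                       svm_cost = 1, n_networks = 7, n_terms = 20,
                       run_single_trial_audit = TRUE,
                       output_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic analysis end to end
#'
#' Executes the complete chain: synthetic data generation, the
#' single-trial audit stage (per-run single-trial designs with nuisance
#' regressors, spike detection on a synthetic global signal, VIF-based
#' trial exclusion), behavioral multilevel GLMs and mediation, voxelwise
#' mediation for the Social and CS models, FDR thresholding with display
#' pruning, conjunctions (a with ab per model, Social with CS across
#' models) and Dice overlap, planted-population recovery scoring,
#' signature scoring, network similarity / subnetwork contrasts /
#' octant-SSD / term decoding, and leave-one-subject-out forced-choice
#' classification. All stages are deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @return a nested list of stage results (see the individual functions),
#'   with `manifest` describing written artifacts (when `output_dir` is
#'   set) and `config` echoing the configuration.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- child_seeds(config$seed, 10L)
  res <- list(config = config)

  ## ---- synthetic data ----
  synth <- stage("synthetic_data",
                 simulate_experiment(config$design, config$behavior,
                                     config$brain, seed = seeds[1]))
  trials <- synth$trials
  res$truth <- synth$truth

  ## ---- single-trial audit: spikes + VIF exclusions ----
  if (config$run_single_trial_audit) {
    res$single_trial <- stage("single_trial", {
      set.seed(seeds[2])
      n_time <- 320L
      vif_log <- list()
      spike_n <- 0L
      excluded <- rep(FALSE, nrow(trials))
      for (s in sort(unique(trials$subject))) {
        for (r in sort(unique(trials$run))) {
          rows <- which(trials$subject == s & trials$run == r)
          nt <- length(rows)
          onsets <- sort(sample(seq(10L, n_time - 10L), nt))
          g <- stats::rnorm(n_time)
          sp <- detect_spikes(cbind(g), config$mad_threshold)
          spike_n <- spike_n + nrow(sp)
          nuis <- matrix(stats::rnorm(n_time * 24L), n_time, 24L)
          X <- single_trial_design(n_time, onsets, nuisance = nuis,
                                   spikes = sp$index)
          vifs <- compute_vif(X)[attr(X, "trial_cols")]
          flt <- apply_vif_filter(seq_len(nt), vifs,
                                  config$vif_threshold, subject = s)
          excluded[rows[!flt$kept]] <- TRUE
          if (nrow(flt$log) > 0) vif_log[[length(vif_log) + 1L]] <- flt$log
        }
      }
      trials$vif_excluded <- excluded
      list(n_spikes = spike_n,
           n_vif_excluded = sum(excluded),
           vif_log = if (length(vif_log)) do.call(rbind, vif_log)
           else data.frame())
    })
    trials <- trials[!trials$vif_excluded, , drop = FALSE]
  }

  ## ---- behavioral multilevel GLMs ----
  res$behavior <- stage("behavior_stats", {
    temp_eff <- fit_multilevel_glm(trials, "pain", "temp_code")
    exp_eff <- fit_multilevel_glm(trials, "expect", c("social", "cs"))
    pain_eff <- fit_multilevel_glm(trials, "pain", c("social", "cs"),
                                   subset = temp_code == 0)
    scr_eff <- fit_multilevel_glm(trials, "scr", c("social", "cs"),
                                  subset = temp_code == 0)
    bexp <- attr(exp_eff, "subject_betas")
    list(
      temperature = temp_eff,
      expectation = exp_eff,
      pain = pain_eff,
      scr = scr_eff,
      social_vs_cs_expect = paired_contrast(bexp[, "social"], bexp[, "cs"],
                                            "social-vs-cs"),
      social_time_expect = fit_time_interaction(trials, "expect", "social"),
      cs_time_expect = fit_time_interaction(trials, "expect", "cs"),
      cs_time_pain = fit_time_interaction(trials, "pain", "cs",
                                          subset = temp_code == 0),
      timecourse = condition_timecourse(trials, "expect", window = 4,
                                        n_boot = 500, seed = seeds[3])
    )
  })

  ## ---- behavioral mediation ----
  res$mediation <- stage("behavior_mediation", list(
    social = mediate(trials, x = "social", covariates = "cs",
                     subset = temp_code == 0,
                     n_boot = config$n_boot_behavior, seed = seeds[4],
                     method = config$method),
    cs = mediate(trials, x = "cs", covariates = "social",
                 subset = temp_code == 0,
                 n_boot = config$n_boot_behavior, seed = seeds[4],
                 method = config$method)
  ))

  if (is.null(synth$brain)) return(res)
  brain <- synth$brain

  ## ---- voxelwise mediation ----
  res$maps <- stage("voxelwise_mediation", list(
    social = voxelwise_mediation(brain, trials, x = "social",
                                 n_boot = config$n_boot_maps,
                                 seed = seeds[5], method = config$method),
    cs = voxelwise_mediation(brain, trials, x = "cs",
                             n_boot = config$n_boot_maps,
                             seed = seeds[5], method = config$method)
  ))

  ## ---- thresholding, pruning, conjunction, Dice ----
  res$thresholded <- stage("thresholding", {
    th <- lapply(res$maps, function(mm)
      lapply(fdr_threshold(mm$maps[c("a", "b", "ab")], q = config$q,
                           pool_paths = TRUE,
                           p01 = config$p01, p05 = config$p05),
             prune_display, connectivity = config$connectivity))
    th
  })
  res$conjunctions <- stage("conjunction", {
    cj <- list(
      social_a_ab = conjunction(res$thresholded$social$a,
                                res$thresholded$social$ab),
      cs_a_ab = conjunction(res$thresholded$cs$a, res$thresholded$cs$ab),
      social_cs_a = conjunction(res$thresholded$social$a,
                                res$thresholded$cs$a),
      social_cs_ab = conjunction(res$thresholded$social$ab,
                                 res$thresholded$cs$ab))
    # Dice at p < 0.05 uncorrected (unpruned two-sided p)
    p05mask <- function(map) {
      arr <- array(FALSE, map$dim)
      arr[map$mask] <- map$p < 0.05
      arr
    }
    cj$dice_a <- dice(p05mask(res$maps$social$maps$a),
                      p05mask(res$maps$cs$maps$a))
    cj$dice_ab <- dice(p05mask(res$maps$social$maps$ab),
                       p05mask(res$maps$cs$maps$ab))
    cj
  })

  ## ---- planted-population recovery ----
  res$recovery <- stage("recovery", {
    labs <- brain$labels[brain$mask]
    one <- function(tmap, target_lab) {
      hit <- significant_mask(tmap, tier = "fdr")[brain$mask]
      list(sensitivity = mean(hit[labs == target_lab]),
           fdp_null = if (sum(hit) > 0)
             sum(hit & labs == 0L) / sum(hit) else 0,
           null_rate = mean(hit[labs == 0L]))
    }
    list(social_ab = one(res$thresholded$social$ab, 1L),
         cs_ab = one(res$thresholded$cs$ab, 2L),
         pain_b = one(res$thresholded$social$b, 3L))
  })

  ## ---- signature scoring ----
  res$signature <- stage("signature", {
    pattern <- as.numeric(brain$labels[brain$mask] == 3L)
    pattern <- pattern / sum(pattern)
    st <- trials
    st$sig <- NA_real_
    subj_ids <- sort(unique(st$subject))
    for (k in seq_along(subj_ids)) {
      rows <- which(st$subject == subj_ids[k])
      # dataset rows are in original trial order, so the trial index
      # addresses the right row even after VIF exclusions
      st$sig[rows] <- score_signature(
        brain$datasets[[k]][st$trial[rows], , drop = FALSE], pattern)
    }
    list(pain_slope = fit_multilevel_glm(st, "pain", "sig",
                                         subset = temp_code == 0),
         cue_effects = fit_multilevel_glm(st, "sig", c("social", "cs"),
                                          subset = temp_code == 0))
  })

  ## ---- network-level decoding ----
  res$networks <- stage("network_analysis", {
    part <- synthetic_partition(dim(brain$mask), config$n_networks,
                                seed = seeds[6],
                                seed_masks = list(brain$labels == 1L,
                                                  brain$labels == 2L,
                                                  brain$labels == 3L))
    wedge <- list(
      social_ab = network_similarity(res$thresholded$social$ab, part,
                                     brain$mask),
      cs_ab = network_similarity(res$thresholded$cs$ab, part, brain$mask))
    subnet <- subnetwork_contrast(res$maps$social$subject_paths$a,
                                  res$maps$cs$subject_paths$a,
                                  part, brain$mask)
    oct <- octant_summary(res$maps$social$maps$ab, res$maps$cs$maps$ab,
                          part, brain$mask)
    set.seed(seeds[7])
    V <- sum(brain$mask)
    terms <- lapply(seq_len(config$n_terms), function(i)
      stats::rnorm(V))
    names(terms) <- sprintf("noise%02d", seq_len(config$n_terms))
    terms$planted_social <- as.numeric(brain$labels[brain$mask] == 1L) +
      stats::rnorm(V, 0, 0.5)
    terms$planted_cs <- as.numeric(brain$labels[brain$mask] == 2L) +
      stats::rnorm(V, 0, 0.5)
    tm <- do.call(cbind, terms)
    list(partition = part, wedge = wedge, subnetworks = subnet,
         octants = oct,
         terms_social_ab = term_decode(res$maps$social$maps$ab$estimate,
                                       tm, k = 10),
         terms_cs_ab = term_decode(res$maps$cs$maps$ab$estimate,
                                   tm, k = 10))
  })

  ## ---- classification ----
  res$classification <- stage("classification", {
    umask <- res$conjunctions$social_a_ab | res$conjunctions$cs_a_ab
    if (sum(umask) < 10)
      umask <- significant_mask(res$thresholded$social$ab, "fdr") |
        significant_mask(res$thresholded$cs$ab, "fdr")
    if (sum(umask) < 10) umask <- brain$mask
    cols <- which(umask[brain$mask])
    loso_forced_choice(res$maps$social$subject_paths$a[, cols, drop = FALSE],
                       res$maps$cs$subject_paths$a[, cols, drop = FALSE],
                       cost = config$svm_cost)
  })

  ## ---- artifacts + manifest ----
  if (!is.null(config$output_dir)) {
    res$manifest <- stage("manifest", {
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
      files <- write_trials_tsv(trials, file.path(config$output_dir,
                                                  "trials"))
      for (mdl in names(res$thresholded)) {
        for (p in names(res$thresholded[[mdl]])) {
          files <- c(files, write_thresholded_nifti(
            res$thresholded[[mdl]][[p]],
            file.path(config$output_dir, paste0(mdl, "_", p))))
        }
      }
      report <- list(
        seed = config$seed,
        attained_fdr_cutoff = list(
          social = res$thresholded$social$a$cutoff,
          cs = res$thresholded$cs$a$cutoff),
        voxels_per_tier = lapply(res$thresholded, function(m)
          lapply(m, function(t) as.list(table(t$tier)))),
        dice = list(a = res$conjunctions$dice_a,
                    ab = res$conjunctions$dice_ab),
        n_vif_excluded = res$single_trial$n_vif_excluded,
        classification = list(accuracy = res$classification$accuracy,
                              p = res$classification$p))
      fr <- file.path(config$output_dir, "report.json")
      jsonlite::write_json(report, fr, auto_unbox = TRUE, pretty = TRUE)
      files <- c(files, fr)
      data.frame(file = files, md5 = unname(tools::md5sum(files)))
    })
  }
  res
}
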