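#' Experimental design configuration
#'
#' Describes the factorial pain-learning design: a 2 (social information:
#' low/high) x 2 (conditioned stimulus, CS: low/high) cue structure crossed
#' with three stimulation temperatures. The CS is partially reinforced
#' (CS-low is followed by 48 or 49 degrees C, CS-high by 49 or 50 degrees C,
#' 50/50 each), while the social cue is statistically independent of
#' temperature. The default configuration is 36 subjects, 6 runs of 16
#' trials (96 trials total), yielding exactly 24 trials at 48 C, 48 at
#' 49 C and 24 at 50 C per subject.
#'
#' @param n_subjects number of subjects (default 36).
#' @param n_trials trials per subject (default 96).
#' @param n_runs runs per subject (default 6).
#' @param trials_per_run trials per run (default 16); must satisfy
#'   `trials_per_run * n_runs == n_trials`.
#' @param temperatures stimulation temperatures in degrees C, coded
#'   -1/0/+1 in ascending order downstream.
#' @param cs_contingency named list with elements `low` and `high`, each a
#'   named numeric vector of temperature probabilities summing to 1.
#' @param seed master RNG seed; per-subject child seeds are spawned from it
#'   so that earlier subjects are unchanged when `n_subjects` grows.
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_subjects = 36, n_trials = 96, n_runs = 6,
                          trials_per_run = 16,
                          temperatures = c(48, 49, 50),
                          cs_contingency = list(
                            low  = c("48" = 0.5, "49" = 0.5),
                            high = c("49" = 0.5, "50" = 0.5)
                          ),
                          seed = 1L) {
  if (trials_per_run * n_runs != n_trials)
    stop("trials_per_run * n_runs must equal n_trials")
  if (!setequal(names(cs_contingency), c("low", "high")))
    stop("cs_contingency must have elements 'low' and 'high'")
  for (lev in c("low", "high")) {
    pr <- cs_contingency[[lev]]
    if (abs(sum(pr) - 1) > 1e-8)
      stop("cs_contingency probabilities for CS ", lev, " do not sum to 1")
    if (!all(names(pr) %in% as.character(temperatures)))
      stop("cs_contingency temperatures must be among `temperatures`")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 n_runs = as.integer(n_runs),
                 trials_per_run = as.integer(trials_per_run),
                 temperatures = sort(temperatures),
                 cs_contingency = cs_contingency,
                 seed = as.integer(seed)),
            class = "design_config")
}

#' Spawn reproducible child seeds from a master seed
#'
#' Child seeds are a prefix-stable stream: requesting more seeds never
#' changes the earlier ones, so adding subjects does not reshuffle existing
#' subjects' data.
#'
#' @param master master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
child_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(2147483646L, n)
}

#' Generate trial tables for the factorial cue design
#'
#' Builds one exactly counterbalanced trial table per subject: trial counts
#' per CS x temperature cell follow the contingency table exactly (not in
#' expectation), and the social cue is balanced within every CS x
#' temperature cell, making it independent of temperature by construction.
#' Trial order is randomized per subject under the subject's child seed.
#'
#' @param config a [design_config()].
#' @return A data frame (one row per subject x trial) with columns
#'   `subject`, `run`, `trial`, `social` (-1/+1), `cs` (-1/+1), `temp`
#'   (degrees C), `temp_code` (-1/0/+1), and within-condition trial
#'   counters `t_social`, `t_cs` (1-based order of appearance within each
#'   cue level, the time axis used for learning-curve effects).
#' @export
generate_design <- function(config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  n_half <- config$n_trials / 2L
  cells <- list()
  for (lev in c("low", "high")) {
    pr <- config$cs_contingency[[lev]]
    cnt <- pr * n_half
    if (any(abs(cnt - round(cnt)) > 1e-8))
      stop("contingency probabilities do not yield integer cell counts")
    cnt <- round(cnt)
    if (any(cnt %% 2L != 0L))
      stop("cell counts must be even to counterbalance the social cue")
    for (tp in names(cnt)) {
      k <- cnt[[tp]]
      if (k == 0L) next
      cells[[length(cells) + 1L]] <- data.frame(
        cs = if (lev == "low") -1 else 1,
        temp = as.numeric(tp),
        social = rep(c(-1, 1), each = k / 2L)
      )
    }
  }
  proto <- do.call(rbind, cells)
  seeds <- child_seeds(config$seed, config$n_subjects)
  out <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(seeds[i])
    tab <- proto[sample.int(nrow(proto)), , drop = FALSE]
    tab$subject <- i
    tab$run <- rep(seq_len(config$n_runs), each = config$trials_per_run)
    tab$trial <- seq_len(config$n_trials)
    tab$temp_code <- match(tab$temp, config$temperatures) -
      (length(config$temperatures) + 1L) / 2
    tab$t_social <- stats::ave(tab$trial, tab$social, FUN = seq_along)
    tab$t_cs <- stats::ave(tab$trial, tab$cs, FUN = seq_along)
    rownames(tab) <- NULL
    out[[i]] <- tab[, c("subject", "run", "trial", "social", "cs",
                        "temp", "temp_code", "t_social", "t_cs")]
  }
  res <- do.call(rbind, out)
  attr(res, "config") <- config
  res
}

#' Generate symbolic social-information stimuli
#'
#' Each stimulus depicts ten vertical lines on a 0-1 rating scale,
#' representing ten other participants' pain ratings. Positions are drawn
#' from N(0.3, 0.15) for the low condition and N(0.7, 0.15) for the high
#' condition, restricted to `[0, 1]` by rejection resampling (so the
#' realized distribution is the truncated normal).
#'
#' @param n_per_condition number of stimuli per condition.
#' @param seed RNG seed.
#' @param mean_low,mean_high condition means on the 0-1 scale.
#' @param sd common standard deviation.
#' @return A long data frame with columns `condition` ("low"/"high"),
#'   `stimulus` (index within condition), `line` (1-10), `position`.
#' @export
generate_social_stimuli <- function(n_per_condition = 48, seed = 1L,
                                    mean_low = 0.3, mean_high = 0.7,
                                    sd = 0.15) {
  stopifnot(n_per_condition >= 1)
  set.seed(as.integer(seed))
  draw <- function(n, mu) {
    x <- numeric(0)
    while (length(x) < n) {
      y <- stats::rnorm(2L * (n - length(x)), mu, sd)
      x <- c(x, y[y >= 0 & y <= 1])
    }
    x[seq_len(n)]
  }
  n_pos <- 10L * n_per_condition
  out <- data.frame(
    condition = rep(c("low", "high"), each = n_pos),
    stimulus = rep(rep(seq_len(n_per_condition), each = 10L), times = 2L),
    line = rep(1:10, times = 2L * n_per_condition),
    position = c(draw(n_pos, mean_low), draw(n_pos, mean_high))
  )
  out
}

#' Mean of a normal distribution truncated to an interval
#'
#' Closed-form mean of N(mu, sd) truncated to `[a, b]`; used as the
#' analytic reference for the rejection-sampled stimulus positions.
#'
#' @param mu,sd untruncated mean and SD.
#' @param a,b truncation bounds.
#' @return the truncated mean (numeric scalar).
#' @export
truncnorm_mean <- function(mu, sd, a = 0, b = 1) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) /
    (stats::pnorm(be) - stats::pnorm(al))
}
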