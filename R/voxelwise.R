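#' @noRd
residualize <- function(A, Z) {
  A - Z %*% qr.coef(qr(Z), A)
}

#' Subject-level mediation paths for every voxel
#'
#' Vectorized per-subject OLS of the three mediation regressions with one
#' voxel at a time as the mediator, via Frisch-Waugh-Lovell
#' residualization: identical to calling [fit_subject_paths()] per voxel
#' but in a handful of matrix operations.
#'
#' @param M trials x voxels mediator matrix.
#' @param x treatment vector.
#' @param y outcome vector.
#' @param covariates optional covariate matrix.
#' @return list of per-voxel vectors `a`, `b`, `c` (scalar, recycled),
#'   `cprime`, `ab`, plus `zero_var` (voxels with zero mediator variance,
#'   whose paths are NA).
#' @export
voxelwise_subject_paths <- function(M, x, y, covariates = NULL) {
  M <- as.matrix(M)
  n <- nrow(M)
  stopifnot(length(x) == n, length(y) == n)
  Z <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  xt <- drop(residualize(matrix(x), Z))
  Mt <- residualize(M, Z)
  yt <- drop(residualize(matrix(y), Z))
  sxx <- sum(xt^2)
  a <- colSums(xt * Mt) / sxx
  cc <- sum(xt * yt) / sxx
  # path b: residualize M and y on [Z, x]
  Zx <- cbind(Z, x)
  Mb <- residualize(M, Zx)
  yb <- drop(residualize(matrix(y), Zx))
  smm <- colSums(Mb^2)
  zero_var <- smm < 1e-12 * n
  b <- ifelse(zero_var, NA_real_, colSums(Mb * yb) / smm)
  a[zero_var] <- NA_real_
  ab <- a * b
  list(a = a, b = b, c = rep(cc, ncol(M)), cprime = cc - ab, ab = ab,
       zero_var = zero_var)
}

#' @noRd
new_stat_map <- function(estimate, p, mask, path, model) {
  structure(list(estimate = estimate, p = p, mask = mask,
                 dim = dim(mask), path = path, model = model),
            class = "stat_map")
}

#' Place a stat map's per-voxel values on its 3-D grid
#'
#' @param map a `stat_map`.
#' @param what "estimate" or "p".
#' @param fill value outside the mask.
#' @return 3-D array.
#' @export
map_to_array <- function(map, what = c("estimate", "p"), fill = NA_real_) {
  what <- match.arg(what)
  out <- array(fill, map$dim)
  out[map$mask] <- map[[what]]
  out
}

#' Voxelwise multilevel mediation
#'
#' Applies the mediation model independently at every in-mask voxel:
#' subject-level paths by vectorized OLS, then group inference with a
#' common subject-resampling plan across voxels (one bootstrap index
#' matrix per map, for speed and cross-voxel coherence). Only 49 C trials
#' are used by default (to control for temperature). Voxels with zero
#' variance in any subject are recorded with p = 1 and flagged.
#'
#' @param brain a `brain_data` object, or a list of trials x voxels
#'   matrices (one per subject) plus a `mask` argument.
#' @param trials trial table aligned with the voxel matrices.
#' @param x treatment column ("social" or "cs").
#' @param y outcome column.
#' @param covariates covariate columns (default: the other cue).
#' @param subset logical expression on `trials`; default `temp_code == 0`.
#' @param n_boot bootstrap resamples for group inference.
#' @param seed RNG seed.
#' @param method "bootstrap" (studentized, the calibrated default),
#'   "ttest", or "sobel" (see [group_mediation()]).
#' @param mask logical 3-D array when `brain` is a plain list.
#' @param chunk voxels per bootstrap chunk (memory control).
#' @return object of class `mediation_maps`: list with `maps` (stat_map
#'   per path a, b, ab, cprime), `subject_paths` (list of subjects x voxels
#'   matrices), `mask`, `model`, `n_flagged`.
#' @export
voxelwise_mediation <- function(brain, trials = NULL, x = "social",
                                y = "pain",
                                covariates = setdiff(c("social", "cs"), x),
                                subset = NULL, n_boot = 5000, seed = 1L,
                                method = c("bootstrap", "ttest", "sobel"),
                                mask = NULL, chunk = 2000L) {
  method <- match.arg(method)
  if (inherits(brain, "brain_data")) {
    datasets <- brain$datasets
    mask <- brain$mask
    if (is.null(trials)) trials <- brain$trials
  } else {
    datasets <- brain
    if (is.null(mask)) stop("mask required when brain is a plain list")
  }
  sub <- substitute(subset)
  keep_expr <- if (is.null(sub)) quote(temp_code == 0) else sub
  subjects <- sort(unique(trials$subject))
  stopifnot(length(subjects) == length(datasets))
  V <- ncol(datasets[[1]])
  n_subj <- length(subjects)
  paths <- c("a", "b", "ab", "cprime")
  SP <- lapply(paths, function(p) matrix(NA_real_, n_subj, V))
  names(SP) <- paths
  flagged <- logical(V)
  for (k in seq_len(n_subj)) {
    d <- trials[trials$subject == subjects[k], , drop = FALSE]
    keep <- eval(keep_expr, d, parent.frame())
    M <- datasets[[k]][keep, , drop = FALSE]
    cv <- if (length(covariates) > 0)
      as.matrix(d[keep, covariates, drop = FALSE]) else NULL
    sp <- voxelwise_subject_paths(M, d[[x]][keep], d[[y]][keep], cv)
    for (p in paths) SP[[p]][k, ] <- sp[[p]]
    flagged <- flagged | sp$zero_var
  }
  if (any(flagged))
    message(sum(flagged), " voxel(s) with zero variance flagged (p = 1)")
  est <- lapply(SP, function(m) colMeans(m))
  pv <- lapply(paths, function(p) rep(1, V))
  names(pv) <- paths
  ok <- !flagged
  if (method == "bootstrap") {
    # studentized bootstrap with one common subject-resampling plan
    # across all voxels and paths (see group_mediation for the pivot)
    idx <- boot_index_matrix(n_subj, n_boot, seed)
    W <- matrix(0, n_boot, n_subj)
    for (r in seq_len(n_subj)) {
      W[, r] <- rowSums(idx == r)
    }
    W <- W / n_subj
    vok <- which(ok)
    for (p in paths) {
      mat <- SP[[p]]
      for (start in seq(1, length(vok), by = chunk)) {
        cols <- vok[start:min(start + chunk - 1L, length(vok))]
        m <- mat[, cols, drop = FALSE]
        e <- est[[p]][cols]
        se_hat <- sqrt((colMeans(m^2) - e^2) * n_subj / (n_subj - 1) /
                         n_subj)
        m1 <- W %*% m
        m2 <- W %*% m^2
        bv <- (m2 - m1^2) * n_subj / (n_subj - 1)
        tb <- abs(m1 - rep(e, each = n_boot)) / sqrt(bv / n_subj)
        tb[!is.finite(tb)] <- Inf
        t_obs <- ifelse(se_hat > 0, abs(e) / se_hat, 0)
        cnt <- colSums(tb >= rep(t_obs, each = n_boot))
        pp <- (1 + cnt) / (n_boot + 1)
        pp[se_hat == 0] <- 1
        pv[[p]][cols] <- pp
      }
    }
  } else {
    for (p in paths) {
      mat <- SP[[p]]
      mu <- colMeans(mat)
      se <- apply(mat, 2, stats::sd) / sqrt(n_subj)
      tt <- ifelse(se > 0, mu / se, 0)
      pp <- 2 * stats::pt(-abs(tt), n_subj - 1)
      if (p == "ab" && method == "sobel") {
        ma <- colMeans(SP[["a"]]); mb <- colMeans(SP[["b"]])
        sa <- apply(SP[["a"]], 2, stats::sd) / sqrt(n_subj)
        sb <- apply(SP[["b"]], 2, stats::sd) / sqrt(n_subj)
        seab <- sqrt(mb^2 * sa^2 + ma^2 * sb^2)
        z <- ifelse(seab > 0, ma * mb / seab, 0)
        pp <- 2 * stats::pnorm(-abs(z))
      }
      pv[[p]][ok] <- pp[ok]
    }
  }
  maps <- lapply(paths, function(p) {
    e <- est[[p]]
    e[flagged] <- 0
    new_stat_map(e, pv[[p]], mask, path = p, model = x)
  })
  names(maps) <- paths
  structure(list(maps = maps, subject_paths = SP, mask = mask,
                 model = x, n_flagged = sum(flagged)),
            class = "mediation_maps")
}
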