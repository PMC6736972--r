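#' Benjamini-Hochberg step-up threshold
#'
#' Plain BH step-up over a p-value vector: reject the k smallest p-values
#' where k is the largest i with p_(i) <= i * q / m. Returns the realized
#' p cutoff (the largest rejected p; 0 when nothing is rejected).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param q FDR level.
#' @return list: `reject` (logical, aligned with `p`), `cutoff`.
#' @export
bh_threshold <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("invalid p-values")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  pass <- which(ps <= q * seq_len(m) / m)
  if (length(pass) == 0)
    return(list(reject = rep(FALSE, m), cutoff = 0))
  k <- max(pass)
  list(reject = p <= ps[k], cutoff = ps[k])
}

#' @noRd
tier_levels <- c("none", "p05", "p01", "fdr")

#' @noRd
new_thresholded_map <- function(map, tier, cutoff, q) {
  structure(list(estimate = map$estimate, p = map$p, tier = tier,
                 sign = sign(map$estimate), mask = map$mask, dim = map$dim,
                 path = map$path, model = map$model,
                 cutoff = cutoff, q = q),
            class = "thresholded_map")
}

#' FDR thresholding with display tiers
#'
#' Applies BH FDR at level `q` over all in-mask voxels, pooling p-values
#' across the supplied maps (e.g., paths a, b and ab of one model, as when
#' correcting "across the whole brain and mediation paths") when
#' `pool_paths` is TRUE, or per map otherwise. Each voxel is assigned a
#' tier: `fdr` (survives BH), `p01` (p < 0.01), `p05` (p < 0.05), or
#' `none`; tiers are nested as p-value sets. Signs are carried from the
#' effect estimates (thresholding is two-sided on p).
#'
#' @param maps a `stat_map` or list of `stat_map`s on one grid.
#' @param q FDR level (default 0.05).
#' @param pool_paths pool p-values across maps before BH (default TRUE).
#' @param p01,p05 display-tier thresholds.
#' @return a `thresholded_map` (or list thereof, matching the input), each
#'   carrying the attained voxel-level `cutoff`.
#' @export
fdr_threshold <- function(maps, q = 0.05, pool_paths = TRUE,
                          p01 = 0.01, p05 = 0.05) {
  single <- inherits(maps, "stat_map")
  if (single) maps <- list(maps)
  if (sum(maps[[1]]$mask) == 0) stop("empty mask")
  assign_tiers <- function(map, reject) {
    tier <- rep("none", length(map$p))
    tier[map$p < p05] <- "p05"
    tier[map$p < p01] <- "p01"
    tier[reject] <- "fdr"
    factor(tier, levels = tier_levels)
  }
  if (pool_paths) {
    pooled <- unlist(lapply(maps, `[[`, "p"))
    bh <- bh_threshold(pooled, q)
    lens <- vapply(maps, function(m) length(m$p), 1L)
    splits <- split(bh$reject, rep(seq_along(maps), lens))
    out <- lapply(seq_along(maps), function(i)
      new_thresholded_map(maps[[i]], assign_tiers(maps[[i]], splits[[i]]),
                          bh$cutoff, q))
  } else {
    out <- lapply(maps, function(m) {
      bh <- bh_threshold(m$p, q)
      new_thresholded_map(m, assign_tiers(m, bh$reject), bh$cutoff, q)
    })
  }
  names(out) <- names(maps)
  if (single) out[[1]] else out
}

#' Label connected components of a 3-D binary mask
#'
#' Flood-fill labeling under 6- (faces), 18- (faces+edges) or
#' 26-neighborhood (faces+edges+corners) connectivity.
#'
#' @param mask logical 3-D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3, connectivity %in% c(6, 18, 26))
  dm <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & nz <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, dm)
  nextlab <- 0L
  idx_all <- which(mask)
  coord <- arrayInd(idx_all, dm)
  pos <- array(0L, dm)
  pos[idx_all] <- seq_along(idx_all)
  visited <- logical(length(idx_all))
  for (s in seq_along(idx_all)) {
    if (visited[s]) next
    nextlab <- nextlab + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      lab[idx_all[cur]] <- nextlab
      cc <- coord[cur, ]
      nb <- sweep(offs, 2, cc, "+")
      okn <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
        nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[okn, , drop = FALSE]
      lin <- nb[, 1] + dm[1] * (nb[, 2] - 1L) + dm[1] * dm[2] * (nb[, 3] - 1L)
      pp <- pos[lin]
      pp <- pp[pp > 0]
      pp <- pp[!visited[pp]]
      if (length(pp) > 0) {
        visited[pp] <- TRUE
        queue <- c(queue, pp)
      }
    }
  }
  lab
}

#' @noRd
tier_array <- function(tmap) {
  out <- array(0L, tmap$dim)
  out[tmap$mask] <- as.integer(tmap$tier) - 1L  # 0 none .. 3 fdr
  out
}

#' Prune display tiers to clusters adjacent to FDR voxels
#'
#' Connected components of the lenient-threshold voxel sets (p < 0.05 and
#' p < 0.01) are retained only if they contain at least one FDR-significant
#' voxel; all other lenient voxels are demoted to `none`. FDR voxels are
#' never removed. Pruning is performed separately at each lenient level,
#' so the p01 tier remains a subset of the p05 tier.
#'
#' @param tmap a `thresholded_map` from [fdr_threshold()].
#' @param connectivity component connectivity (default 26).
#' @return the pruned `thresholded_map`.
#' @export
prune_display <- function(tmap, connectivity = 26) {
  stopifnot(inherits(tmap, "thresholded_map"))
  ta <- tier_array(tmap)
  fdr <- ta == 3L
  keep_at <- function(level_mask) {
    lab <- label_components(level_mask, connectivity)
    keep_labs <- setdiff(unique(lab[fdr]), 0L)
    lab > 0L & lab %in% keep_labs
  }
  keep05 <- keep_at(ta >= 1L)
  keep01 <- keep_at(ta >= 2L)
  new_ta <- array(0L, tmap$dim)
  new_ta[ta >= 1L & keep05] <- 1L
  new_ta[ta >= 2L & keep01] <- 2L
  new_ta[fdr] <- 3L
  tmap$tier <- factor(tier_levels[new_ta[tmap$mask] + 1L],
                      levels = tier_levels)
  tmap$pruned <- TRUE
  tmap
}

#' Binary significance mask of a thresholded map
#'
#' @param tmap a `thresholded_map`.
#' @param tier most lenient tier to include ("fdr", "p01" or "p05"); the
#'   returned mask contains all voxels at that tier or stricter.
#' @param sign "any", "pos" or "neg".
#' @return logical 3-D array.
#' @export
significant_mask <- function(tmap, tier = "p05", sign = "any") {
  stopifnot(inherits(tmap, "thresholded_map"),
            tier %in% c("fdr", "p01", "p05"))
  lev <- match(tier, tier_levels) - 1L
  ta <- tier_array(tmap)
  out <- ta >= lev
  if (sign != "any") {
    sa <- array(0, tmap$dim)
    sa[tmap$mask] <- tmap$sign
    out <- out & if (sign == "pos") sa > 0 else sa < 0
  }
  out
}

#' Conjunction of two significance maps (conjunction null)
#'
#' A voxel is in the conjunction iff it is significant, at its stated tier,
#' in BOTH maps — the conjunction-null rule, which requires each
#' constituent effect to be individually significant.
#'
#' @param m1,m2 `thresholded_map`s or logical 3-D arrays on the same grid.
#' @param tier tier passed to [significant_mask()] for thresholded input.
#' @param sign sign constraint passed to [significant_mask()].
#' @return logical 3-D array.
#' @export
conjunction <- function(m1, m2, tier = "p05", sign = "any") {
  as_mask <- function(m) {
    if (inherits(m, "thresholded_map")) significant_mask(m, tier, sign)
    else if (is.logical(m) && length(dim(m)) == 3) m
    else stop("inputs must be thresholded maps or logical 3-D arrays")
  }
  a <- as_mask(m1); b <- as_mask(m2)
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  a & b
}

#' Dice overlap coefficient
#'
#' `2 |A and B| / (|A| + |B|)`; 1 means identical nonempty masks, 0 means
#' complete separation. When both masks are empty the coefficient is
#' defined as 0 (with a message).
#'
#' @param a,b logical arrays on the same grid.
#' @return numeric in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    message("both masks empty; Dice defined as 0")
    return(0)
  }
  2 * sum(a & b) / (na + nb)
}

#' Apply a multivariate signature pattern to single-trial images
#'
#' Dot product of a voxel weight map with each trial image, yielding one
#' scalar signature response per trial (as when scoring pain-predictive
#' signatures on single-trial betas). Downstream group tests (signature to
#' pain slopes, cue effects on signature responses) go through
#' [fit_multilevel_glm()].
#'
#' @param data trials x voxels matrix of in-mask voxel values.
#' @param pattern weight map: numeric vector over in-mask voxels, or a 3-D
#'   array co-registered with `mask`.
#' @param mask logical 3-D array (required for array patterns).
#' @return numeric vector of per-trial signature responses.
#' @export
score_signature <- function(data, pattern, mask = NULL) {
  data <- as.matrix(data)
  if (length(dim(pattern)) == 3) {
    if (is.null(mask)) stop("mask required for a 3-D pattern")
    pattern <- pattern[mask]
  }
  if (length(pattern) != ncol(data))
    stop("pattern and data grids do not match")
  if (all(pattern == 0)) stop("pattern has no support inside the data mask")
  drop(data %*% pattern)
}
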