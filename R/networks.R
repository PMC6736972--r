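#' Network partition (label atlas)
#'
#' A resting-state-network style partition: an integer label image (0 =
#' unassigned) plus label names.
#'
#' @param labels integer 3-D array.
#' @param names character vector of network names, in label order
#'   (label i = names[i]); every named label must occur in the image.
#' @return object of class `network_partition`.
#' @export
network_partition <- function(labels, names) {
  stopifnot(length(dim(labels)) == 3)
  labels <- array(as.integer(labels), dim(labels))
  present <- sort(unique(labels[labels > 0]))
  if (!all(seq_along(names) %in% present))
    stop("every named label must be present in the label image")
  structure(list(labels = labels, names = as.character(names)),
            class = "network_partition")
}

#' Synthetic blocky network partition
#'
#' Voronoi partition of the grid around randomly placed network centers:
#' contiguous, irregular network territories for testing spatial-decoding
#' code without any atlas download. Optionally, the first labels are
#' forced to coincide with supplied seed masks (e.g., planted voxel
#' populations), so ground-truth "networks" exist.
#'
#' @param dim grid dimensions.
#' @param n_networks number of networks (default 7).
#' @param seed RNG seed.
#' @param seed_masks optional list of logical arrays claimed verbatim by
#'   the first `length(seed_masks)` labels.
#' @return a [network_partition()] with names `net1..netK` (seeded labels
#'   first).
#' @export
synthetic_partition <- function(dim, n_networks = 7, seed = 1L,
                                seed_masks = NULL) {
  set.seed(as.integer(seed))
  coords <- as.matrix(expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                                  z = seq_len(dim[3])))
  n_seeded <- length(seed_masks)
  n_free <- n_networks - n_seeded
  stopifnot(n_free >= 1)
  centers <- coords[sample.int(nrow(coords), n_free), , drop = FALSE]
  d2 <- sapply(seq_len(n_free), function(i)
    rowSums(sweep(coords, 2, centers[i, ])^2))
  lab <- array(n_seeded + max.col(-d2), dim)
  if (n_seeded > 0) {
    for (i in seq_len(n_seeded)) lab[seed_masks[[i]]] <- i
  }
  network_partition(lab, paste0("net", seq_len(n_networks)))
}

#' @noRd
map_values <- function(map, tier = "p05") {
  if (inherits(map, "stat_map")) {
    out <- array(0, map$dim)
    out[map$mask] <- map$estimate
    out
  } else if (inherits(map, "thresholded_map")) {
    keep <- significant_mask(map, tier)
    out <- array(0, map$dim)
    est <- array(0, map$dim)
    est[map$mask] <- map$estimate
    out[keep] <- est[keep]
    out
  } else if (is.numeric(map) && length(dim(map)) == 3) {
    map
  } else stop("unsupported map type")
}

#' Spatial similarity of a map with each network (wedge profile)
#'
#' Pearson correlation, over in-mask voxels, between a map's voxel values
#' and the binary indicator of each network. For thresholded maps the
#' values are the signed effect estimates zeroed outside the surviving
#' tiers. The wedge display convention is radius proportional to r (and
#' area to r squared); negative correlations get zero radius with the sign
#' kept in the `r` column.
#'
#' @param map a `stat_map`, `thresholded_map`, or 3-D numeric array.
#' @param partition a [network_partition()].
#' @param mask logical 3-D array of analysis voxels (default: all).
#' @param tier tier used for thresholded maps.
#' @return data frame: network, r, radius.
#' @export
network_similarity <- function(map, partition, mask = NULL, tier = "p05") {
  vals <- map_values(map, tier)
  if (is.null(mask))
    mask <- if (inherits(map, c("stat_map", "thresholded_map")))
      map$mask else array(TRUE, dim(vals))
  if (!identical(dim(vals), dim(partition$labels))) stop("grid mismatch")
  v <- vals[mask]
  labs <- partition$labels[mask]
  if (stats::sd(v) == 0) {
    message("constant map; similarity undefined")
    return(data.frame(network = partition$names, r = NA_real_,
                      radius = NA_real_))
  }
  r <- vapply(seq_along(partition$names), function(i)
    stats::cor(v, as.numeric(labs == i)), numeric(1))
  data.frame(network = partition$names, r = r, radius = pmax(r, 0))
}

#' Z-scored subnetwork contrast between two cue models
#'
#' For each subject, the unthresholded path-a beta map of each model is
#' z-scored across in-mask voxels; mean activation is computed per network
#' label; and the two models are compared with a paired t test per label
#' (plus a whole-partition row pooling all labeled voxels). Z-scoring makes
#' the contrast invariant to per-subject affine rescaling of the raw maps.
#'
#' @param subject_maps1,subject_maps2 subjects x voxels matrices of
#'   unthresholded subject-level betas (e.g., path a for Social and CS).
#' @param partition a [network_partition()].
#' @param mask logical 3-D array aligning voxel columns with the grid.
#' @param labels optional subset of network names to test.
#' @return data frame of [group_effect()] rows (one per network, the
#'   difference model1 - model2), with a leading `whole` row.
#' @export
subnetwork_contrast <- function(subject_maps1, subject_maps2, partition,
                                mask, labels = partition$names) {
  A <- as.matrix(subject_maps1)
  B <- as.matrix(subject_maps2)
  stopifnot(identical(dim(A), dim(B)), ncol(A) == sum(mask))
  zrow <- function(M) t(apply(M, 1, function(v) (v - mean(v)) / stats::sd(v)))
  Az <- zrow(A); Bz <- zrow(B)
  labs <- partition$labels[mask]
  rows <- list()
  all_idx <- labs %in% match(labels, partition$names)
  if (sum(all_idx) > 0) {
    d <- rowMeans(Az[, all_idx, drop = FALSE]) -
      rowMeans(Bz[, all_idx, drop = FALSE])
    rows[["whole"]] <- group_effect(d, label = "whole")
  }
  for (nm in labels) {
    i <- which(labs == match(nm, partition$names))
    if (length(i) == 0) {
      warning("network ", nm, " empty inside mask; skipped")
      next
    }
    d <- rowMeans(Az[, i, drop = FALSE]) - rowMeans(Bz[, i, drop = FALSE])
    rows[[nm]] <- group_effect(d, label = nm)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  names(res)[names(res) == "predictor"] <- "network"
  res
}

#' Classify points of the (Social, CS) effect plane into octants
#'
#' The plane of per-voxel Social (x) and CS (y) mediation weights is
#' divided into eight 45-degree sectors numbered clockwise from the +y
#' axis: octant 1 is centered on +y (uniquely CS-positive), 2 on the x=y
#' diagonal (shared positive), 3 on +x (uniquely Social-positive), 4 on
#' x=-y, 5 on -y, 6 on -x=-y (shared negative), 7 on -x, 8 on y=-x
#' (CS-positive with Social suppression). Sector boundaries lie at odd
#' multiples of 22.5 degrees and each sector is half-open (it contains its
#' lower-angle boundary and excludes the upper), so classification is total and
#' deterministic; the origin maps to NA.
#'
#' @param x,y numeric vectors (Social and CS effects).
#' @return integer vector of octants 1-8 (NA at the origin).
#' @export
octant_classify <- function(x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  stopifnot(length(x) == length(y))
  theta <- atan2(y, x) * 180 / pi  # (-180, 180]
  theta <- theta %% 360
  m <- floor((theta - 67.5) / 45)
  k <- ((-m) %% 8) + 1L
  k[x == 0 & y == 0] <- NA_integer_
  as.integer(k)
}

#' Octant counts and SSD per network
#'
#' Classifies every voxel by its (Social, CS) mediation weights and
#' accumulates, per network and octant, the voxel count and the sum of
#' squared distances from the origin (SSD = sum of x^2 + y^2), the
#' magnitude-weighted summary of each octant's contribution.
#'
#' @param social_map,cs_map unthresholded voxelwise effect values:
#'   `stat_map`s, 3-D arrays, or plain vectors over in-mask voxels.
#' @param partition optional [network_partition()]; when NULL all voxels
#'   form one "all" network.
#' @param mask logical 3-D array (defaults to the stat maps' mask).
#' @return data frame: network, octant (1-8), n, ssd; attribute `peak`
#'   gives the peak-SSD octant per network.
#' @export
octant_summary <- function(social_map, cs_map, partition = NULL,
                           mask = NULL) {
  get_vec <- function(m) {
    if (inherits(m, "stat_map")) m$estimate
    else if (length(dim(m)) == 3) m[if (is.null(mask))
      array(TRUE, dim(m)) else mask]
    else as.numeric(m)
  }
  if (is.null(mask) && inherits(social_map, "stat_map"))
    mask <- social_map$mask
  xv <- get_vec(social_map)
  yv <- get_vec(cs_map)
  if (length(xv) != length(yv)) stop("grid mismatch")
  labs <- if (is.null(partition)) rep(1L, length(xv))
  else partition$labels[if (is.null(mask))
    array(TRUE, dim(partition$labels)) else mask]
  nm <- if (is.null(partition)) "all" else partition$names
  oc <- octant_classify(xv, yv)
  ss <- xv^2 + yv^2
  rows <- list()
  for (i in seq_along(nm)) {
    sel <- labs == i & !is.na(oc)
    cnt <- tabulate(oc[sel], 8)
    ssd <- vapply(1:8, function(k) sum(ss[sel][oc[sel] == k]), numeric(1))
    rows[[nm[i]]] <- data.frame(network = nm[i], octant = 1:8,
                                n = cnt, ssd = ssd)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  peak <- vapply(split(res, res$network),
                 function(d) d$octant[which.max(d$ssd)], numeric(1))
  attr(res, "peak") <- peak
  res
}

#' Decode a map against a stack of term maps
#'
#' Pearson correlation of a map with each named term map (e.g.,
#' meta-analytic association z-maps), returning the `k` most positively
#' correlated unique terms (uniqueness = distinct lowercased names) in
#' descending order of r.
#'
#' @param map a `stat_map`, `thresholded_map`, 3-D array, or vector over
#'   in-mask voxels.
#' @param terms named list of 3-D arrays (or a voxels x terms matrix with
#'   column names) co-registered with the map.
#' @param k number of terms to return (default 10); if `k` exceeds the
#'   number of unique terms, all are returned with a warning.
#' @param mask logical 3-D array.
#' @param tier tier for thresholded maps.
#' @return data frame: term, r (descending).
#' @export
term_decode <- function(map, terms, k = 10, mask = NULL, tier = "p05") {
  if (inherits(map, c("stat_map", "thresholded_map"))) {
    if (is.null(mask)) mask <- map$mask
    v <- map_values(map, tier)[mask]
  } else if (length(dim(map)) == 3) {
    if (is.null(mask)) mask <- array(TRUE, dim(map))
    v <- map[mask]
  } else v <- as.numeric(map)
  if (is.list(terms)) {
    T <- sapply(terms, function(tm) if (length(dim(tm)) == 3) tm[mask]
                else as.numeric(tm))
  } else T <- as.matrix(terms)
  if (nrow(T) != length(v)) stop("term maps not co-registered with map")
  r <- drop(stats::cor(v, T))
  df <- data.frame(term = colnames(T), r = r)
  df <- df[order(-df$r), , drop = FALSE]
  df <- df[!duplicated(tolower(df$term)), , drop = FALSE]
  if (k > nrow(df)) {
    warning("k exceeds the number of unique terms; returning all")
    k <- nrow(df)
  }
  out <- utils::head(df, k)
  rownames(out) <- NULL
  out
}
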