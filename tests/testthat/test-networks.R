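test_that("a network's own indicator has r = 1 with itself, negative elsewhere", {
  set.seed(1)
  part <- synthetic_partition(c(8, 8, 8), n_networks = 4, seed = 2)
  ind <- array(as.numeric(part$labels == 2), dim(part$labels))
  ws <- network_similarity(ind, part)
  expect_equal(ws$r[ws$network == "net2"], 1, tolerance = 1e-10)
  expect_true(all(ws$r[ws$network != "net2"] < 0))
  expect_equal(ws$radius[ws$network != "net2"], rep(0, 3))
})

test_that("a constant map yields missing similarity, not an error", {
  part <- synthetic_partition(c(6, 6, 6), n_networks = 3, seed = 3)
  expect_message(ws <- network_similarity(array(1, c(6, 6, 6)), part),
                 "constant map")
  expect_true(all(is.na(ws$r)))
})

test_that("the planted mediator map is most similar to its own network label", {
  synth <- smoke_experiment()
  br <- synth$brain
  part <- synthetic_partition(dim(br$mask), 6, seed = 4,
                              seed_masks = list(br$labels == 1,
                                                br$labels == 2))
  vm <- voxelwise_mediation(br, n_boot = 500, seed = 5)
  ws <- network_similarity(map_to_array(vm$maps$ab, fill = 0), part,
                           br$mask)
  expect_equal(ws$network[which.max(ws$r)], "net1")
})

test_that("octant classification agrees with an angle-based reference", {
  # independent oracle: explicit sector intervals in standard angle
  oracle <- function(x, y) {
    th <- (atan2(y, x) * 180 / pi) %% 360
    centers <- (90 - 45 * (0:7)) %% 360
    k <- rep(NA_integer_, length(th))
    for (i in 1:8) {
      lo <- (centers[i] - 22.5) %% 360
      hi <- (centers[i] + 22.5) %% 360
      inside <- if (lo < hi) th >= lo & th < hi else th >= lo | th < hi
      k[inside] <- i
    }
    k[x == 0 & y == 0] <- NA_integer_
    k
  }
  set.seed(6)
  x <- c(rnorm(1e5), 0, 1, 1, 1, 0, -1, -1, -1)
  y <- c(rnorm(1e5), 1, 1, 0, -1, -1, -1, 0, 1)
  # boundary points at odd multiples of 22.5 degrees
  bth <- (seq(22.5, 337.5, by = 45)) * pi / 180
  x <- c(x, cos(bth)); y <- c(y, sin(bth))
  expect_identical(octant_classify(x, y), oracle(x, y))
  expect_true(is.na(octant_classify(0, 0)))
  expect_error(octant_classify(Inf, 1), "non-finite")
})

test_that("the caption mapping of octants holds", {
  expect_equal(octant_classify(0, 1), 1L)    # CS-positive only
  expect_equal(octant_classify(1, 1), 2L)    # shared positive
  expect_equal(octant_classify(1, 0), 3L)    # Social-positive only
  expect_equal(octant_classify(-1, 1), 8L)   # CS positive, Social negative
  expect_equal(octant_classify(1, -1), 4L)   # Social positive, CS negative
  expect_equal(octant_classify(0, -1), 5L)
  expect_equal(octant_classify(-1, -1), 6L)
  expect_equal(octant_classify(-1, 0), 7L)
})

test_that("octant SSD accounting is exact and symmetric clouds are uniform", {
  # all voxels at (1, 1): everything in octant 2, SSD = 2n
  n <- 50
  os <- octant_summary(rep(1, n), rep(1, n))
  expect_equal(os$n[os$octant == 2], n)
  expect_equal(os$ssd[os$octant == 2], 2 * n)
  expect_equal(sum(os$n), n)
  # SSD sums to the total squared distance over classified voxels
  set.seed(7)
  x <- rnorm(5000); y <- rnorm(5000)
  os2 <- octant_summary(x, y)
  expect_equal(sum(os2$ssd), sum(x^2 + y^2), tolerance = 1e-10)
  expect_equal(unname(chisq.test(os2$n)$p.value) > 1e-3, TRUE)
  # a CS-only cloud peaks in octant 1
  os3 <- octant_summary(rnorm(2000, 0, 0.05), rnorm(2000, 1), )
  expect_equal(unname(attr(os3, "peak")["all"]), 1)
})

test_that("per-network octant summaries respect the partition", {
  synth <- smoke_experiment()
  br <- synth$brain
  part <- synthetic_partition(dim(br$mask), 5, seed = 8,
                              seed_masks = list(br$labels == 1,
                                                br$labels == 2))
  vm_s <- voxelwise_mediation(br, x = "social", n_boot = 200, seed = 9)
  vm_c <- voxelwise_mediation(br, x = "cs", n_boot = 200, seed = 9)
  os <- octant_summary(vm_s$maps$ab, vm_c$maps$ab, part, br$mask)
  peak <- attr(os, "peak")
  # social-mediator network peaks in the Social-positive octant band
  expect_true(peak["net1"] %in% c(2, 3, 4))
  # CS-mediator network peaks in the CS-positive octant band
  expect_true(peak["net2"] %in% c(8, 1, 2))
  expect_equal(sum(os$n[os$network == "net1"]), sum(part$labels == 1))
})

test_that("z-scored subnetwork contrasts detect a planted localized difference", {
  set.seed(10)
  dm <- c(8, 8, 8)
  mask <- array(TRUE, dm)
  part <- synthetic_partition(dm, 4, seed = 11)
  n <- 14; V <- prod(dm)
  A <- matrix(rnorm(n * V), n, V)
  B <- matrix(rnorm(n * V), n, V)
  tgt <- part$labels[mask] == 3
  A[, tgt] <- A[, tgt] + 1.5
  res <- subnetwork_contrast(A, B, part, mask)
  expect_lt(res$p[res$network == "net3"], 0.01)
  expect_gt(res$beta[res$network == "net3"], 0)
  others <- res$network %in% c("net1", "net2", "net4")
  expect_gt(res$beta[res$network == "net3"],
            max(res$beta[others]))  # planted label dominates

  # identical inputs: all contrasts exactly zero (the zero-variance
  # warning from the degenerate group test is the expected behavior)
  res0 <- suppressWarnings(subnetwork_contrast(A, A, part, mask))
  expect_true(all(abs(res0$beta) < 1e-12))

  # z-scoring invariance: per-subject affine rescaling changes nothing
  # (the whole-partition row is excluded: with a partition covering the
  # entire mask its z-scored means are exactly zero, so its t statistic
  # is float noise by construction)
  A2 <- A * 3 + 7
  res2 <- subnetwork_contrast(A2, B, part, mask)
  nets <- res$network != "whole"
  expect_equal(res2$beta[nets], res$beta[nets], tolerance = 1e-10)
  expect_equal(res2$t[nets], res$t[nets], tolerance = 1e-8)
})

test_that("term decoding ranks a planted correlate first", {
  set.seed(12)
  V <- 500
  map <- rnorm(V)
  terms <- sapply(1:15, function(i) rnorm(V))
  colnames(terms) <- paste0("noise", 1:15)
  terms <- cbind(terms, self = map,
                 planted = 0.6 * scale(map)[, 1] + rnorm(V, 0, 0.8))
  td <- term_decode(map, terms, k = 10)
  expect_equal(td$term[1], "self")
  expect_equal(td$r[1], 1, tolerance = 1e-12)
  expect_equal(td$term[2], "planted")
  expect_equal(nrow(td), 10)
  expect_true(all(diff(td$r) <= 0))
  # k = 0 gives an empty list; k too large warns and returns all unique
  expect_equal(nrow(term_decode(map, terms, k = 0)), 0)
  expect_warning(all_t <- term_decode(map, terms, k = 100), "unique")
  expect_equal(nrow(all_t), 17)
  # uniqueness by lowercased name
  terms2 <- cbind(terms, SELF = map)
  expect_equal(sum(grepl("self", tolower(term_decode(map, terms2,
                                                     k = 17)$term))), 1)
})

test_that("a planted correlate at r ~ 0.6 wins over noise terms almost always", {
  set.seed(13)
  wins <- replicate(100, {
    V <- 300
    map <- rnorm(V)
    terms <- sapply(1:20, function(i) rnorm(V))
    colnames(terms) <- paste0("noise", 1:20)
    terms <- cbind(terms,
                   planted = 0.6 * scale(map)[, 1] +
                     rnorm(V, 0, sqrt(1 - 0.36)))
    term_decode(map, terms, k = 1)$term == "planted"
  })
  expect_gt(mean(wins), 0.95)
})

test_that("empty subnetworks are skipped with a warning", {
  dm <- c(6, 6, 6)
  part <- synthetic_partition(dm, 3, seed = 14)
  mask <- part$labels != 2  # hide network 2 entirely
  A <- matrix(rnorm(5 * sum(mask)), 5)
  B <- matrix(rnorm(5 * sum(mask)), 5)
  expect_warning(res <- subnetwork_contrast(A, B, part, mask), "empty")
  expect_false("net2" %in% res$network)
})
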