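test_that("vectorized voxelwise paths equal the per-voxel estimator", {
  set.seed(1)
  n <- 30; V <- 8
  x <- rep(c(-1, 1), 15)
  cv <- rnorm(n)
  M <- matrix(rnorm(n * V), n, V)
  y <- rnorm(n)
  fast <- voxelwise_subject_paths(M, x, y, cv)
  for (v in 1:V) {
    slow <- fit_subject_paths(x, M[, v], y, cv)
    expect_equal(fast$a[v], unname(slow["a"]), tolerance = 1e-10)
    expect_equal(fast$b[v], unname(slow["b"]), tolerance = 1e-10)
    expect_equal(fast$ab[v], unname(slow["ab"]), tolerance = 1e-10)
    expect_equal(fast$cprime[v], unname(slow["cprime"]), tolerance = 1e-10)
  }
})

test_that("planted populations light up the correct paths", {
  synth <- smoke_experiment()
  br <- synth$brain
  labs <- br$labels[br$mask]
  vm_soc <- voxelwise_mediation(br, seed = 5, method = "ttest")
  th <- fdr_threshold(vm_soc$maps[c("a", "b", "ab")], q = 0.05)
  hit_ab <- significant_mask(th$ab, "p05")[br$mask]
  hit_a <- significant_mask(th$a, "fdr")[br$mask]
  hit_b <- significant_mask(th$b, "fdr")[br$mask]
  # social mediators: strong path a at FDR; mediation ab detectable at
  # the lenient display tier at this reduced cohort size (full-power FDR
  # detection of ab is exercised at the 36-subject design scale in the
  # calibration suite); null region mostly silent
  expect_gt(mean(hit_a[labs == 1]), 0.9)
  expect_gt(mean(hit_ab[labs == 1]), 0.5)
  expect_lt(mean(hit_ab[labs == 0]), 0.07)
  expect_lt(mean(significant_mask(th$ab, "fdr")[br$mask][labs == 0]), 0.01)
  # pain-only voxels: path b without path a
  expect_gt(mean(hit_b[labs == 3]), 0.8)
  expect_lt(mean(hit_a[labs == 3]), 0.05)
})

test_that("shuffling cue labels destroys path a but not path b in pain-only voxels", {
  synth <- smoke_experiment()
  br <- synth$brain
  labs <- br$labels[br$mask]
  trials <- br$trials
  set.seed(8)
  for (s in unique(trials$subject)) {
    i <- which(trials$subject == s)
    trials$social[i] <- sample(trials$social[i])
  }
  vm <- voxelwise_mediation(br, trials = trials, seed = 5, method = "ttest")
  th <- fdr_threshold(vm$maps[c("a", "b", "ab")], q = 0.05)
  hit_a <- significant_mask(th$a, "fdr")[br$mask]
  hit_b <- significant_mask(th$b, "fdr")[br$mask]
  expect_lt(mean(hit_a[labs == 1]), 0.1)   # path a destroyed
  expect_gt(mean(hit_b[labs == 3]), 0.8)   # path b preserved
})

test_that("zero-variance voxels get p = 1 and are flagged", {
  synth <- smoke_experiment()
  br <- synth$brain
  br$datasets <- lapply(br$datasets, function(m) { m[, 1] <- 0; m })
  expect_message(vm <- voxelwise_mediation(br, n_boot = 200, seed = 2),
                 "zero variance")
  expect_equal(vm$n_flagged, 1L)
  expect_equal(vm$maps$ab$p[1], 1)
})

test_that("BH equals the brute-force step-up rule and p.adjust", {
  brute_bh <- function(p, q) {
    m <- length(p)
    ps <- sort(p)
    k <- 0
    for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
    if (k == 0) rep(FALSE, m) else p <= ps[k]
  }
  set.seed(2)
  for (m in 1:20) {
    for (rep in 1:20) {
      p <- runif(m)^sample(c(1, 2, 4), 1)
      got <- bh_threshold(p, 0.05)
      expect_identical(got$reject, brute_bh(p, 0.05))
      expect_identical(got$reject, p.adjust(p, "BH") <= 0.05 + 1e-12)
    }
  }
  # the worked step-up example: all four pass at q = 0.05
  ex <- bh_threshold(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(ex$reject))
  expect_equal(ex$cutoff, 0.04)
  expect_false(any(bh_threshold(rep(1, 10), 0.05)$reject))
  expect_error(bh_threshold(numeric(0)), "empty")
  expect_error(bh_threshold(c(0.5, 2)), "invalid")
})

test_that("uniform null p-values keep the realized FDR at or below q", {
  set.seed(3)
  fdp <- replicate(500, {
    p <- runif(200)
    rej <- bh_threshold(p, 0.05)$reject
    if (sum(rej) == 0) 0 else 1  # every rejection is false under the null
  })
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
})

test_that("tiers are nested and pooling changes the family as documented", {
  synth <- smoke_experiment()
  vm <- voxelwise_mediation(synth$brain, seed = 4, method = "ttest")
  th <- fdr_threshold(vm$maps[c("a", "b", "ab")], q = 0.05,
                      pool_paths = TRUE)
  for (t1 in th) {
    i_fdr <- t1$tier == "fdr"
    i_p01 <- t1$tier %in% c("fdr", "p01")
    i_p05 <- t1$tier %in% c("fdr", "p01", "p05")
    expect_true(all(t1$p[i_fdr] <= max(t1$cutoff, min(t1$p))))
    expect_true(all(t1$p[t1$tier == "p01"] < 0.01))
    expect_true(all(t1$p[t1$tier == "p05"] < 0.05))
    expect_true(sum(i_fdr) <= sum(i_p01), sum(i_p01) <= sum(i_p05))
  }
  th_sep <- fdr_threshold(vm$maps[c("a", "b", "ab")], q = 0.05,
                          pool_paths = FALSE)
  expect_false(identical(th$a$cutoff, th_sep$ab$cutoff))
})

test_that("connected components respect the chosen connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE  # touches only diagonally
  l6 <- label_components(m, 6)
  l26 <- label_components(m, 26)
  expect_equal(max(l6), 2L)
  expect_equal(max(l26), 1L)
  # a solid block is one component either way
  b <- array(FALSE, c(5, 5, 5)); b[2:4, 2:4, 2:4] <- TRUE
  expect_equal(max(label_components(b, 6)), 1L)
})

test_that("display pruning keeps only lenient clusters touching FDR voxels", {
  dm <- c(10, 10, 3)
  mask <- array(TRUE, dm)
  p <- rep(0.5, prod(dm))
  arr <- array(seq_len(prod(dm)), dm)
  # cluster A: an FDR core with a lenient shell
  core <- arr[2, 2, 2]
  shellA <- c(arr[1:3, 1:3, 1:3])
  # cluster B: lenient blob far away, no FDR voxel
  blobB <- c(arr[7:9, 7:9, 2])
  p[shellA] <- 0.04
  p[blobB] <- 0.04
  p[core] <- 1e-6
  sm <- structure(list(estimate = rep(1, prod(dm)), p = p, mask = mask,
                       dim = dm, path = "ab", model = "social"),
                  class = "stat_map")
  th <- fdr_threshold(sm, q = 0.05, pool_paths = FALSE)
  pruned <- prune_display(th)
  keep <- significant_mask(pruned, "p05")
  expect_true(all(keep[arrayInd(shellA, dm)]))   # retained fully
  expect_false(any(keep[arrayInd(blobB, dm)]))   # dropped
  expect_true(keep[2, 2, 2])                     # FDR voxel never removed
  # diagonal-touching blob: retained under 26- but not 6-connectivity
  p2 <- p
  p2[arr[4, 4, 4 - 1]] <- 0.04  # diagonal neighbor of the 3x3x3 shell corner
  sm2 <- sm; sm2$p <- p2
  th2 <- fdr_threshold(sm2, q = 0.05, pool_paths = FALSE)
  k26 <- significant_mask(prune_display(th2, 26), "p05")
  k6 <- significant_mask(prune_display(th2, 6), "p05")
  expect_true(k26[4, 4, 3])
  expect_false(k6[4, 4, 3])
})

test_that("conjunction obeys idempotence, disjointness and inclusion", {
  set.seed(5)
  a <- array(runif(27) < 0.4, c(3, 3, 3))
  b <- array(runif(27) < 0.4, c(3, 3, 3))
  expect_identical(conjunction(a, a), a)
  expect_false(any(conjunction(a, a & !a)))
  cj <- conjunction(a, b)
  expect_true(all(cj[a & b]) && !any(cj & !a) && !any(cj & !b))
  expect_error(conjunction(a, array(TRUE, c(2, 2, 2))), "grid mismatch")
})

test_that("Dice matches the hand formula and conventions", {
  A <- array(FALSE, c(3, 3, 3)); B <- A
  A[1:4] <- TRUE
  B[3:8] <- TRUE  # |A| = 4, |B| = 6, overlap = 2
  expect_equal(dice(A, B), 2 * 2 / (4 + 6))
  expect_equal(dice(A, A), 1)
  expect_equal(dice(A, !A & FALSE), 0)
  expect_equal(dice(B, A), dice(A, B))
  expect_message(z <- dice(A & FALSE, B & FALSE), "both masks empty")
  expect_equal(z, 0)
})

test_that("signature scoring is a dot product with sane errors", {
  set.seed(6)
  data <- matrix(rnorm(5 * 10), 5, 10)
  onehot <- c(1, rep(0, 9))
  expect_equal(score_signature(data, onehot), data[, 1])
  # orthogonal pattern: centered data column space
  w <- rep(1, 10)
  dc <- sweep(data, 1, rowMeans(data) * 10 / 10)  # not orthogonal per se
  expect_equal(score_signature(data, w), rowSums(data))
  expect_error(score_signature(data, rep(0, 10)), "no support")
  expect_error(score_signature(data, rep(1, 4)), "do not match")
})

test_that("a planted b-weight signature tracks pain", {
  synth <- smoke_experiment()
  br <- synth$brain
  pattern <- as.numeric(br$labels[br$mask] == 3) /
    sum(br$labels[br$mask] == 3)
  st <- br$trials
  st$sig <- NA_real_
  ids <- sort(unique(st$subject))
  for (k in seq_along(ids)) {
    rows <- st$subject == ids[k]
    st$sig[rows] <- score_signature(br$datasets[[k]], pattern)
  }
  fit <- fit_multilevel_glm(st, "pain", "sig", subset = temp_code == 0)
  expect_gt(fit$beta, 0)
  expect_lt(fit$p, 0.01)
})
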