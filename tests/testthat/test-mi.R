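test_that("grid counting uses half-open squares and conserves totals", {
  gc <- grid_counts(matrix(c(5, 5), 1), sigma = 10, origin = c(0, 0))
  expect_equal(sum(gc$counts), 1)
  expect_equal(gc$counts[1, 1], 1)
  # a point exactly on an edge goes to the higher-index square
  gc2 <- grid_counts(matrix(c(10, 0), 1), sigma = 10, origin = c(0, 0),
                     dims = c(3, 1))
  expect_equal(gc2$counts[2, 1], 1)
  expect_equal(gc2$counts[1, 1], 0)
  set.seed(61)
  pts <- cbind(runif(100, 0, 80), runif(100, 0, 60))
  expect_equal(sum(grid_counts(pts, 10)$counts), 100)
})

test_that("quantile binning follows the inf-CDF threshold definition", {
  # counts {0,0,1,1}, q = 2 -> thresholds (0, 1), bins {1,1,2,2}
  qb <- quantile_bin(matrix(c(0, 0, 1, 1), 2), q = 2)
  expect_equal(qb$thresholds, c(0, 1))
  expect_equal(sort(as.numeric(qb$bins)), c(1, 1, 2, 2))
  # constant field: every threshold equals the value, all bins = q
  qc <- quantile_bin(matrix(7, 3, 3), q = 5)
  expect_true(all(qc$bins == 5))
  # binned value is non-decreasing in the raw count
  set.seed(62)
  m <- matrix(rpois(64, 3), 8)
  qb2 <- quantile_bin(m, q = 4)
  o <- order(as.numeric(m))
  expect_true(all(diff(as.numeric(qb2$bins)[o]) >= 0))
})

test_that("the conditional MI score matches exhaustive enumeration of draws", {
  # one megasquare, K = 1, left column bin 1 / right column bin 2
  b <- matrix(c(1, 1, 2, 2), 2)   # rows = x index, cols = y index
  sc <- mi_score(b, megasquare_scheme(K = 1))
  expect_equal(sc$mi, naive_mi(b, 1), tolerance = 1e-12)
  # one split direction determines M exactly, the other is uninformative:
  # I = (1/2) log 2 over the direction mixture
  expect_equal(sc$mi, 0.5 * log(2), tolerance = 1e-12)
  # random grids against the brute-force oracle
  for (seed in 1:3) {
    set.seed(seed)
    bg <- matrix(sample(1:3, 36, TRUE), 6)
    expect_equal(mi_score(bg, megasquare_scheme(K = 2))$mi,
                 naive_mi(bg, 2), tolerance = 1e-12)
  }
  # support masking matches the oracle's masked enumeration
  set.seed(9)
  bg <- matrix(sample(1:2, 36, TRUE), 6)
  sup <- matrix(TRUE, 6, 6); sup[1:3, 1:3] <- FALSE
  expect_equal(mi_score(bg, megasquare_scheme(K = 2), support = sup)$mi,
               naive_mi(bg, 2, support = sup), tolerance = 1e-12)
  # constant field scores exactly zero; non-negativity in general
  expect_identical(mi_score(matrix(4, 8, 8), megasquare_scheme(K = 2))$mi, 0)
  expect_gte(mi_score(bg, megasquare_scheme(K = 2))$mi, 0)
  expect_error(mi_score(matrix(1, 2, 2), megasquare_scheme(K = 4)), "megasquare")
})

test_that("spatially organized features outscore scattered ones with matched marginals", {
  set.seed(63)
  n <- 608
  # striped: expressed homogeneously in the left half only (jittered lattice,
  # 19 detections per occupied square); scattered: same count, uniform
  sq <- expand.grid(i = 0:3, j = 0:7)
  left <- cbind(rep(sq$i * 50, each = 19) + runif(n, 2, 48),
                rep(sq$j * 50, each = 19) + runif(n, 2, 48))
  pts <- rbind(data.frame(x = left[, 1], y = left[, 2], feature = "striped"),
               data.frame(x = runif(n, 0, 400), y = runif(n, 0, 400),
                          feature = "scattered"))
  sc <- mi_feature_scores(pts, sigma = 50, q = 4, scheme = megasquare_scheme(K = 4))
  expect_gt(sc$total[sc$feature == "striped"], sc$total[sc$feature == "scattered"])
  expect_equal(rank_and_select(sc, 1), "striped")
  # permuting square positions destroys the striped structure
  gcs <- grid_counts(left, sigma = 50, origin = c(0, 0), dims = c(8, 8))
  orig <- mi_score(quantile_bin(gcs, 4), megasquare_scheme(K = 4))$mi
  perm <- gcs
  set.seed(64)
  perm$counts[] <- sample(gcs$counts)
  shuf <- mi_score(quantile_bin(perm, 4), megasquare_scheme(K = 4))$mi
  expect_gt(orig, shuf)
})

test_that("selection is greedy by total score with lexicographic ties", {
  sc <- data.frame(feature = c("a", "b", "c"), total = c(3, 1, 2))
  expect_equal(rank_and_select(sc, 2), c("a", "c"))
  tie <- data.frame(feature = c("z", "m", "a"), total = c(1, 1, 1))
  expect_equal(rank_and_select(tie, 3), c("a", "m", "z"))
  expect_error(rank_and_select(sc, 5), "exceeds")
  # full ordering consistent with pairwise comparisons
  set.seed(65)
  sc2 <- data.frame(feature = letters[1:6], total = runif(6))
  r <- rank_and_select(sc2, 6)
  expect_equal(r, sc2$feature[order(-sc2$total, sc2$feature)])
  # decoy flagging in the score table
  pts <- data.frame(x = runif(500, 0, 400), y = runif(500, 0, 400),
                    feature = sample(c("BLANK-1", "geneA"), 500, TRUE))
  tab <- mi_feature_scores(pts, sigma = 50, q = 3, scheme = megasquare_scheme(K = 2))
  expect_true(tab$decoy[tab$feature == "BLANK-1"])
  expect_false(tab$decoy[tab$feature == "geneA"])
})
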