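striped_toy <- function(n = 300, band = 10, extent = c(120, 60), seed = 3) {
  set.seed(seed)
  fs <- feature_space(c("a", "b"))
  pos <- cbind(runif(n, 0, extent[1]), runif(n, 0, extent[2]), 0)
  stripe <- (floor(pos[, 1] / band) %% 2) + 1
  probs <- matrix(0, n, 2); probs[cbind(seq_len(n), stripe)] <- 1
  particle_measure(pos, rep(1, n), probs, fs)
}

test_that("lattice initialization aggregates cube mass with uniform features", {
  fs <- feature_space(c("a", "b"))
  # all particles inside one cube -> single particle, summed mass, uniform p
  mu <- particle_measure(cbind(c(1, 2, 3), 1, 0), c(1, 2, 3),
                         matrix(c(1, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE), fs)
  ini <- init_lattice(mu, approx_config(sigma = 10, seed = 1))
  expect_equal(n_particles(ini), 1L)
  expect_equal(ini$weights, 6)
  expect_equal(ini$feature_probs[1, ], c(a = 0.5, b = 0.5), ignore_attr = TRUE)
  # 2x2 block toy: per-cube weights equal per-cube count sums (points stay
  # clear of cube boundaries so the min-anchored lattice keeps them apart)
  set.seed(19)
  pts <- rbind(cbind(runif(5, 2, 8), runif(5, 2, 8)),
               cbind(runif(3, 12, 18), runif(3, 2, 8)),
               cbind(runif(7, 2, 8), runif(7, 12, 18)))
  pts[1, ] <- c(2, 2)                     # pin the anchor
  mu2 <- particle_measure(cbind(pts, 0), rep(1, 15),
                          matrix(0.5, 15, 2), fs)
  ini2 <- init_lattice(mu2, approx_config(sigma = 10, seed = 2))
  expect_equal(n_particles(ini2), 3L)        # empty cube contributes nothing
  expect_equal(sort(ini2$weights), c(3, 5, 7))
  expect_equal(total_mass(ini2), total_mass(mu2))
})

test_that("optimized approximation descends and resolves local feature mixtures", {
  mu <- striped_toy()
  cfg <- approx_config(sigma = 20, stage_iters = 150, seed = 7)
  res <- optimize_approximation(mu, cfg)
  expect_true(all(diff(res$distance_trace) <= 0))
  expect_lt(utils::tail(res$distance_trace, 1), res$distance_trace[1])
  expect_true(all(res$approx$weights >= 0))
  expect_equal(rowSums(res$approx$feature_probs), rep(1, n_particles(res$approx)))
  # stripes are narrower than sigma: reduced particles carry non-uniform
  # mixtures near the local 50/50 band proportions
  pa <- res$approx$feature_probs[, 1]
  expect_lt(max(abs(colMeans(res$approx$feature_probs) - 0.5)), 0.05)
  # a measure already at one particle per lattice cube is a near-fixed point
  set.seed(23)
  fs <- feature_space(c("a", "b"))
  gl <- as.matrix(expand.grid(0:4, 0:3))
  pl <- runif(20)
  lat <- particle_measure(cbind(gl * 20 + 5, 0), runif(20, 0.5, 2),
                          cbind(pl, 1 - pl), fs)
  resc <- optimize_approximation(lat, approx_config(20, 200, seed = 1))
  expect_lt(utils::tail(resc$distance_trace, 1),
            1e-6 * inner_product(lat, lat, kernel_spec(20)))
  # identical seed gives identical results
  res2 <- optimize_approximation(mu, cfg)
  expect_identical(res$approx$positions, res2$approx$positions)
  expect_identical(res$approx$weights, res2$approx$weights)
})

test_that("the optimized approximation beats k-means and grid baselines", {
  mu <- striped_toy()
  metric <- kernel_spec(20)
  res <- optimize_approximation(mu, approx_config(20, 150, seed = 7))
  dopt <- norm_distance_sq(res$approx, mu, metric)
  km <- kmeans_baseline(mu, n_particles(res$approx), seed = 7)
  gb <- grid_baseline(mu, 20)
  expect_lt(dopt, norm_distance_sq(km, mu, metric))
  expect_lt(dopt, norm_distance_sq(gb, mu, metric))
  # k-means contracts: K = N reproduces the measure up to reordering
  small <- subset_particles(mu, 1:12)
  kmN <- kmeans_baseline(small, 12, seed = 1)
  o <- order(kmN$positions[, 1], kmN$positions[, 2])
  oo <- order(small$positions[, 1], small$positions[, 2])
  expect_equal(kmN$positions[o, ], small$positions[oo, ], tolerance = 1e-8)
  # K = 1 centroid is the weighted mean
  km1 <- kmeans_baseline(small, 1, seed = 1)
  expect_equal(as.numeric(km1$positions), colMeans(small$positions),
               tolerance = 1e-6)
  # grid baseline conserves mass
  expect_equal(total_mass(gb), total_mass(mu), tolerance = 1e-8 * total_mass(mu))
})

test_that("finer scales approximate better and truncation is numerically exact", {
  mu <- striped_toy(n = 250)
  d_at <- function(s) {
    r <- optimize_approximation(mu, approx_config(s, 120, seed = 5))
    norm_distance_sq(r$approx, mu, kernel_spec(s))
  }
  # distances are not directly comparable across metrics; compare in a fixed
  # metric at the coarser scale
  r30 <- optimize_approximation(mu, approx_config(30, 120, seed = 5))
  r15 <- optimize_approximation(mu, approx_config(15, 120, seed = 5))
  metric <- kernel_spec(30)
  expect_lte(norm_distance_sq(r15$approx, mu, metric),
             norm_distance_sq(r30$approx, mu, metric))
  # truncated kernel sums match untruncated within 1e-6 relative at radius 4
  # when the data's long-range pairs sit beyond the Gaussian tail (clustered
  # support); on fully spread data the discarded tail is O(exp(-8)) per pair
  set.seed(77)
  cl <- rbind(cbind(runif(60, 0, 30), runif(60, 0, 30), 0),
              cbind(runif(60, 160, 190), runif(60, 0, 30), 0))
  qcl <- runif(120)
  mucl <- particle_measure(cl, rep(1, 120), cbind(qcl, 1 - qcl),
                           feature_space(c("a", "b")))
  k_ex <- kernel_spec(20)
  k_tr <- kernel_spec(20, truncation = 4)
  v_ex <- inner_product(mucl, mucl, k_ex)
  expect_lt(abs(inner_product(mucl, mucl, k_tr) - v_ex) / v_ex, 1e-6)
})

test_that("occupied-cube complexity scales like the ambient dimension", {
  set.seed(71)
  # planar cloud: slope of log(count) vs log(sigma) close to -2
  pos2 <- cbind(runif(6000, 0, 300), runif(6000, 0, 300), 0)
  mu2 <- particle_measure(pos2, rep(1, 6000), matrix(1, 6000, 1),
                          feature_space("a"))
  sig2 <- c(15, 20, 30, 50)
  n2 <- vapply(sig2, function(s)
    n_particles(init_lattice(mu2, approx_config(s, seed = 1))), numeric(1))
  slope2 <- stats::coef(stats::lm(log(n2) ~ log(sig2)))[2]
  expect_lt(abs(slope2 + 2), 0.3)
  # volumetric cloud: slope close to -3
  pos3 <- matrix(runif(60000, 0, 200), ncol = 3)
  mu3 <- particle_measure(pos3, rep(1, 20000), matrix(1, 20000, 1),
                          feature_space("a"))
  sig3 <- c(40, 50, 67, 100)
  n3 <- vapply(sig3, function(s)
    n_particles(init_lattice(mu3, approx_config(s, seed = 1))), numeric(1))
  slope3 <- stats::coef(stats::lm(log(n3) ~ log(sig3)))[2]
  expect_lt(abs(slope3 + 3), 0.3)
})

test_that("block-split approximation covers the input and conserves structure", {
  mu <- striped_toy(n = 280)
  res <- optimize_approximation(mu, approx_config(25, 80, seed = 9, split = 2))
  expect_gt(n_particles(res$approx), 0)
  expect_equal(total_mass(res$approx), total_mass(mu),
               tolerance = 0.1 * total_mass(mu))
  expect_true(all(rowSums(res$approx$feature_probs) - 1 < 1e-8))
})
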