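test_that("inner product matches hand values and the brute-force oracle", {
  fs <- feature_space(c("a", "b", "c"))
  one <- function(pos, f) particle_measure(matrix(pos, 1, 3), 1,
                                           matrix(as.numeric(fs$labels == f), 1), fs)
  k <- kernel_spec(1)
  # coincident particles, identical one-hot feature, unit weight -> k(0) = 1
  expect_equal(inner_product(one(c(0, 0, 0), "a"), one(c(0, 0, 0), "a"), k), 1)
  # disjoint one-hot features kill the feature overlap
  expect_equal(inner_product(one(c(0, 0, 0), "a"), one(c(0, 0, 0), "b"), k), 0)
  # empty measure -> empty sum
  expect_equal(inner_product(one(c(0, 0, 0), "a"), empty_measure(fs), k), 0)

  for (seed in 1:3) {
    mu <- random_measure(5, seed = seed)
    nu <- random_measure(5, seed = seed + 100)
    kk <- kernel_spec(c(1, 2.5), c(1, 0.4))
    v <- inner_product(mu, nu, kk)
    expect_equal(v, naive_inner_product(mu, nu, kk), tolerance = 1e-10)
    expect_equal(v, inner_product(nu, mu, kk))           # symmetry
    expect_equal(inner_product(scale_mass(mu, 2.5), nu, kk), 2.5 * v,
                 tolerance = 1e-12)                      # bilinearity in mass
  }
})

test_that("norm distance is a squared metric with the closed-form two-particle value", {
  fs <- feature_space(c("a", "b"))
  k <- kernel_spec(2)
  for (seed in 1:5) {
    mu <- random_measure(6, nf = 2, seed = seed)
    nu <- random_measure(4, nf = 2, seed = seed + 50)
    expect_lt(norm_distance_sq(mu, mu, k), 1e-10)
    expect_equal(norm_distance_sq(mu, nu, k), norm_distance_sq(nu, mu, k))
    expect_gte(norm_distance_sq(mu, nu, k), 0)
    expect_gte(inner_product(mu, mu, k), 0)
  }
  # two unit particles, identical one-hot features, separation r:
  # d^2 = 2 - 2 exp(-r^2 / (2 sigma^2))
  r <- 3.2; sigma <- 2
  a <- particle_measure(matrix(c(0, 0, 0), 1), 1, matrix(c(1, 0), 1), fs)
  b <- particle_measure(matrix(c(r, 0, 0), 1), 1, matrix(c(1, 0), 1), fs)
  expect_equal(norm_distance_sq(a, b, kernel_spec(sigma)),
               2 - 2 * exp(-r^2 / (2 * sigma^2)), tolerance = 1e-12)
})

test_that("kernel spec validates and evaluates to the amplitude sum at zero", {
  expect_error(kernel_spec(-1), "bandwidths")
  expect_error(kernel_spec(1, -2), "amplitudes")
  k <- kernel_spec(c(150, 750), c(2, 0.5))
  expect_equal(varimap:::spatial_kernel(matrix(0), k)[1, 1], 2.5)
})

test_that("mismatched feature spaces and invalid inputs are rejected", {
  mu <- random_measure(3, nf = 2, seed = 1)
  nu <- random_measure(3, nf = 3, seed = 2)
  expect_error(inner_product(mu, nu, kernel_spec(1)), "feature spaces")
  expect_error(particle_measure(matrix(NA_real_, 1, 3), 1, matrix(1, 1),
                                feature_space("a")), "finite")
  expect_error(particle_measure(matrix(0, 1, 3), -1, matrix(1, 1),
                                feature_space("a")), "non-negative")
  expect_error(particle_measure(matrix(0, 1, 3), 1, matrix(0.7, 1),
                                feature_space("a")), "sum to 1")
})

test_that("diffeomorphic action moves mass correctly", {
  mu <- random_measure(8, seed = 4)
  # identity is exact
  expect_equal(apply_diffeo(identity_transform(mu), mu), mu)
  # translation preserves weights
  tr <- point_transform(sweep(mu$positions, 2, c(1, -2, 3), `+`))
  out <- apply_diffeo(tr, mu)
  expect_equal(out$weights, mu$weights)
  expect_equal(out$positions[, 1], mu$positions[, 1] + 1)
  # isotropic scaling by s multiplies weights by s^3
  s <- 1.7
  sc <- apply_similitude(similitude_params(scale = s), mu)
  expect_equal(sc$weights, mu$weights * s^3, tolerance = 1e-12)
  expect_equal(sc$feature_probs, mu$feature_probs)
  # action composition: T2 o T1 with multiplicative jacobians
  t1 <- point_transform(mu$positions * 1.2, rep(1.2^3, 8))
  mid <- apply_diffeo(t1, mu)
  t2 <- point_transform(sweep(mid$positions, 2, c(5, 0, 0), `+`))
  t12 <- point_transform(sweep(mu$positions * 1.2, 2, c(5, 0, 0), `+`), rep(1.2^3, 8))
  expect_equal(apply_diffeo(t2, mid), apply_diffeo(t12, mu), tolerance = 1e-12)
  expect_error(point_transform(mu$positions, rep(-1, 8)), "positive")
})

test_that("empirical measures count detections per label", {
  fs <- feature_space(c("gene1", "gene2"))
  df <- data.frame(x = c(0, 1, 2), y = 0, z = 0,
                   feature = c("gene1", "gene1", "gene2"))
  mu <- empirical_measure_from_points(df, fs)
  expect_equal(n_particles(mu), 3L)
  expect_equal(total_mass(mu), 3)
  expect_error(empirical_measure_from_points(
    data.frame(x = 0, y = 0, feature = "nope"), fs), "nope")
  expect_equal(n_particles(empirical_measure_from_points(df[0, ], fs)), 0L)
  # per-label mass equals per-label point counts, also under duplicates
  set.seed(21)
  df2 <- data.frame(x = sample(1:3, 10, TRUE), y = sample(1:2, 10, TRUE),
                    feature = sample(fs$labels, 10, TRUE))
  m2 <- empirical_measure_from_points(df2, fs)
  expect_equal(feature_mass(m2), table(factor(df2$feature, fs$labels)) |>
                 as.numeric() |> stats::setNames(fs$labels))
  # section weighting scales mass
  expect_equal(total_mass(empirical_measure_from_points(df, fs, 100)), 300)
})
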