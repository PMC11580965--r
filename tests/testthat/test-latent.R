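region_lattice <- function(n_side = 10, extent = 40) {
  # two-region square atlas: left half / right half
  h <- extent / n_side
  ctr <- seq(h / 2, extent - h / 2, by = h)
  g <- as.matrix(expand.grid(ctr, ctr))
  fs <- feature_space(c("L", "R"))
  pi_mat <- cbind(as.numeric(g[, 1] <= extent / 2),
                  as.numeric(g[, 1] > extent / 2))
  particle_measure(cbind(g, 0), rep(1, nrow(g)), pi_mat, fs)
}

test_that("the KL prior matches hand evaluations and scales linearly in the laws", {
  atlas <- region_lattice()
  fsF <- feature_space(c("f1", "f2"))
  # uniform normalized laws give exactly zero
  lat_u <- atlas_latent_model(atlas, fsF, laws = matrix(0.5, 2, 2))
  expect_equal(kl_prior(lat_u), 0)
  # one region, |F| = 2, p = (1, 0), mass ratio 1 -> log 2
  one <- particle_measure(matrix(0, 1, 3), 1, matrix(1, 1), feature_space("only"))
  lat1 <- atlas_latent_model(one, fsF, laws = matrix(c(1, 0), 1))
  expect_equal(kl_prior(lat1, region_masses = 1, target_feature_mass = 1), log(2))
  # homogeneity: scaling laws by c scales each term by c, pbar unchanged
  set.seed(81)
  laws <- matrix(rexp(4), 2)
  lat <- atlas_latent_model(atlas, fsF, laws = laws)
  lat3 <- atlas_latent_model(atlas, fsF, laws = 3 * laws)
  expect_equal(kl_prior(lat3, region_masses = c(1, 1), target_feature_mass = 2),
               3 * kl_prior(lat, region_masses = c(1, 1), target_feature_mass = 2),
               tolerance = 1e-12)
  # zero-mass region contributes nothing
  expect_equal(kl_prior(lat, region_masses = c(0, 0), target_feature_mass = 1), 0)
})

test_that("the induced measure renormalizes non-normalized laws into mass", {
  atlas <- region_lattice(n_side = 4)
  fsF <- feature_space(c("f1", "f2"))
  laws <- rbind(c(2, 0), c(0.5, 0.5))   # region L doubles mass, R keeps it
  lat <- atlas_latent_model(atlas, fsF, laws = laws)
  ind <- induced_measure(lat)
  left <- atlas$feature_probs[, 1] == 1
  expect_equal(ind$weights[left], 2 * atlas$weights[left])
  expect_equal(ind$weights[!left], atlas$weights[!left])
  expect_equal(ind$feature_probs[left, 1], rep(1, sum(left)))
  expect_equal(ind$feature_probs[!left, ], matrix(0.5, sum(!left), 2),
               ignore_attr = TRUE)
})

test_that("latent laws are recovered under frozen identity geometry", {
  atlas <- region_lattice(n_side = 8)
  fsF <- feature_space(c("f1", "f2"))
  true_laws <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  lat_true <- atlas_latent_model(atlas, fsF, laws = true_laws)
  target <- induced_measure(lat_true)
  fit <- fit_crossmodality_map(atlas_latent_model(atlas, fsF), target,
                               v_kernel = kernel_spec(10),
                               m_kernel = kernel_spec(8),
                               estimate_deformation = FALSE, maxit = 150)
  tv <- 0.5 * rowSums(abs(normalized_laws(fit$latent) - true_laws / rowSums(true_laws)))
  expect_lt(max(tv), 0.05)
  # degenerate single-feature target pushes the law onto that feature
  target_f1 <- particle_measure(atlas$positions, atlas$weights,
                                cbind(rep(1, n_particles(atlas)), 0), fsF)
  fit1 <- fit_crossmodality_map(atlas_latent_model(atlas, fsF), target_f1,
                                v_kernel = kernel_spec(10),
                                m_kernel = kernel_spec(8),
                                estimate_deformation = FALSE, maxit = 150)
  expect_gte(min(normalized_laws(fit1$latent)[, 1]), 0.99)
})

test_that("with known laws and no censor the cross-modality data term reduces to the plain norm", {
  atlas <- region_lattice(n_side = 6)
  fsF <- feature_space(c("f1", "f2"))
  laws <- rbind(c(0.7, 0.3), c(0.1, 0.9))
  lat <- atlas_latent_model(atlas, fsF, laws = laws)
  mk <- kernel_spec(8)
  set.seed(82)
  target <- random_measure(30, nf = 2, extent = 40, seed = 82)
  target$feature_space <- fsF
  colnames(target$feature_probs) <- fsF$labels
  fit <- fit_crossmodality_map(lat, target, kernel_spec(10), mk,
                               estimate_deformation = FALSE,
                               estimate_laws = FALSE, maxit = 1)
  expect_equal(fit$residual, norm_distance_sq(induced_measure(lat), target, mk),
               tolerance = 1e-8)
  expect_error(fit_crossmodality_map(lat, empty_measure(fsF), kernel_spec(10), mk),
               "empty")
})

test_that("an all-censoring support function is rejected as degenerate", {
  atlas <- region_lattice(n_side = 4)
  fsF <- feature_space(c("f1", "f2"))
  lat <- atlas_latent_model(atlas, fsF, laws = matrix(0.5, 2, 2))
  target <- induced_measure(lat)
  expect_error(fit_crossmodality_map(lat, target, kernel_spec(10), kernel_spec(8),
                                     censor = function(x) rep(0, nrow(x)),
                                     estimate_deformation = FALSE, maxit = 5),
               "degenerate|vanish")
})
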