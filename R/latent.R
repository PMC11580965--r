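#' Atlas with latent per-region feature laws
#'
#' A tissue-scale atlas carries a region ontology but not the molecular
#' features of a target.  Cross-modality mapping augments each region
#' \eqn{\ell} with a latent non-normalized law \eqn{p_\ell(f)} over the
#' target's feature space; each atlas particle mixes laws through its region
#' memberships \eqn{\pi_i(\ell)} (one-hot for interior particles, mixed at
#' region boundaries).
#'
#' @param atlas `particle_measure` whose feature space is the region
#'   ontology: its `feature_probs` rows are the memberships \eqn{\pi_i}.
#' @param feature_space Target [feature_space()] the latent laws live on.
#' @param laws Optional |L| x |F| non-negative matrix of non-normalized laws
#'   (rows = regions in ontology order); `NULL` until estimated.
#' @return An object of class `atlas_latent_model`.
#' @export
atlas_latent_model <- function(atlas, feature_space, laws = NULL) {
  if (!inherits(atlas, "particle_measure")) stop("'atlas' must be a particle_measure")
  nl <- length(atlas$feature_space$labels)
  nf <- length(feature_space$labels)
  if (!is.null(laws)) {
    laws <- as.matrix(laws)
    if (!all(dim(laws) == c(nl, nf))) stop(sprintf("'laws' must be %d x %d", nl, nf))
    if (any(laws < 0)) stop("latent laws must be non-negative")
    dimnames(laws) <- list(atlas$feature_space$labels, feature_space$labels)
  }
  structure(list(atlas = atlas, feature_space = feature_space, laws = laws),
            class = "atlas_latent_model")
}

#' @export
print.atlas_latent_model <- function(x, ...) {
  cat(sprintf("<atlas_latent_model> N = %d particles, %d regions -> %d features, laws %s\n",
              n_particles(x$atlas), length(x$atlas$feature_space$labels),
              length(x$feature_space$labels),
              if (is.null(x$laws)) "unset" else "estimated"))
  invisible(x)
}

#' Normalized latent laws
#' @param latent An `atlas_latent_model` with laws set.
#' @return |L| x |F| matrix of row-normalized laws \eqn{\bar p_\ell}
#'   (rows with zero total mass are left at zero).
#' @export
normalized_laws <- function(latent) {
  if (is.null(latent$laws)) stop("latent laws have not been estimated")
  rs <- rowSums(latent$laws)
  sweep(latent$laws, 1L, ifelse(rs > 0, rs, 1), `/`)
}

#' Measure over the target features induced by the latent laws
#'
#' \eqn{\mu_A^p = \sum_i w_i \delta_{x_i} \otimes \sum_\ell \pi_i(\ell)
#' p_\ell}: since the laws are non-normalized, each particle's weight picks
#' up the total law mass \eqn{\sum_f \sum_\ell \pi_i(\ell) p_\ell(f)} and the
#' conditional distribution is renormalized.
#'
#' @param latent An `atlas_latent_model` with laws set.
#' @param atlas Optional replacement for the atlas particles (e.g. the
#'   deformed atlas at the current optimization state); defaults to
#'   `latent$atlas`.
#' @return A `particle_measure` over `latent$feature_space`.
#' @export
induced_measure <- function(latent, atlas = NULL) {
  if (is.null(latent$laws)) stop("latent laws have not been estimated")
  if (is.null(atlas)) atlas <- latent$atlas
  q <- atlas$feature_probs %*% latent$laws       # N x |F|, non-normalized
  m <- rowSums(q)
  probs <- sweep(q, 1L, ifelse(m > 0, m, 1), `/`)
  probs[m <= 0, ] <- 1 / ncol(q)
  particle_measure(atlas$positions, atlas$weights * m, probs,
                   latent$feature_space)
}

#' Kullback-Leibler prior on the latent feature laws
#'
#' Penalizes each region's law away from the uniform distribution, weighted
#' by the region's share of deformed-atlas mass relative to the total target
#' feature mass:
#' \deqn{\sum_\ell \frac{M^A_\ell}{\sum_f M^T_f} \sum_f p_\ell(f)\,
#'   \log\frac{\bar p_\ell(f)}{1/|F|}.}
#' Regions with zero mass contribute 0 by convention, as do features with
#' \eqn{p_\ell(f) = 0} (the usual \eqn{0\log 0 = 0}).
#'
#' @param latent An `atlas_latent_model` with laws set.
#' @param region_masses Vector \eqn{M^A_\ell} of per-region atlas masses
#'   following deformation (and censoring, when active); defaults to the
#'   masses of `latent$atlas` as stored.
#' @param target_feature_mass Total target mass \eqn{\sum_f M^T_f}.
#' @return Scalar penalty.
#' @export
kl_prior <- function(latent, region_masses = NULL, target_feature_mass = NULL) {
  if (is.null(latent$laws)) stop("latent laws have not been estimated")
  p <- latent$laws
  if (is.null(region_masses))
    region_masses <- as.numeric(crossprod(latent$atlas$feature_probs,
                                          latent$atlas$weights))
  if (is.null(target_feature_mass)) target_feature_mass <- 1
  nf <- ncol(p)
  pbar <- sweep(p, 1L, ifelse(rowSums(p) > 0, rowSums(p), 1), `/`)
  lg <- log(pmax(pbar * nf, .Machine$double.xmin))
  lg[p == 0] <- 0
  sum((region_masses / target_feature_mass) * rowSums(p * lg))
}

#' Censored varifold action
#'
#' Applies a diffeomorphic transform to a measure and masks the transported
#' mass by a spatial support function evaluated at the mapped positions:
#' \deqn{\sum_i \alpha_\lambda(\varphi(x_i))\,|D\varphi|(x_i)\,w_i\,
#'   \delta_{\varphi(x_i)} \otimes p_i.}
#'
#' @param censor A censor object ([planar_censor()], [mlp_censor] from
#'   [fit_mlp_support()], a plain function of an N x 3 matrix, or `NULL` for
#'   no censoring).
#' @param transform A [point_transform()].
#' @param mu The `particle_measure` being transported.
#' @param lambda Optional bandwidth overriding the censor's own.
#' @return The censored, transported `particle_measure`.
#' @export
censored_action <- function(censor, transform, mu, lambda = NULL) {
  out <- apply_diffeo(transform, mu)
  if (is.null(censor)) return(out)
  a <- censor_weights(censor, out$positions, lambda = lambda)
  if (any(a < -1e-9) || any(a > 1 + 1e-9))
    stop("censor weights must lie in [0, 1]")
  out$weights <- out$weights * pmin(pmax(a, 0), 1)
  out
}
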