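#' Particle measure (image varifold)
#'
#' A weighted sum of point masses in physical space, each paired with a
#' conditional probability distribution over a finite feature space:
#' \deqn{\mu = \sum_i w_i \,\delta_{x_i} \otimes p_i.}
#' Mass lives in the weights `w_i` (detection counts, cell counts, or voxel
#' volume); each row `p_i` of `feature_probs` is a probability vector.
#'
#' @param positions Numeric matrix, N x 3, coordinates in micrometers.  2D
#'   sections are embedded with a constant third coordinate.
#' @param weights Numeric vector of N non-negative masses.
#' @param feature_probs Numeric matrix, N x |F|; each row non-negative and
#'   summing to 1 (within 1e-8).
#' @param feature_space A [feature_space()].
#' @return An object of class `particle_measure`.  N may be 0: the empty
#'   measure is legal and has norm zero.
#' @export
particle_measure <- function(positions, weights, feature_probs, feature_space) {
  if (!inherits(feature_space, "feature_space"))
    stop("'feature_space' must be a feature_space object")
  positions <- as_matrix3(positions)
  weights <- as.numeric(weights)
  feature_probs <- as.matrix(feature_probs)
  n <- nrow(positions)
  nf <- length(feature_space$labels)
  if (n == 0L) {
    feature_probs <- matrix(numeric(0), 0L, nf)
  }
  if (length(weights) != n)
    stop("'weights' must have one entry per particle")
  if (nrow(feature_probs) != n || ncol(feature_probs) != nf)
    stop(sprintf("'feature_probs' must be %d x %d", n, nf))
  if (n > 0L) {
    if (any(!is.finite(positions))) stop("positions must be finite")
    if (any(!is.finite(weights)) || any(weights < 0))
      stop("weights must be finite and non-negative")
    if (any(!is.finite(feature_probs)) || any(feature_probs < -1e-12))
      stop("feature probabilities must be finite and non-negative")
    rs <- rowSums(feature_probs)
    if (any(abs(rs - 1) > 1e-8))
      stop("each row of 'feature_probs' must sum to 1 (within 1e-8)")
  }
  colnames(feature_probs) <- feature_space$labels
  structure(list(positions = positions, weights = weights,
                 feature_probs = feature_probs, feature_space = feature_space),
            class = "particle_measure")
}

#' Empty particle measure over a feature space
#' @param feature_space A [feature_space()].
#' @return A `particle_measure` with zero particles.
#' @export
empty_measure <- function(feature_space) {
  particle_measure(matrix(numeric(0), 0L, 3L), numeric(0),
                   matrix(numeric(0), 0L, length(feature_space$labels)),
                   feature_space)
}

as_matrix3 <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) return(matrix(numeric(0), 0L, 3L))
  if (ncol(x) == 2L) x <- cbind(x, 0)  # planar data embedded at z = 0
  if (ncol(x) != 3L) stop("positions must have 2 or 3 columns")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.particle_measure <- function(x, ...) {
  cat(sprintf("<particle_measure> N = %d, total mass = %.6g, |F| = %d (%s)\n",
              n_particles(x), total_mass(x), length(x$feature_space$labels),
              x$feature_space$kind))
  invisible(x)
}

#' Number of particles
#' @param mu A `particle_measure`.
#' @return Integer particle count.
#' @export
n_particles <- function(mu) nrow(mu$positions)

#' Total mass of a particle measure
#' @param mu A `particle_measure`.
#' @return Sum of the particle weights.
#' @export
total_mass <- function(mu) sum(mu$weights)

#' Mass per feature, summed over particles
#'
#' Column sums of \eqn{w_i p_i(f)}: the total mass carried by each feature.
#' @param mu A `particle_measure`.
#' @return Named numeric vector over the feature labels.
#' @export
feature_mass <- function(mu) {
  if (n_particles(mu) == 0L)
    return(stats::setNames(numeric(length(mu$feature_space$labels)),
                           mu$feature_space$labels))
  stats::setNames(as.numeric(crossprod(mu$feature_probs, mu$weights)),
                  mu$feature_space$labels)
}

#' Scale the mass of a measure
#' @param mu A `particle_measure`.
#' @param a Non-negative scalar.
#' @return `mu` with all weights multiplied by `a`.
#' @export
scale_mass <- function(mu, a) {
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0)
  mu$weights <- mu$weights * a
  mu
}

#' Subset particles of a measure
#' @param mu A `particle_measure`.
#' @param idx Index vector of particles to keep.
#' @return The restricted `particle_measure`.
#' @export
subset_particles <- function(mu, idx) {
  particle_measure(mu$positions[idx, , drop = FALSE], mu$weights[idx],
                   mu$feature_probs[idx, , drop = FALSE], mu$feature_space)
}

#' Concatenate particle measures over a common feature space
#' @param ... `particle_measure` objects sharing one feature space.
#' @return A single `particle_measure`.
#' @export
bind_measures <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1]]) && !inherits(ms[[1]], "particle_measure"))
    ms <- ms[[1]]
  fs <- ms[[1]]$feature_space
  for (m in ms) if (!same_feature_space(fs, m$feature_space))
    stop("measures must share a feature space")
  particle_measure(do.call(rbind, lapply(ms, `[[`, "positions")),
                   unlist(lapply(ms, `[[`, "weights")),
                   do.call(rbind, lapply(ms, `[[`, "feature_probs")), fs)
}
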