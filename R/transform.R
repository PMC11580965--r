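#' Pointwise transform of particle positions
#'
#' The discrete record of a diffeomorphism evaluated at a set of particles:
#' the mapped positions \eqn{\varphi(x_i)} and the local volume changes
#' \eqn{|D\varphi|(x_i) > 0}.
#'
#' @param mapped_positions Numeric matrix, N x 3, of mapped points.
#' @param jacobian_dets Numeric vector of N strictly positive Jacobian
#'   determinants; defaults to 1 (volume-preserving).
#' @return An object of class `point_transform`.
#' @export
point_transform <- function(mapped_positions, jacobian_dets = NULL) {
  mapped_positions <- as_matrix3(mapped_positions)
  n <- nrow(mapped_positions)
  if (is.null(jacobian_dets)) jacobian_dets <- rep(1, n)
  jacobian_dets <- as.numeric(jacobian_dets)
  if (length(jacobian_dets) != n)
    stop("'jacobian_dets' must have one entry per point")
  if (n > 0L && (any(!is.finite(jacobian_dets)) || any(jacobian_dets <= 0)))
    stop("jacobian determinants must be finite and strictly positive")
  structure(list(mapped_positions = mapped_positions,
                 jacobian_dets = jacobian_dets),
            class = "point_transform")
}

#' Identity transform on the particles of a measure
#' @param mu A `particle_measure`.
#' @return A `point_transform` fixing every particle with unit Jacobian.
#' @export
identity_transform <- function(mu) point_transform(mu$positions)

#' Varifold action of a diffeomorphism on a particle measure
#'
#' Transports a measure under a mapping: positions move to \eqn{\varphi(x_i)}
#' and masses scale by the local Jacobian determinant,
#' \deqn{\varphi\cdot\mu = \sum_i |D\varphi|(x_i)\, w_i\,
#'   \delta_{\varphi(x_i)} \otimes p_i,}
#' leaving the feature distributions unchanged.
#'
#' @param transform A [point_transform()] with one entry per particle of `mu`.
#' @param mu A `particle_measure`.
#' @return The transported `particle_measure`.
#' @export
apply_diffeo <- function(transform, mu) {
  if (!inherits(transform, "point_transform"))
    stop("'transform' must be a point_transform")
  if (nrow(transform$mapped_positions) != n_particles(mu))
    stop("transform and measure have different particle counts")
  particle_measure(transform$mapped_positions,
                   transform$jacobian_dets * mu$weights,
                   mu$feature_probs, mu$feature_space)
}

#' Global similitude (rotation + translation + isotropic scale)
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @param translation Length-3 numeric vector (micrometers).
#' @param scale Positive isotropic scale factor.
#' @return An object of class `similitude_params`.
#' @export
similitude_params <- function(rotation = diag(3), translation = c(0, 0, 0),
                              scale = 1) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("'rotation' must be a proper 3x3 rotation matrix")
  if (length(translation) != 3L || !is.numeric(translation))
    stop("'translation' must be a length-3 numeric vector")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("'scale' must be a positive scalar")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = scale),
            class = "similitude_params")
}

#' Apply a similitude to a particle measure
#'
#' Positions map to \eqn{s R x + \tau}; masses scale by the Jacobian
#' determinant \eqn{s^3}.
#'
#' @param sim A [similitude_params()].
#' @param mu A `particle_measure`.
#' @return The transformed `particle_measure`.
#' @export
apply_similitude <- function(sim, mu) {
  if (!inherits(sim, "similitude_params")) stop("'sim' must be similitude_params")
  if (n_particles(mu) == 0L) return(mu)
  pos <- sim$scale * tcrossprod(mu$positions, sim$rotation)
  pos <- sweep(pos, 2L, sim$translation, `+`)
  apply_diffeo(point_transform(pos, rep(sim$scale^3, n_particles(mu))), mu)
}

#' Rotation matrix about the z axis
#' @param theta Angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_z <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3L, 3L)
}

# Rodrigues' formula: rotation matrix from a rotation vector (axis * angle).
rotation_from_vector <- function(omega) {
  th <- sqrt(sum(omega^2))
  if (th < 1e-12) return(diag(3))
  k <- omega / th
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3L, 3L)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}
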