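#' Planar censoring function (two opposing tanh fronts)
#'
#' Spatial support weight for targets bounded by two parallel (or oblique)
#' planes, e.g. the first and last section of a serial stack:
#' \deqn{\alpha_\lambda(x) = \tfrac12\left[\tanh\frac{\langle x-a_0,
#'   n_0\rangle}{\lambda} + \tanh\frac{\langle x-a_1, n_1\rangle}{\lambda}
#'   \right]}
#' with both normals pointing toward the interior.  Values are ~1 deep
#' inside, ~1/2 on each anchor plane, and ~0 outside.
#'
#' @param a0,a1 Anchor points (length-3, target coordinates, micrometers).
#' @param n0,n1 Normals pointing toward the interior sections (normalized
#'   internally).
#' @param lambda Transition bandwidth (micrometers, > 0).
#' @return An object of class `planar_censor`.
#' @export
planar_censor <- function(a0, a1, n0, n1, lambda) {
  if (lambda <= 0) stop("'lambda' must be > 0")
  norm0 <- sqrt(sum(n0^2)); norm1 <- sqrt(sum(n1^2))
  if (norm0 == 0 || norm1 == 0) stop("normals must be non-zero")
  structure(list(a0 = as.numeric(a0), a1 = as.numeric(a1),
                 n0 = as.numeric(n0) / norm0, n1 = as.numeric(n1) / norm1,
                 lambda = lambda),
            class = c("planar_censor", "censor_field"))
}

#' Evaluate a planar censor at points
#' @param x Numeric matrix (N x 3) or length-3 vector of points.
#' @param censor A [planar_censor()].
#' @param lambda Optional bandwidth overriding `censor$lambda`.
#' @return Vector of support weights in `[0, 1]`.
#' @export
planar_support <- function(x, censor, lambda = NULL) {
  if (is.null(lambda)) lambda <- censor$lambda
  x <- if (is.matrix(x)) x else matrix(x, ncol = 3L)
  s0 <- as.numeric(sweep(x, 2L, censor$a0, `-`) %*% censor$n0)
  s1 <- as.numeric(sweep(x, 2L, censor$a1, `-`) %*% censor$n1)
  pmin(pmax(0.5 * (tanh(s0 / lambda) + tanh(s1 / lambda)), 0), 1)
}

#' Bandwidth regularization for the censor transition zone
#'
#' \eqn{J_s(\lambda) = u\ln u + 1 - u} with \eqn{u = \lambda^2/0.1}:
#' zero at \eqn{\lambda^2 = 0.1} and growing on either side, discouraging
#' both vanishing and unbounded transition widths.  The reference constant
#' 0.1 is calibrated with \eqn{\lambda} in millimeters (so the minimum sits
#' at a ~316 micrometer transition); pass `unit = "um"` to supply
#' micrometers directly.
#'
#' @param lambda Bandwidth (> 0), in the units given by `unit`.
#' @param unit `"mm"` (default) or `"um"`.
#' @return Scalar penalty (>= 0, zero at the reference bandwidth).
#' @export
lambda_reg <- function(lambda, unit = c("mm", "um")) {
  unit <- match.arg(unit)
  if (any(lambda <= 0)) stop("'lambda' must be > 0")
  if (unit == "um") lambda <- lambda / 1000
  u <- lambda^2 / 0.1
  u * log(u) + 1 - u
}

#' Censor weights at points (generic)
#' @param censor A censor object or plain function.
#' @param x N x 3 matrix of points.
#' @param lambda Optional bandwidth override.
#' @return Vector of weights in `[0, 1]`.
#' @export
censor_weights <- function(censor, x, lambda = NULL) UseMethod("censor_weights")

#' @export
censor_weights.planar_censor <- function(censor, x, lambda = NULL)
  planar_support(x, censor, lambda = lambda)

#' @export
censor_weights.function <- function(censor, x, lambda = NULL) censor(x)

#' @export
censor_weights.mlp_censor <- function(censor, x, lambda = NULL)
  mlp_forward(censor, x, lambda = lambda)$out

# --- small dense support classifier -----------------------------------------

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

# Forward pass of the 3 -> 15 -> 5 -> 1 network; returns intermediates for
# backprop.  Output is tanh(z / lambda) shifted and rescaled to [0, 1].
mlp_forward <- function(net, x, lambda = NULL) {
  if (is.null(lambda)) lambda <- net$lambda
  x <- if (is.matrix(x)) x else matrix(x, ncol = 3L)
  xs <- sweep(sweep(x, 2L, net$center, `-`), 2L, net$scale, `/`)
  z1 <- sweep(xs %*% net$W1, 2L, net$b1, `+`); h1 <- elu(z1)
  z2 <- sweep(h1 %*% net$W2, 2L, net$b2, `+`); h2 <- elu(z2)
  z3 <- as.numeric(h2 %*% net$W3) + net$b3
  list(xs = xs, z1 = z1, h1 = h1, z2 = z2, h2 = h2, z3 = z3,
       out = (tanh(z3 / lambda) + 1) / 2)
}

#' Fit the dense support classifier for irregular censor boundaries
#'
#' Trains a small fully connected network (layers 3 x 15 and 15 x 5 with
#' exponential-linear activations, then 5 x 1 with a hyperbolic-tangent
#' output rescaled to `[0, 1]`) to separate measured-tissue particles
#' (label 1) from boundary particles (label 0): manually placed medial-edge
#' points plus synthetic cap sections placed rostral and caudal of the stack.
#' The minority class is up-weighted 1000:1 in the cross-entropy loss.
#' Training (full-batch Adam) is deterministic given the seed.
#'
#' @param support_particles N1 x 3 matrix of in-support points (label 1).
#' @param boundary_particles N0 x 3 matrix of boundary/exterior points
#'   (label 0).
#' @param epochs Training epochs (default 500).
#' @param lr Adam learning rate (default 0.01).
#' @param lambda Output bandwidth; joins the mapping optimization later, as
#'   for the planar censor (default 1).
#' @param class_weight Weight multiplier for the minority class
#'   (default 1000).
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `mlp_censor`; evaluate it with
#'   [censor_weights()].
#' @export
fit_mlp_support <- function(support_particles, boundary_particles,
                            epochs = 500, lr = 0.01, lambda = 1,
                            class_weight = 1000, seed = 1) {
  s <- as_matrix3(support_particles); b <- as_matrix3(boundary_particles)
  if (nrow(s) == 0L || nrow(b) == 0L)
    stop("need at least one particle of each class")
  x <- rbind(s, b)
  y <- c(rep(1, nrow(s)), rep(0, nrow(b)))
  wts <- rep(1, length(y))
  if (nrow(s) != nrow(b)) {
    minority <- if (nrow(s) < nrow(b)) 1 else 0
    wts[y == minority] <- class_weight
  }
  wts <- wts / sum(wts)
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd); scale[scale == 0 | !is.finite(scale)] <- 1
  set.seed(seed)
  init <- function(r, c) matrix(stats::runif(r * c, -1, 1) / sqrt(r), r, c)
  net <- structure(list(W1 = init(3, 15), b1 = numeric(15),
                        W2 = init(15, 5), b2 = numeric(5),
                        W3 = init(5, 1), b3 = 0,
                        lambda = lambda, center = center, scale = scale),
                   class = c("mlp_censor", "censor_field"))
  # Adam state
  mom <- lapply(net[1:6], function(p) p * 0)
  vel <- mom
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
  for (ep in seq_len(epochs)) {
    fw <- mlp_forward(net, x)
    o <- pmin(pmax(fw$out, 1e-7), 1 - 1e-7)
    # weighted binary cross-entropy; d loss / d z3 via tanh derivative
    dL_do <- wts * (o - y) / (o * (1 - o))
    dz3 <- dL_do * (1 - tanh(fw$z3 / net$lambda)^2) / (2 * net$lambda)
    gW3 <- crossprod(fw$h2, dz3); gb3 <- sum(dz3)
    dh2 <- outer(as.numeric(dz3), as.numeric(net$W3)) * elu_grad(fw$z2)
    gW2 <- crossprod(fw$h1, dh2); gb2 <- colSums(dh2)
    dh1 <- (dh2 %*% t(net$W2)) * elu_grad(fw$z1)
    gW1 <- crossprod(fw$xs, dh1); gb1 <- colSums(dh1)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
    for (nm in names(grads)) {
      mom[[nm]] <- b1a * mom[[nm]] + (1 - b1a) * grads[[nm]]
      vel[[nm]] <- b2a * vel[[nm]] + (1 - b2a) * grads[[nm]]^2
      mhat <- mom[[nm]] / (1 - b1a^ep)
      vhat <- vel[[nm]] / (1 - b2a^ep)
      net[[nm]] <- net[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  net
}

#' @export
print.mlp_censor <- function(x, ...) {
  cat(sprintf("<mlp_censor> dense 3-15-5-1 support classifier, lambda = %g\n",
              x$lambda))
  invisible(x)
}
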