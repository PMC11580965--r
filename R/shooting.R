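#' Geodesic control: initial momenta of the particle flow
#'
#' A diffeomorphic flow of particles is parameterized entirely by its initial
#' momenta: a 3-vector space momentum and a scalar mass momentum per atlas
#' particle, together with the Green's kernel of the velocity field.
#' Zero momenta produce the identity flow.
#'
#' @param rho_x Numeric matrix, N x 3, of space momenta.
#' @param rho_w Numeric vector of N mass momenta.
#' @param v_kernel [kernel_spec()] for the velocity field (Gaussian or sum of
#'   Gaussians).
#' @return An object of class `geodesic_control`.
#' @export
geodesic_control <- function(rho_x, rho_w, v_kernel) {
  rho_x <- as.matrix(rho_x)
  if (ncol(rho_x) != 3L) stop("'rho_x' must be N x 3")
  rho_w <- as.numeric(rho_w)
  if (length(rho_w) != nrow(rho_x))
    stop("'rho_w' must have one entry per particle")
  if (!inherits(v_kernel, "kernel_spec")) stop("'v_kernel' must be a kernel_spec")
  structure(list(rho_x = rho_x, rho_w = rho_w, v_kernel = v_kernel),
            class = "geodesic_control")
}

#' Zero control (identity flow) for an atlas
#' @param atlas A `particle_measure`.
#' @param v_kernel Velocity-field [kernel_spec()].
#' @return A `geodesic_control` with all momenta zero.
#' @export
zero_control <- function(atlas, v_kernel) {
  n <- n_particles(atlas)
  geodesic_control(matrix(0, n, 3L), numeric(n), v_kernel)
}

#' Velocity field induced by a particle state and its momenta
#'
#' For each Gaussian component \eqn{a\,k_\sigma} of the velocity kernel,
#' \deqn{v(x) = \sum_i k_\sigma(x, x_i)\,\rho^x_i +
#'   \frac{x - x_i}{\sigma^2}\, w_i \rho^w_i\, k_\sigma(x, x_i),}
#' summed over components (each component contributes with its own
#' \eqn{\sigma}).
#'
#' @param points Numeric matrix, M x 3, of probe points.
#' @param state List with elements `x` (N x 3 particle positions), `w`
#'   (N weights), `rx` (N x 3 space momenta), `rw` (N mass momenta).
#' @param v_kernel Velocity-field [kernel_spec()].
#' @return M x 3 matrix of velocities.
#' @export
velocity_field <- function(points, state, v_kernel) {
  points <- as_matrix3(points)
  b <- state$w * state$rw
  v <- matrix(0, nrow(points), 3L)
  d2 <- cross_dist2(points, state$x)
  for (c in seq_along(v_kernel$sigmas)) {
    s2 <- v_kernel$sigmas[c]^2
    e <- v_kernel$amplitudes[c] * exp(-d2 / (2 * s2))
    v <- v + e %*% state$rx
    for (d in 1:3) {
      xd <- outer(points[, d], state$x[, d], `-`)
      v[, d] <- v[, d] + as.numeric((e * xd) %*% b) / s2
    }
  }
  v
}

# Right-hand side of the Hamiltonian system (Gaussian kernels, closed form):
#   xdot_i  = v(x_i)
#   wdot_i  = div v(x_i) w_i
#   rxdot_i = -grad_{x_i} H
#   rwdot_i = -dH/dw_i  ( = -rho^w_i div v(x_i) )
# with H(q, rho) = 1/2 sum_i [rho^x_i . v(x_i) + rho^w_i w_i div v(x_i)].
# The divergence is analytic, not finite-difference; tests validate both the
# divergence and the momentum equations against numerical oracles.
geodesic_dynamics <- function(state, v_kernel, want_hamiltonian = FALSE) {
  x <- state$x; w <- state$w; rx <- state$rx; rw <- state$rw
  n <- nrow(x)
  b <- w * rw
  d2 <- cross_dist2(x, x)
  v <- matrix(0, n, 3L)
  dv <- numeric(n)          # div v at particles
  rxdot <- matrix(0, n, 3L)
  rr <- tcrossprod(rx)      # rho^x_i . rho^x_j
  xd <- vector("list", 3L)
  for (d in 1:3) xd[[d]] <- outer(x[, d], x[, d], `-`)
  for (c in seq_along(v_kernel$sigmas)) {
    s2 <- v_kernel$sigmas[c]^2
    e <- v_kernel$amplitudes[c] * exp(-d2 / (2 * s2))
    # A1_ij = rho^x_i . r_ij ; A2_ij = rho^x_j . r_ij   (r_ij = x_i - x_j)
    a1 <- matrix(0, n, n); a2 <- matrix(0, n, n)
    for (d in 1:3) {
      a1 <- a1 + rx[, d] * xd[[d]]
      a2 <- a2 + xd[[d]] * rep(rx[, d], each = n)
    }
    ddig <- 3 / s2 - d2 / s2^2
    eb <- as.numeric(e %*% b)
    erx <- e %*% rx
    # velocity and divergence
    v <- v + erx
    for (d in 1:3) v[, d] <- v[, d] + as.numeric((e * xd[[d]]) %*% b) / s2
    for (d in 1:3) dv <- dv - as.numeric((e * xd[[d]]) %*% rx[, d]) / s2
    dv <- dv + as.numeric((e * ddig) %*% b)
    # momentum equations
    s <- rr + (sweep(a1, 2L, b, `*`) - b * a2) / s2 + outer(b, b) * ddig
    es <- e * s
    for (d in 1:3) {
      g_d <- (rx[, d] * eb - b * erx[, d]) / s2 -
        (2 * b / s2^2) * as.numeric((e * xd[[d]]) %*% b)
      rxdot[, d] <- rxdot[, d] + rowSums(es * xd[[d]]) / s2 - g_d
    }
  }
  out <- list(xdot = v, wdot = dv * w, rxdot = rxdot, rwdot = -rw * dv)
  if (want_hamiltonian)
    out$hamiltonian <- 0.5 * (sum(rx * v) + sum(rw * w * dv))
  out
}

#' Hamiltonian (kinetic energy) of a particle state
#'
#' Conserved along geodesics; its initial value is the kinetic-energy term
#' of the mapping objectives.
#'
#' @param state List with `x`, `w`, `rx`, `rw` as in [velocity_field()].
#' @param v_kernel Velocity-field [kernel_spec()].
#' @return Scalar Hamiltonian value.
#' @export
hamiltonian <- function(state, v_kernel) {
  geodesic_dynamics(state, v_kernel, want_hamiltonian = TRUE)$hamiltonian
}

#' Geodesic shooting of a particle measure
#'
#' Integrates the Hamiltonian system from t = 0 to 1 with fixed-step RK4
#' (default) or forward Euler, starting from the atlas particles and the
#' given initial momenta.  The endpoint weights implement the Jacobian
#' scaling \eqn{|D\varphi|\,w_i} of the varifold action.
#'
#' @param control A [geodesic_control()].
#' @param atlas A `particle_measure` with one particle per momentum pair.
#' @param n_steps Number of time steps (>= 1), default 10.
#' @param integrator `"rk4"` (default) or `"euler"` (kept for cross-checks).
#' @return An object of class `geodesic_path`: lists `x`, `w`, `rx`, `rw`
#'   indexed by time step, `times`, and `hamiltonian_trace`.
#' @export
shoot <- function(control, atlas, n_steps = 10, integrator = c("rk4", "euler")) {
  integrator <- match.arg(integrator)
  if (n_steps < 1) stop("'n_steps' must be >= 1")
  if (nrow(control$rho_x) != n_particles(atlas))
    stop("control and atlas have different particle counts")
  state <- list(x = atlas$positions, w = atlas$weights,
                rx = control$rho_x, rw = control$rho_w)
  dt <- 1 / n_steps
  kern <- control$v_kernel
  path <- list(times = seq(0, 1, length.out = n_steps + 1L),
               x = vector("list", n_steps + 1L), w = vector("list", n_steps + 1L),
               rx = vector("list", n_steps + 1L), rw = vector("list", n_steps + 1L),
               hamiltonian_trace = numeric(n_steps + 1L))
  store <- function(k, st) {
    path$x[[k]] <<- st$x; path$w[[k]] <<- st$w
    path$rx[[k]] <<- st$rx; path$rw[[k]] <<- st$rw
    path$hamiltonian_trace[k] <<- hamiltonian(st, kern)
  }
  add <- function(st, dd, h)
    list(x = st$x + h * dd$xdot, w = st$w + h * dd$wdot,
         rx = st$rx + h * dd$rxdot, rw = st$rw + h * dd$rwdot)
  store(1L, state)
  for (k in seq_len(n_steps)) {
    if (integrator == "euler") {
      state <- add(state, geodesic_dynamics(state, kern), dt)
    } else {
      k1 <- geodesic_dynamics(state, kern)
      k2 <- geodesic_dynamics(add(state, k1, dt / 2), kern)
      k3 <- geodesic_dynamics(add(state, k2, dt / 2), kern)
      k4 <- geodesic_dynamics(add(state, k3, dt), kern)
      state <- list(
        x = state$x + dt / 6 * (k1$xdot + 2 * k2$xdot + 2 * k3$xdot + k4$xdot),
        w = state$w + dt / 6 * (k1$wdot + 2 * k2$wdot + 2 * k3$wdot + k4$wdot),
        rx = state$rx + dt / 6 * (k1$rxdot + 2 * k2$rxdot + 2 * k3$rxdot + k4$rxdot),
        rw = state$rw + dt / 6 * (k1$rwdot + 2 * k2$rwdot + 2 * k3$rwdot + k4$rwdot))
    }
    if (any(!is.finite(state$x)) || any(!is.finite(state$w)))
      stop("geodesic integration produced non-finite state at step ", k)
    store(k + 1L, state)
  }
  structure(path, class = "geodesic_path", atlas_features = atlas$feature_probs,
            feature_space = atlas$feature_space)
}

#' Endpoint measure of a geodesic path
#'
#' The deformed atlas at t = 1: positions and Jacobian-scaled weights from the
#' flow, feature distributions carried along unchanged.
#'
#' @param path A `geodesic_path` from [shoot()].
#' @return A `particle_measure`.
#' @export
endpoint_measure <- function(path) {
  k <- length(path$x)
  particle_measure(path$x[[k]], pmax(path$w[[k]], 0),
                   attr(path, "atlas_features"), attr(path, "feature_space"))
}

#' @export
print.geodesic_path <- function(x, ...) {
  h <- x$hamiltonian_trace
  cat(sprintf("<geodesic_path> %d steps, N = %d, H(0) = %.6g, max rel drift = %.2e\n",
              length(x$times) - 1L, nrow(x$x[[1]]), h[1],
              if (abs(h[1]) > 0) max(abs(h - h[1])) / abs(h[1]) else 0))
  invisible(x)
}
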