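#' Configuration for optimization-based scale-space resampling
#'
#' @param sigma Approximation scale (micrometers): both the edge of the
#'   initialization lattice and the spatial bandwidth of the approximation
#'   metric.
#' @param stage_iters L-BFGS iterations per optimization stage (default 200).
#' @param truncation_radius Multiple of sigma beyond which kernel terms are
#'   zeroed (default 4, must be >= 2).
#' @param seed Integer seed for the random in-cube initializer.
#' @param split Number of spatial blocks large inputs are divided into
#'   (1, 2 or 4; axis-aligned cuts at weighted medians, approximated
#'   independently and concatenated).  Default 1.
#' @return An object of class `approx_config`.
#' @export
approx_config <- function(sigma, stage_iters = 200, truncation_radius = 4,
                          seed = 1, split = 1) {
  if (sigma <= 0) stop("'sigma' must be > 0")
  if (truncation_radius < 2) stop("'truncation_radius' must be >= 2")
  if (!split %in% c(1, 2, 4)) stop("'split' must be 1, 2 or 4")
  structure(list(sigma = sigma, stage_iters = stage_iters,
                 truncation_radius = truncation_radius, seed = seed,
                 split = split),
            class = "approx_config")
}

# Integer cube index per particle: half-open cubes [k*sigma, (k+1)*sigma)
# anchored at the bounding-box minimum.
cube_index <- function(positions, sigma, origin = NULL) {
  if (is.null(origin)) origin <- apply(positions, 2L, min)
  idx <- floor(sweep(positions, 2L, origin, `-`) / sigma)
  list(key = paste(idx[, 1], idx[, 2], idx[, 3], sep = "_"), idx = idx,
       origin = origin)
}

#' Lattice initialization of a reduced particle set
#'
#' One particle per occupied cube of edge sigma: its position is a randomly
#' selected (seeded) high-resolution particle inside the cube, its weight the
#' cube's total mass, and its feature distribution uniform.
#'
#' @param mu High-resolution `particle_measure` (non-empty).
#' @param cfg An [approx_config()].
#' @return A `particle_measure` of one particle per occupied cube.
#' @export
init_lattice <- function(mu, cfg) {
  if (n_particles(mu) == 0L) stop("'mu' must be non-empty")
  ci <- cube_index(mu$positions, cfg$sigma)
  keys <- unique(ci$key)
  set.seed(cfg$seed)
  nf <- length(mu$feature_space$labels)
  pos <- matrix(0, length(keys), 3L)
  wts <- numeric(length(keys))
  groups <- split(seq_len(n_particles(mu)), ci$key)
  groups <- groups[keys]  # preserve first-occurrence cube order
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    pick <- if (length(g) == 1L) g else g[sample.int(length(g), 1L)]
    pos[k, ] <- mu$positions[pick, ]
    wts[k] <- sum(mu$weights[g])
  }
  particle_measure(pos, wts, matrix(1 / nf, length(keys), nf),
                   mu$feature_space)
}

# Varifold distance^2 between (pos, w, p) and a fixed high-res measure, plus
# analytic gradients w.r.t. pos, w and p.  Identity feature kernel; single
# scale sigma with optional truncation.
approx_objective <- function(pos, w, p, mu, kernel, self_mu) {
  d2aa <- cross_dist2(pos, pos)
  kaa <- spatial_kernel(d2aa, kernel)
  d2ab <- cross_dist2(pos, mu$positions)
  kab <- spatial_kernel(d2ab, kernel)
  faa <- tcrossprod(p)
  fab <- tcrossprod(p, mu$feature_probs)
  waa <- outer(w, w)
  wab <- outer(w, mu$weights)
  val <- sum(waa * kaa * faa) - 2 * sum(wab * kab * fab) + self_mu
  # gradients (identity feature kernel; exact-Gaussian derivative also used
  # for truncated kernels, where zeroed entries simply drop out)
  gaa <- kaa * faa
  gab <- kab * fab
  gw <- 2 * as.numeric(gaa %*% w) - 2 * as.numeric(gab %*% mu$weights)
  gp <- 2 * ((waa * kaa) %*% p) - 2 * ((wab * kab) %*% mu$feature_probs)
  # dK/dx_i needs per-component sigma; recompute component-wise
  gx_acc <- matrix(0, nrow(pos), 3L)
  for (c in seq_along(kernel$sigmas)) {
    s2 <- kernel$sigmas[c]^2
    eaa <- kernel$amplitudes[c] * exp(-d2aa / (2 * s2))
    eab <- kernel$amplitudes[c] * exp(-d2ab / (2 * s2))
    if (!is.null(kernel$truncation)) {
      eaa[d2aa > (kernel$truncation * kernel$sigmas[c])^2] <- 0
      eab[d2ab > (kernel$truncation * kernel$sigmas[c])^2] <- 0
    }
    caa <- waa * faa * eaa / s2
    cab <- wab * fab * eab / s2
    for (d in 1:3) {
      xdaa <- outer(pos[, d], pos[, d], `-`)
      xdab <- outer(pos[, d], mu$positions[, d], `-`)
      gx_acc[, d] <- gx_acc[, d] - 2 * rowSums(caa * xdaa) +
        2 * rowSums(cab * xdab)
    }
  }
  list(value = val, gw = gw, gp = gp, gx = gx_acc)
}

#' Optimized fixed-complexity approximation of a particle measure
#'
#' Finds the reduced particle measure closest to a high-resolution measure in
#' the varifold norm at scale sigma.  Stage 1 holds positions at the lattice
#' initialization and optimizes weights and feature distributions; stage 2
#' optimizes positions, weights and distributions jointly.  Weight
#' positivity uses a softplus parameterization and the feature simplex a
#' row-softmax; gradients are analytic.
#'
#' @param mu High-resolution `particle_measure`.
#' @param cfg An [approx_config()].
#' @return A list of class `approx_result`: `approx` (the reduced
#'   `particle_measure`), `distance_trace` (accepted objective values across
#'   both stages), `displacement` (per-particle distance moved from the
#'   initialization), and `init` (the lattice initialization).
#' @export
optimize_approximation <- function(mu, cfg) {
  if (cfg$split > 1) return(split_approximation(mu, cfg))
  kernel <- kernel_spec(cfg$sigma, truncation = cfg$truncation_radius)
  init <- init_lattice(mu, cfg)
  self_mu <- inner_product(mu, mu, kernel)
  nr <- n_particles(init)
  nf <- length(mu$feature_space$labels)

  pack_free <- function(w, p) c(softplus_inv(w), as.numeric(log(pmax(p, 1e-12))))
  unpack_wp <- function(q) {
    w <- softplus(q[seq_len(nr)])
    p <- row_softmax(matrix(q[nr + seq_len(nr * nf)], nr, nf))
    list(w = w, p = p)
  }
  grad_wp <- function(q, wp, gw, gp) {
    # chain rule through softplus and row-softmax
    dq_w <- gw * sigmoid(q[seq_len(nr)])
    gsum <- rowSums(gp * wp$p)
    dq_p <- wp$p * (gp - gsum)
    c(dq_w, as.numeric(dq_p))
  }

  # stage 1: weights + distributions, positions fixed
  pos <- init$positions
  q0 <- pack_free(init$weights, init$feature_probs)
  cache <- new.env(parent = emptyenv())
  eval1 <- function(q) {
    wp <- unpack_wp(q)
    o <- approx_objective(pos, wp$w, wp$p, mu, kernel, self_mu)
    cache$o <- o; cache$wp <- wp
    o$value
  }
  gr1 <- function(q) {
    if (is.null(cache$o)) eval1(q)
    grad_wp(q, cache$wp, cache$o$gw, cache$o$gp)
  }
  s1 <- minimize_lbfgs(q0, eval1, gr = function(q) { eval1(q); gr1(q) },
                       maxit = cfg$stage_iters)
  wp1 <- unpack_wp(s1$par)

  # stage 2: joint over positions, weights, distributions
  eval2 <- function(q) {
    pos2 <- matrix(q[seq_len(3 * nr)], nr, 3L)
    wp <- unpack_wp(q[-seq_len(3 * nr)])
    o <- approx_objective(pos2, wp$w, wp$p, mu, kernel, self_mu)
    cache$o2 <- o; cache$wp2 <- wp
    o$value
  }
  gr2 <- function(q) {
    eval2(q)
    c(as.numeric(cache$o2$gx),
      grad_wp(q[-seq_len(3 * nr)], cache$wp2, cache$o2$gw, cache$o2$gp))
  }
  q2 <- c(as.numeric(pos), pack_free(wp1$w, wp1$p))
  s2 <- minimize_lbfgs(q2, eval2, gr = gr2, maxit = cfg$stage_iters)
  pos_f <- matrix(s2$par[seq_len(3 * nr)], nr, 3L)
  wpf <- unpack_wp(s2$par[-seq_len(3 * nr)])

  approx <- particle_measure(pos_f, wpf$w, wpf$p, mu$feature_space)
  structure(list(approx = approx,
                 distance_trace = cummin(c(s1$trace, s2$trace)),
                 displacement = sqrt(rowSums((pos_f - init$positions)^2)),
                 init = init),
            class = "approx_result")
}

split_approximation <- function(mu, cfg) {
  blocks <- list(seq_len(n_particles(mu)))
  n_cuts <- if (cfg$split == 2) 1L else 2L
  for (cut in seq_len(n_cuts)) {
    blocks <- unlist(lapply(blocks, function(ix) {
      pos <- mu$positions[ix, , drop = FALSE]
      ax <- which.max(apply(pos, 2L, function(v) diff(range(v))))
      med <- wtd_median(pos[, ax], mu$weights[ix])
      list(ix[pos[, ax] < med], ix[pos[, ax] >= med])
    }), recursive = FALSE)
  }
  sub_cfg <- cfg; sub_cfg$split <- 1
  parts <- lapply(Filter(length, blocks), function(ix)
    optimize_approximation(subset_particles(mu, ix), sub_cfg))
  structure(list(approx = bind_measures(lapply(parts, `[[`, "approx")),
                 distance_trace = do.call(c, lapply(parts, `[[`, "distance_trace")),
                 displacement = do.call(c, lapply(parts, `[[`, "displacement")),
                 init = bind_measures(lapply(parts, `[[`, "init"))),
            class = "approx_result")
}

wtd_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' @export
print.approx_result <- function(x, ...) {
  cat(sprintf("<approx_result> %d particles, final distance^2 = %.6g, mean displacement = %.3g um\n",
              n_particles(x$approx), utils::tail(x$distance_trace, 1L),
              mean(x$displacement)))
  invisible(x)
}

#' K-means baseline aggregation (Lloyd's algorithm)
#'
#' Clusters particle positions with Lloyd's algorithm; the reduced measure
#' has the cluster centroids as positions and per-cluster summed masses per
#' feature as weights and distributions.  Spatial-only clustering: the
#' comparison baseline for [optimize_approximation()].
#'
#' @param mu A `particle_measure`.
#' @param K Number of clusters (<= N).
#' @param seed Seed for the random initial centers (a particle subset).
#' @return A `particle_measure` with at most `K` particles (empty clusters
#'   are dropped with a warning).
#' @export
kmeans_baseline <- function(mu, K, seed = 1) {
  n <- n_particles(mu)
  if (K > n) stop("'K' must be <= the number of particles")
  set.seed(seed)
  centers <- mu$positions[sample.int(n, K), , drop = FALSE]
  km <- tryCatch(
    stats::kmeans(mu$positions, centers = centers, iter.max = 100,
                  algorithm = "Lloyd"),
    error = function(e) stats::kmeans(mu$positions, centers = centers,
                                      iter.max = 100, algorithm = "MacQueen"))
  agg_measure_by(mu, km$cluster, km$centers, K)
}

agg_measure_by <- function(mu, assign, centers, K) {
  nf <- length(mu$feature_space$labels)
  wts <- numeric(K); probs <- matrix(0, K, nf)
  for (k in seq_len(K)) {
    ix <- which(assign == k)
    if (!length(ix)) next
    wts[k] <- sum(mu$weights[ix])
    probs[k, ] <- colSums(mu$feature_probs[ix, , drop = FALSE] * mu$weights[ix]) /
      wts[k]
  }
  keep <- wts > 0
  if (any(!keep)) warning(sum(!keep), " empty cluster(s) dropped")
  particle_measure(centers[keep, , drop = FALSE], wts[keep],
                   probs[keep, , drop = FALSE], mu$feature_space)
}

#' Grid (kernel redistribution) baseline aggregation
#'
#' Places reduced particles at the centers of occupied cubes of edge sigma
#' and redistributes each high-resolution particle's mass over the centers
#' with Gaussian weights of bandwidth sigma, normalized per particle so
#' total mass is conserved.
#'
#' @param mu A `particle_measure`.
#' @param sigma Cube edge and redistribution bandwidth (micrometers).
#' @return A `particle_measure` on the occupied-cube centers.
#' @export
grid_baseline <- function(mu, sigma) {
  if (sigma <= 0) stop("'sigma' must be > 0")
  ci <- cube_index(mu$positions, sigma)
  keys <- unique(ci$key)
  idx_u <- ci$idx[match(keys, ci$key), , drop = FALSE]
  centers <- sweep((idx_u + 0.5) * sigma, 2L, ci$origin, `+`)
  g <- exp(-cross_dist2(mu$positions, centers) / (2 * sigma^2))
  g <- g / rowSums(g)
  wg <- g * mu$weights                         # N x C mass allocations
  wts <- colSums(wg)
  probs <- crossprod(wg, mu$feature_probs)     # C x F
  probs <- sweep(probs, 1L, ifelse(wts > 0, wts, 1), `/`)
  keep <- wts > 0
  particle_measure(centers[keep, , drop = FALSE], wts[keep],
                   probs[keep, , drop = FALSE], mu$feature_space)
}
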