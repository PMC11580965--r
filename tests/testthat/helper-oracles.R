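# Shared fixtures and independent brute-force oracles.  Oracles deliberately
# use plain element loops so they share no code path with the vectorized
# implementations they check.

random_measure <- function(n, nf = 3, extent = 10, seed = NULL, planar = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  fs <- feature_space(paste0("f", seq_len(nf)))
  pos <- matrix(stats::runif(n * 3, 0, extent), n, 3)
  if (planar) pos[, 3] <- 0
  p <- matrix(stats::rexp(n * nf), n, nf)
  p <- p / rowSums(p)
  particle_measure(pos, stats::runif(n, 0.5, 2), p, fs)
}

naive_inner_product <- function(mu, nu, kernel) {
  total <- 0
  for (i in seq_len(n_particles(mu))) for (j in seq_len(n_particles(nu))) {
    d2 <- sum((mu$positions[i, ] - nu$positions[j, ])^2)
    k <- 0
    for (c in seq_along(kernel$sigmas))
      k <- k + kernel$amplitudes[c] * exp(-d2 / (2 * kernel$sigmas[c]^2))
    fsum <- 0
    for (f in seq_along(mu$feature_space$labels))
      fsum <- fsum + mu$feature_probs[i, f] * nu$feature_probs[j, f]
    total <- total + mu$weights[i] * nu$weights[j] * k * fsum
  }
  as.numeric(total)
}

naive_velocity <- function(points, state, kernel) {
  v <- matrix(0, nrow(points), 3)
  for (m in seq_len(nrow(points))) for (i in seq_len(nrow(state$x))) {
    for (c in seq_along(kernel$sigmas)) {
      s2 <- kernel$sigmas[c]^2
      k <- kernel$amplitudes[c] * exp(-sum((points[m, ] - state$x[i, ])^2) / (2 * s2))
      v[m, ] <- v[m, ] + k * state$rx[i, ] +
        (points[m, ] - state$x[i, ]) / s2 * state$w[i] * state$rw[i] * k
    }
  }
  v
}

# Exhaustive enumeration of Omega = megasquares x squares x directions for
# the conditional mutual-information score.
naive_mi <- function(bins, K, support = NULL, min_support_frac = 0.5) {
  side <- 2L * K
  nx <- nrow(bins); ny <- ncol(bins)
  draws <- list()
  for (cx in seq_len(nx - side + 1L)) for (cy in seq_len(ny - side + 1L)) {
    if (!is.null(support) &&
        mean(support[cx:(cx + side - 1), cy:(cy + side - 1)]) < min_support_frac) next
    cid <- paste(cx, cy)
    for (i in seq_len(side)) for (j in seq_len(side)) for (d in c("h", "v")) {
      x <- if (d == "h") { if (i <= K) "l" else "r" } else { if (j <= K) "b" else "t" }
      m <- bins[cx + i - 1L, cy + j - 1L]
      draws[[length(draws) + 1L]] <- c(cid, x, m)
    }
  }
  df <- as.data.frame(do.call(rbind, draws), stringsAsFactors = FALSE)
  names(df) <- c("c", "x", "m")
  n <- nrow(df)
  total <- 0
  for (cc in unique(df$c)) {
    sub <- df[df$c == cc, ]
    pc <- nrow(sub) / n
    for (xx in unique(sub$x)) for (mm in unique(sub$m)) {
      pxm <- mean(sub$x == xx & sub$m == mm)
      if (pxm == 0) next
      px <- mean(sub$x == xx); pm <- mean(sub$m == mm)
      total <- total + pc * pxm * log(pxm / (px * pm))
    }
  }
  total
}
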