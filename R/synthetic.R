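#' Toy cross-modality matching pair: three-region atlas vs black/white target
#'
#' A square atlas parcelled into three rectangular regions and a molecular
#' target over two features laid out on the same square so that homogeneous
#' regions correspond only under a half-turn of the atlas: the top band of
#' the atlas maps onto the target's dark bottom band under a 180-degree
#' rotation, and the two lower atlas rectangles map onto all-light areas.
#' At 0, 90, or 270 degrees every candidate layout leaves at least one
#' region straddling both target features.  Both measures live on the same
#' lattice, so their total masses agree by construction.
#'
#' @param n_side Lattice points per side (default 16).
#' @param extent Square side length (micrometers, default 60).
#' @return A list: `atlas` (an [atlas_latent_model()] over regions R, G, B
#'   with laws unset), `target` (a `particle_measure` over features B, W),
#'   `extent`.
#' @export
make_fig2_toy <- function(n_side = 16, extent = 60) {
  h <- extent / n_side
  ctr <- seq(h / 2, extent - h / 2, by = h)
  gridpts <- as.matrix(expand.grid(x = ctr, y = ctr))
  n <- nrow(gridpts)
  region <- ifelse(gridpts[, 2] > 2 / 3 * extent, "R",
                   ifelse(gridpts[, 1] <= extent / 2, "G", "B"))
  region_fs <- feature_space(c("R", "G", "B"))
  pi_mat <- matrix(0, n, 3L)
  pi_mat[cbind(seq_len(n), match(region, region_fs$labels))] <- 1
  atlas <- particle_measure(cbind(gridpts, 0), rep(1, n), pi_mat, region_fs)
  target_fs <- feature_space(c("B", "W"))
  dark <- gridpts[, 2] < 1 / 3 * extent
  probs <- cbind(as.numeric(dark), as.numeric(!dark))
  target <- particle_measure(cbind(gridpts, 0), rep(1, n), probs, target_fs)
  list(atlas = atlas_latent_model(atlas, target_fs), target = target,
       extent = extent)
}

#' Synthetic atlas/target pair under a known analytic warp
#'
#' Builds a seeded random particle cloud and warps it with an analytic
#' diffeomorphism whose Jacobian determinant is known in closed form; the
#' target carries the Jacobian-scaled weights of the varifold action.  Used
#' for parameter-recovery tests of the mapping modules.
#'
#' @param n Number of particles (default 20).
#' @param extent Cloud extent per axis (micrometers, default 40).
#' @param warp `"identity"`, `"translation"`, or `"radial"`
#'   (\eqn{x \mapsto c + (x - c)(1 + \epsilon r)}, \eqn{r = |x - c|}, with
#'   Jacobian determinant \eqn{(1 + 2\epsilon r)(1 + \epsilon r)^2}).
#' @param translation Length-3 shift for `warp = "translation"`.
#' @param epsilon Radial expansion rate (1/micrometers); must satisfy
#'   \eqn{1 + 2\epsilon r > 0} over the support.
#' @param center Center of the radial warp; defaults to the cloud centroid.
#' @param n_features Number of feature labels (default 2), assigned by
#'   spatial octant so features carry geometric information.
#' @param planar If `TRUE`, particles lie in the z = 0 plane.
#' @param seed Integer seed.
#' @return A list: `mu` (atlas), `nu` (warped target), `transform` (the
#'   ground-truth [point_transform()]).
#' @export
make_warped_pair <- function(n = 20, extent = 40,
                             warp = c("identity", "translation", "radial"),
                             translation = c(0, 0, 0), epsilon = 0.002,
                             center = NULL, n_features = 2, planar = FALSE,
                             seed = 1) {
  warp <- match.arg(warp)
  set.seed(seed)
  pos <- matrix(stats::runif(n * 3, 0, extent), n, 3L)
  if (planar) pos[, 3] <- 0
  fs <- feature_space(paste0("f", seq_len(n_features)))
  grp <- 1L + (pos[, 1] > stats::median(pos[, 1]))
  if (n_features > 2) grp <- 1L + (grp - 1L) + 2L * (pos[, 2] > stats::median(pos[, 2]))
  grp <- pmin(grp, n_features)
  probs <- matrix(0, n, n_features)
  probs[cbind(seq_len(n), grp)] <- 1
  mu <- particle_measure(pos, stats::runif(n, 0.8, 1.2), probs, fs)
  tr <- switch(warp,
    identity = identity_transform(mu),
    translation = point_transform(sweep(pos, 2L, translation, `+`)),
    radial = {
      if (is.null(center)) center <- colMeans(pos)
      d <- sweep(pos, 2L, center, `-`)
      r <- sqrt(rowSums(d^2))
      if (any(1 + 2 * epsilon * r <= 0))
        stop("radial warp is not a diffeomorphism on the support (1 + 2*eps*r <= 0)")
      point_transform(sweep(d * (1 + epsilon * r), 2L, center, `+`),
                      (1 + 2 * epsilon * r) * (1 + epsilon * r)^2)
    })
  list(mu = mu, nu = apply_diffeo(tr, mu), transform = tr)
}

#' Synthetic serial-section stack with known jitter and censoring
#'
#' Samples sections from a 3D phantom of concentric square regions, keeps a
#' central fraction of the stacking axis (rostral/caudal truncation),
#' optionally truncates one hemisphere at the midline, and applies known
#' rigid jitter to the interior sections (endpoints fixed, matching the
#' alignment convention).
#'
#' @param n_sections Sections in the (untruncated) stack (default 5).
#' @param spacing Inter-section distance (micrometers, default 100).
#' @param points_per_section Detections sampled per section (default 150).
#' @param extent Section side length (micrometers, default 100).
#' @param kept_fraction Fraction of the stacking axis retained, centered
#'   (default 1 = no truncation).
#' @param hemi If `TRUE`, drop detections with x beyond the midline.
#' @param jitter_theta,jitter_tau Max |rotation| (radians) and |translation|
#'   (micrometers) of the per-section jitter (default 0 = none).
#' @param shared_points If `TRUE` (default), all sections share one sampled
#'   point constellation, so the injected jitter is exactly recoverable;
#'   if `FALSE` each section is sampled independently.
#' @param seed Integer seed.
#' @return A list: `stack` (a [section_stack()] with jitter applied),
#'   `truth` (data frame `theta`, `tx`, `ty` of the injected motions),
#'   `support` (list with `z_range` kept and `hemi_x` midline or `NA`).
#' @export
make_censored_stack <- function(n_sections = 5, spacing = 100,
                                points_per_section = 150, extent = 100,
                                kept_fraction = 1, hemi = FALSE,
                                jitter_theta = 0, jitter_tau = 0,
                                shared_points = TRUE, seed = 1) {
  if (kept_fraction <= 0 || kept_fraction > 1)
    stop("'kept_fraction' must be in (0, 1]")
  set.seed(seed)
  fs <- feature_space(c("core", "ring", "rim"))
  z_all <- (seq_len(n_sections) - 1) * spacing
  z_mid <- mean(range(z_all))
  half_span <- diff(range(z_all)) / 2 * kept_fraction
  keep <- abs(z_all - z_mid) <= half_span + 1e-9
  kept_z <- z_all[keep]
  n_kept <- length(kept_z)
  if (n_kept < 2L) stop("truncation leaves fewer than 2 sections")
  theta <- numeric(n_kept); tau <- matrix(0, n_kept, 2L)
  if (n_kept > 2L) {
    interior <- 2:(n_kept - 1L)
    theta[interior] <- stats::runif(length(interior), -jitter_theta, jitter_theta)
    tau[interior, ] <- stats::runif(2L * length(interior), -jitter_tau, jitter_tau)
  }
  sample_xy <- function() matrix(stats::runif(points_per_section * 2,
                                              -extent / 2, extent / 2), ncol = 2L)
  xy_shared <- sample_xy()
  sections <- vector("list", n_kept)
  for (k in seq_len(n_kept)) {
    xy <- if (shared_points) xy_shared else sample_xy()
    if (hemi) xy <- xy[xy[, 1] <= 0, , drop = FALSE]
    # rings off-center so the feature field itself is rotationally asymmetric
    rad <- pmax(abs(xy[, 1] - extent / 8), abs(xy[, 2] + extent / 12))
    lab <- ifelse(rad < extent / 6, "core",
                  ifelse(rad < extent / 3, "ring", "rim"))
    probs <- matrix(0, nrow(xy), 3L)
    probs[cbind(seq_len(nrow(xy)), match(lab, fs$labels))] <- 1
    sec <- particle_measure(cbind(xy, kept_z[k]), rep(1, nrow(xy)), probs, fs)
    sections[[k]] <- transform_section(sec, theta[k], tau[k, ], "z")
  }
  list(stack = section_stack(sections, spacing, axis = "z"),
       truth = data.frame(theta = theta, tx = tau[, 1], ty = tau[, 2]),
       support = list(z_range = range(kept_z), hemi_x = if (hemi) 0 else NA))
}
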