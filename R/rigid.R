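#' Stack of serial 2D sections
#'
#' An ordered stack of particle measures, each restricted to a single plane
#' perpendicular to the stacking axis, with uniform inter-section spacing.
#'
#' @param sections List of >= 2 `particle_measure` objects sharing one
#'   feature space; each section's coordinates along `axis` should be
#'   constant (the section plane).
#' @param spacing Inter-section distance (micrometers, > 0).
#' @param axis Stacking axis: `"z"` (default), `"x"`, or `"y"`.
#' @return An object of class `section_stack`.
#' @export
section_stack <- function(sections, spacing, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  if (!is.list(sections) || length(sections) < 2L)
    stop("a section stack needs at least 2 sections")
  for (s in sections) if (!inherits(s, "particle_measure"))
    stop("every section must be a particle_measure")
  fs <- sections[[1]]$feature_space
  for (s in sections) if (!same_feature_space(fs, s$feature_space))
    stop("all sections must share one feature space")
  if (spacing <= 0) stop("'spacing' must be > 0")
  structure(list(sections = sections, spacing = spacing, axis = axis),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf("<section_stack> %d sections along %s, spacing %g um, N = %s\n",
              length(x$sections), x$axis, x$spacing,
              paste(vapply(x$sections, n_particles, integer(1)), collapse = "/")))
  invisible(x)
}

inplane_axes <- function(axis) setdiff(1:3, match(axis, c("x", "y", "z")))

#' Center each section at its in-plane mass centroid
#'
#' Translates every section so that its mass-weighted centroid lies at the
#' in-plane origin; the stacking-axis coordinate is untouched.  Empty
#' sections are skipped with a warning.
#'
#' @param stack A [section_stack()].
#' @return The centered `section_stack`.
#' @export
center_sections <- function(stack) {
  ax <- inplane_axes(stack$axis)
  stack$sections <- lapply(seq_along(stack$sections), function(i) {
    s <- stack$sections[[i]]
    if (n_particles(s) == 0L) {
      warning("section ", i, " is empty; left untouched")
      return(s)
    }
    ctr <- colSums(s$positions[, ax, drop = FALSE] * s$weights) / total_mass(s)
    s$positions[, ax] <- sweep(s$positions[, ax, drop = FALSE], 2L, ctr, `-`)
    s
  })
  stack
}

#' Per-section rigid motions
#'
#' @param theta Numeric vector of in-plane rotation angles (radians), one per
#'   section; first and last must be 0.
#' @param tau N x 2 matrix of in-plane translations; first and last rows must
#'   be zero.
#' @return An object of class `rigid_params`.
#' @export
rigid_params <- function(theta, tau) {
  tau <- as.matrix(tau)
  if (length(theta) != nrow(tau) || ncol(tau) != 2L)
    stop("'theta' and 'tau' must have one entry per section, tau being N x 2")
  n <- length(theta)
  if (abs(theta[1]) > 0 || abs(theta[n]) > 0 || any(abs(tau[c(1, n), ]) > 0))
    stop("first and last sections are fixed at zero motion")
  structure(list(theta = theta, tau = tau), class = "rigid_params")
}

#' @export
print.rigid_params <- function(x, ...) {
  cat(sprintf("<rigid_params> %d sections, max |theta| = %.4g rad, max |tau| = %.4g\n",
              length(x$theta), max(abs(x$theta)), max(abs(x$tau))))
  invisible(x)
}

# Apply an in-plane rotation + translation to one section.
transform_section <- function(section, theta, tau, axis) {
  ax <- inplane_axes(axis)
  p <- section$positions[, ax, drop = FALSE]
  ct <- cos(theta); st <- sin(theta)
  section$positions[, ax] <-
    cbind(ct * p[, 1] - st * p[, 2] + tau[1],
          st * p[, 1] + ct * p[, 2] + tau[2])
  section
}

#' Apply per-section rigid motions to a stack
#' @param stack A [section_stack()].
#' @param params A [rigid_params()].
#' @return The transformed `section_stack`.
#' @export
apply_rigid <- function(stack, params) {
  if (length(params$theta) != length(stack$sections))
    stop("params and stack have different section counts")
  stack$sections <- lapply(seq_along(stack$sections), function(i)
    transform_section(stack$sections[[i]], params$theta[i], params$tau[i, ],
                      stack$axis))
  stack
}

# Eq.-style pairwise objective: sum over adjacent pairs of the squared
# varifold distance, computed in the 2D section plane.
rigid_objective <- function(stack, params, kernel) {
  ax <- inplane_axes(stack$axis)
  planar <- lapply(seq_along(stack$sections), function(i) {
    s <- transform_section(stack$sections[[i]], params$theta[i],
                           params$tau[i, ], stack$axis)
    pos <- s$positions
    pos[, setdiff(1:3, ax)] <- 0
    particle_measure(pos, s$weights, s$feature_probs, s$feature_space)
  })
  total <- 0
  for (i in seq_len(length(planar) - 1L))
    total <- total + norm_distance_sq(planar[[i]], planar[[i + 1L]], kernel)
  total
}

#' Rigid alignment of a section stack
#'
#' Estimates an in-plane rotation and translation for every interior section
#' (the first and last are fixed) by minimizing the summed pairwise varifold
#' distance between adjacent sections with quasi-Newton iterations from the
#' zero initialization.  Sections should be centered (see
#' [center_sections()]) first.
#'
#' @param stack A [section_stack()] with >= 3 sections.
#' @param kernel Matching [kernel_spec()] (Gaussian spatial kernel, identity
#'   feature kernel).
#' @param maxit L-BFGS iterations (default 500).
#' @param multi_start If `TRUE`, each interior section's rotation is also
#'   started from 90/180/270 degrees and the best basin kept (guards against
#'   gross flips; default `FALSE`).
#' @return A `rigid_params` object with attributes `objective` (at the
#'   optimum) and `objective_zero` (at the zero initialization).
#' @export
align_stack <- function(stack, kernel, maxit = 500, multi_start = FALSE) {
  n <- length(stack$sections)
  if (n < 3L) stop("rigid alignment needs at least 3 sections")
  interior <- 2:(n - 1L)
  unpack <- function(p) {
    theta <- numeric(n); tau <- matrix(0, n, 2L)
    theta[interior] <- p[seq_along(interior)]
    tau[interior, ] <- matrix(p[-seq_along(interior)], length(interior), 2L)
    rigid_params(theta, tau)
  }
  fn <- function(p) rigid_objective(stack, unpack(p), kernel)
  starts <- list(rep(0, 3L * length(interior)))
  if (multi_start) {
    for (ang in c(pi / 2, pi, 3 * pi / 2))
      starts <- c(starts, list(c(rep(ang, length(interior)),
                                 rep(0, 2L * length(interior)))))
  }
  best <- NULL
  for (p0 in starts) {
    r <- minimize_lbfgs(p0, fn, maxit = maxit, fd_step = 1e-7, central = TRUE)
    if (is.null(best) || r$value < best$value) best <- r
  }
  out <- unpack(best$par)
  attr(out, "objective") <- best$value
  attr(out, "objective_zero") <- fn(rep(0, 3L * length(interior)))
  attr(out, "trace") <- best$trace
  out
}

#' Write rigid parameters to CSV
#' @param params A [rigid_params()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rigid <- function(params, path) {
  utils::write.csv(data.frame(section_index = seq_along(params$theta),
                              theta_rad = params$theta,
                              tx = params$tau[, 1], ty = params$tau[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read rigid parameters from CSV
#' @param path CSV written by [write_rigid()].
#' @return A `rigid_params` object.
#' @export
read_rigid <- function(path) {
  df <- utils::read.csv(path)
  rigid_params(df$theta_rad, cbind(df$tx, df$ty))
}
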