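#' Cross-modality mapping with latent feature laws and censoring
#'
#' Jointly estimates (subsets of) the diffeomorphic flow momenta, a global
#' similitude, the per-region latent feature laws, and the censor bandwidth
#' by minimizing
#' \deqn{H(q_0, \rho_0) + \sum_\ell J_{KL}(p_\ell) +
#'   \|\alpha_\lambda(\varphi_1\cdot\mu_A^p) - \mu_T\|_M^2 + J_s(\lambda),}
#' where the kinetic term is the conserved Hamiltonian, the KL prior weights
#' each region by its share of deformed (censored) atlas mass, and the
#' censor term is present only when a censor is supplied.  Positivity of the
#' laws is maintained by an elementwise softplus parameterization.
#'
#' @param latent An [atlas_latent_model()]; its laws (if set) serve as the
#'   initialization, otherwise laws start uniform with total mass matched to
#'   the target.
#' @param target `particle_measure` over `latent$feature_space`.
#' @param v_kernel,m_kernel Velocity and matching [kernel_spec()] objects.
#' @param censor Optional censor ([planar_censor()], `mlp_censor`, function,
#'   or `NULL`), defined in target coordinates.
#' @param similitude Fixed [similitude_params()] applied to the atlas before
#'   the flow (default identity).
#' @param estimate_deformation Estimate flow momenta (default `TRUE`; set
#'   `FALSE` to fit laws under frozen geometry).
#' @param estimate_laws Estimate the latent laws (default `TRUE`).
#' @param estimate_lambda Estimate the censor bandwidth jointly (default:
#'   `TRUE` whenever a censor with a `lambda` field is supplied).
#' @param data_weight Multiplier on the matching term (default 1).
#' @param n_steps,maxit Integrator steps and L-BFGS iterations.
#' @return A list of class `varimap_crossfit`: `control`, `similitude`,
#'   `latent` (laws estimated; see [normalized_laws()]), `lambda`, `value`,
#'   `trace`, and `endpoint` (deformed, censored induced measure).
#' @export
fit_crossmodality_map <- function(latent, target, v_kernel, m_kernel,
                                  censor = NULL,
                                  similitude = similitude_params(),
                                  estimate_deformation = TRUE,
                                  estimate_laws = TRUE,
                                  estimate_lambda = NULL,
                                  data_weight = 1, n_steps = 10, maxit = 150) {
  if (!inherits(latent, "atlas_latent_model")) stop("'latent' must be an atlas_latent_model")
  if (n_particles(target) == 0L) stop("'target' is empty")
  if (!same_feature_space(latent$feature_space, target$feature_space))
    stop("target features must live on the latent model's feature space")
  censor_lambda <- if (!is.null(censor) && !is.function(censor))
    censor$lambda else NULL
  if (is.null(estimate_lambda))
    estimate_lambda <- !is.null(censor_lambda)
  atlas0 <- apply_similitude(similitude, latent$atlas)
  n <- n_particles(atlas0)
  nl <- length(atlas0$feature_space$labels)
  nf <- length(latent$feature_space$labels)
  tt <- inner_product(target, target, m_kernel)
  target_mass <- total_mass(target)

  laws0 <- latent$laws
  if (is.null(laws0))
    laws0 <- matrix(target_mass / max(total_mass(atlas0), 1e-12) / nf, nl, nf)
  lam0 <- censor_lambda

  # parameter layout: [momenta (4n) | law free vars (nl*nf) | log lambda]
  n_mom <- if (estimate_deformation) 4L * n else 0L
  n_law <- if (estimate_laws) nl * nf else 0L
  p0 <- c(if (estimate_deformation) rep(0, n_mom),
          if (estimate_laws) softplus_inv(as.numeric(laws0)),
          if (estimate_lambda) log(lam0))

  evaluate <- function(p, detail = FALSE) {
    kin <- 0
    if (estimate_deformation) {
      ctrl <- geodesic_control(matrix(p[1:(3 * n)], n, 3L),
                               p[(3 * n + 1):(4 * n)], v_kernel)
      path <- tryCatch(shoot(ctrl, atlas0, n_steps = n_steps),
                       error = function(e) NULL)
      if (is.null(path)) {
        if (detail) stop("geodesic integration diverged at the returned optimum")
        return(1e10)
      }
      deformed <- endpoint_measure(path)  # still over the region ontology
      kin <- path$hamiltonian_trace[1]
    } else {
      ctrl <- zero_control(atlas0, v_kernel)
      deformed <- atlas0
    }
    laws <- if (estimate_laws)
      matrix(softplus(p[n_mom + seq_len(n_law)]), nl, nf) else laws0
    lam <- if (estimate_lambda) exp(p[n_mom + n_law + 1L]) else lam0
    alpha <- if (is.null(censor)) rep(1, n_particles(deformed)) else
      pmin(pmax(censor_weights(censor, deformed$positions, lambda = lam), 0), 1)
    if (!is.null(censor) && max(alpha) < 1e-6)
      stop("censor weights vanish on the entire deformed atlas (degenerate fit)")
    cw <- deformed$weights * alpha
    lmodel <- atlas_latent_model(
      particle_measure(deformed$positions, cw, deformed$feature_probs,
                       deformed$feature_space),
      latent$feature_space, laws)
    region_masses <- as.numeric(crossprod(deformed$feature_probs, cw))
    induced <- induced_measure(lmodel)
    dterm <- inner_product(induced, induced, m_kernel) -
      2 * inner_product(induced, target, m_kernel) + tt
    klterm <- kl_prior(lmodel, region_masses = region_masses,
                       target_feature_mass = target_mass)
    sterm <- if (!is.null(censor) && estimate_lambda)
      lambda_reg(lam, unit = "um") else 0
    val <- kin + klterm + data_weight * dterm + sterm
    if (!detail) return(val)
    list(value = val, kinetic = kin, kl = klterm, data = max(dterm, 0),
         control = ctrl, laws = laws, lambda = lam, endpoint = induced)
  }

  res <- minimize_lbfgs(p0, evaluate, maxit = maxit, fd_step = 1e-6)
  fin <- evaluate(res$par, detail = TRUE)
  out_latent <- atlas_latent_model(latent$atlas, latent$feature_space, fin$laws)
  structure(list(control = fin$control, similitude = similitude,
                 latent = out_latent, lambda = fin$lambda,
                 value = fin$value, kinetic = fin$kinetic, kl = fin$kl,
                 residual = fin$data, trace = res$trace,
                 endpoint = fin$endpoint),
            class = "varimap_crossfit")
}

#' @export
print.varimap_crossfit <- function(x, ...) {
  cat(sprintf("<varimap_crossfit> objective = %.6g (kinetic %.4g, KL %.4g, data %.4g)\n",
              x$value, x$kinetic, x$kl, x$residual))
  invisible(x)
}

#' Cross-modality objective across candidate global rotations
#'
#' Rotates the atlas about its mass centroid (in the xy plane) by each
#' candidate angle, re-fits the latent feature laws at that pose under a
#' frozen identity flow, and records the minimized objective.  Used to
#' resolve gross pose ambiguity before (or instead of) estimating the
#' diffeomorphism.
#'
#' @param latent An [atlas_latent_model()].
#' @param target `particle_measure` over the latent feature space.
#' @param m_kernel Matching [kernel_spec()].
#' @param angles_deg Candidate rotations in degrees (default
#'   `c(0, 90, 180, 270)`).
#' @param maxit L-BFGS iterations per pose (default 100).
#' @param ... Passed to [fit_crossmodality_map()].
#' @return Data frame with columns `angle_deg` and `objective`, plus
#'   attribute `best` (the argmin angle).
#' @export
rotation_sweep_objective <- function(latent, target, m_kernel,
                                     angles_deg = c(0, 90, 180, 270),
                                     maxit = 100, ...) {
  ctr <- colSums(latent$atlas$positions * latent$atlas$weights) /
    total_mass(latent$atlas)
  vk <- kernel_spec(m_kernel$sigmas[1])  # unused under frozen geometry
  obj <- vapply(angles_deg, function(a) {
    th <- a * pi / 180
    rot <- rotation_z(th)
    sim <- similitude_params(rot, as.numeric(ctr - rot %*% ctr))
    fit <- fit_crossmodality_map(latent, target, v_kernel = vk,
                                 m_kernel = m_kernel, similitude = sim,
                                 estimate_deformation = FALSE,
                                 maxit = maxit, ...)
    fit$value
  }, numeric(1))
  out <- data.frame(angle_deg = angles_deg, objective = obj)
  attr(out, "best") <- angles_deg[which.min(obj)]
  out
}
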