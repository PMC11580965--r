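# Shared optimization helpers: finite-difference gradients and a traced
# L-BFGS-B wrapper.  Objectives in this package are smooth; forward
# differences with a scale-aware step are accurate enough for quasi-Newton
# line searches at the problem sizes the package targets.

numeric_gradient <- function(fn, par, ..., step = 1e-6, central = FALSE) {
  f0 <- if (central) NULL else fn(par, ...)
  g <- numeric(length(par))
  for (k in seq_along(par)) {
    h <- step * (abs(par[k]) + 1)
    pp <- par; pp[k] <- pp[k] + h
    if (central) {
      pm <- par; pm[k] <- pm[k] - h
      g[k] <- (fn(pp, ...) - fn(pm, ...)) / (2 * h)
    } else {
      g[k] <- (fn(pp, ...) - f0) / h
    }
  }
  g
}

# Quasi-Newton minimization with an objective trace of accepted values.
# Returns list(par, value, trace, convergence).
minimize_lbfgs <- function(par, fn, gr = NULL, maxit = 150, factr = 1e7,
                           fd_step = 1e-6, central = FALSE, lower = -Inf,
                           upper = Inf) {
  trace_env <- new.env(parent = emptyenv())
  trace_env$best <- Inf
  trace_env$trace <- numeric(0)
  wrapped <- function(p) {
    v <- fn(p)
    if (is.na(v)) stop("objective became NaN during optimization; trace: ",
                       paste(signif(trace_env$trace, 6), collapse = ", "))
    if (v < trace_env$best) {
      trace_env$best <- v
      trace_env$trace <- c(trace_env$trace, v)
    }
    v
  }
  if (is.null(gr))
    gr <- function(p) numeric_gradient(wrapped, p, step = fd_step, central = central)
  res <- stats::optim(par, wrapped, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = factr))
  list(par = res$par, value = res$value, trace = trace_env$trace,
       convergence = res$convergence)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))
sigmoid <- function(x) 1 / (1 + exp(-x))

row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
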