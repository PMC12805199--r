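#' Tuning configuration
#'
#' @param lambda penalty strength on the total-log-likelihood scale (>= 0).
#'   [select_model()] and the command-line front-end expose the per-respondent
#'   convenience scale `lam_user`, with `lambda = lam_user * N`.
#' @param tau TLP truncation threshold (> 0; `Inf` gives the plain fused-L1
#'   penalty).
#' @param rho ADMM penalty parameter (> 0); `NULL` defers to the solver
#'   default `N / 10`, which keeps the quadratic term commensurate with the
#'   likelihood curvature. `rho` mainly affects the convergence rate, not the
#'   solution.
#' @return list of class `tuning_config`.
#' @export
tuning_config <- function(lambda, tau, rho = NULL) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  if (!is.null(rho) && rho <= 0) stop("rho must be > 0")
  structure(list(lambda = lambda, tau = tau, rho = rho),
            class = "tuning_config")
}

#' Solver options
#'
#' @param tol convergence tolerance: the fit stops when the absolute change in
#'   every parameter (a, b, mu, sigma2, delta) between consecutive iterations
#'   is below `tol` and the DC weights are stable.
#' @param max_outer cap on DC (weight-refresh) iterations.
#' @param max_inner cap on ADMM iterations per DC iteration.
#' @param lbfgs_iters L-BFGS iteration cap per item block per M-step.
#' @param K number of Gauss-Hermite quadrature nodes per group.
#' @param seed optional integer seed recorded with the fit.
#' @param var_floor lower bound on group latent variances.
#' @param verbose 0 = silent, 1 = per-iteration diagnostics on stderr.
#' @return list of class `solver_options`.
#' @export
solver_options <- function(tol = 1e-4, max_outer = 20, max_inner = 500,
                           lbfgs_iters = 20, K = 21, seed = NULL,
                           var_floor = 1e-4, verbose = 0) {
  if (tol <= 0) stop("tol must be > 0")
  if (max_outer < 1 || max_inner < 1 || lbfgs_iters < 1) {
    stop("iteration caps must be >= 1")
  }
  structure(list(tol = tol, max_outer = max_outer, max_inner = max_inner,
                 lbfgs_iters = lbfgs_iters, K = K, seed = seed,
                 var_floor = var_floor, verbose = verbose),
            class = "solver_options")
}

# Neutral starting values: unit slopes, intercepts from pooled proportions
# correct, standard-normal impact, zeroed pair state.
.neutral_start <- function(data) {
  p <- colMeans(data$responses, na.rm = TRUE)
  p <- pmin(pmax(p, 1 / (2 * data$N)), 1 - 1 / (2 * data$N))
  a <- matrix(1, data$J, data$S)
  b <- matrix(-stats::qlogis(p), data$J, data$S)
  params <- model_params(a, b, rep(0, data$S), rep(1, data$S))
  list(params = params, pairs = init_pair_state(data$J, data$S))
}

#' Initialize the solver
#'
#' Builds the neutral start (a = 1, b from pooled proportions, standard-normal
#' impact, zero difference parameters and duals) and, when `tau` is finite,
#' warm-starts by running the full algorithm once with `tau = Inf` — the
#' fused-L1 limit, whose convex penalty makes it the easy problem — at the
#' same `lambda`. When the user already requested `tau = Inf` the L1 run and
#' the requested run would coincide, so only the neutral start is returned.
#'
#' @param data a [response_data] object.
#' @param tuning a [tuning_config].
#' @param opts a [solver_options].
#' @return list with `params`, `pairs`, and `lp_converged` (NA when no warm
#'   run was needed).
#' @export
initialize_fit <- function(data, tuning, opts = solver_options()) {
  start <- .neutral_start(data)
  if (!is.finite(tuning$tau)) {
    return(c(start, list(lp_converged = NA)))
  }
  lp_tuning <- tuning_config(tuning$lambda, Inf, tuning$rho)
  lp <- fit_single(data, lp_tuning, opts, init = start)
  if (!lp$converged) {
    warning("L1 initialization run did not converge; using its last iterate")
  }
  list(params = lp$params, pairs = lp$pairs, lp_converged = lp$converged)
}

#' Convergence check on the parameter change
#'
#' TRUE iff the maximum absolute change over all of a, b, mu, sigma2 and
#' delta is strictly below `tol`. The scaled duals are auxiliary variables
#' and are excluded; primal feasibility is monitored separately through the
#' feasibility gap.
#'
#' @param old,new lists with elements `params` ([model_params]) and `pairs`
#'   (`pair_state`).
#' @param tol tolerance (> 0).
#' @return logical flag; attribute `max_change` carries the observed maximum.
#' @export
check_convergence <- function(old, new, tol) {
  mc <- max(abs(new$params$a - old$params$a),
            abs(new$params$b - old$params$b),
            abs(new$params$mu - old$params$mu),
            abs(new$params$sigma2 - old$params$sigma2),
            abs(new$pairs$delta - old$pairs$delta))
  structure(mc < tol, max_change = mc)
}

#' Fit the penalized multi-group 2PL at one (lambda, tau)
#'
#' The workhorse: an outer difference-of-convex loop refreshes the TLP
#' majorization weights from the current difference parameters; an inner ADMM
#' loop alternates (i) one EM cycle on the augmented-Lagrangian objective —
#' E-step posteriors by quadrature, closed-form impact update, L-BFGS update
#' of every item block — (ii) the closed-form soft-threshold update of the
#' difference parameters, and (iii) the scaled-dual update. Iteration stops
#' when every parameter moves less than `opts$tol` and the weights are
#' stable, or the caps are reached.
#'
#' @param data a [response_data] object (needs S >= 2).
#' @param tuning a [tuning_config]; `lambda` on the total-likelihood scale.
#' @param opts a [solver_options].
#' @param init optional warm start (list with `params`, `pairs`); by default
#'   [initialize_fit()] is called, i.e. a fused-L1 run provides the warm
#'   start whenever `tau` is finite.
#' @return object of class `dif_fit`: `params`, `pairs` (final delta, u, w),
#'   `loglik` (unpenalized log marginal likelihood at the final parameters),
#'   `objective_trace` (penalized objective per ADMM iteration),
#'   `converged`, `iterations` (outer count and total inner count),
#'   `feasibility_gap` (max |raw difference - delta|), `tuning`, `opts`.
#' @export
fit_single <- function(data, tuning, opts = solver_options(), init = NULL) {
  if (data$S < 2) stop("need at least 2 groups")
  rho <- if (is.null(tuning$rho)) data$N / 10 else tuning$rho
  lam <- tuning$lambda
  tau <- tuning$tau
  if (is.null(init)) init <- initialize_fit(data, tuning, opts)
  params <- init$params
  pairs <- init$pairs
  pairs <- dc_weights(pairs, tau)
  trace <- numeric(0)
  converged <- FALSE
  n_outer <- 0L
  n_inner <- 0L
  for (outer in seq_len(opts$max_outer)) {
    n_outer <- outer
    w_used <- pairs$w
    inner_conv <- FALSE
    for (inner in seq_len(opts$max_inner)) {
      n_inner <- n_inner + 1L
      old <- list(params = params, pairs = pairs)
      grid <- build_quadrature(params$mu, params$sigma2, opts$K)
      es <- estep_posteriors(data, params, grid)
      imp <- mstep_impact(es$post, grid, data, var_floor = opts$var_floor)
      params <- update_items(params, es$post, grid, data, pairs, rho,
                             maxit = opts$lbfgs_iters)
      params$mu <- imp$mu
      params$sigma2 <- imp$sigma2
      diff <- .pair_diffs(params, pairs)
      pairs$delta <- delta_update(diff, pairs$u, pairs$w, lam, rho)
      pairs$u <- dual_update(pairs$u, diff, pairs$delta)
      obj <- -es$loglik + sum(tlp_value(pairs$delta, lam, tau))
      if (!is.finite(obj)) {
        stop("divergent objective at outer ", outer, ", inner ", inner,
             "; max |a| = ", max(abs(params$a)),
             ", max |b| = ", max(abs(params$b)))
      }
      trace <- c(trace, obj)
      cc <- check_convergence(old, list(params = params, pairs = pairs),
                              opts$tol)
      if (opts$verbose > 0) {
        message(sprintf(
          "outer %d inner %d obj %.4f max-change %.2e feas %.2e",
          outer, inner, obj, attr(cc, "max_change"),
          max(abs(diff - pairs$delta))))
      }
      if (cc) { inner_conv <- TRUE; break }
    }
    refreshed <- dc_weights(pairs, tau)
    w_stable <- all(refreshed$w == w_used)
    pairs <- refreshed
    if (inner_conv && w_stable) { converged <- TRUE; break }
  }
  grid <- build_quadrature(params$mu, params$sigma2, opts$K)
  loglik <- log_marginal_likelihood(data, params, grid)
  diff <- .pair_diffs(params, pairs)
  structure(
    list(params = params, pairs = pairs, loglik = loglik,
         objective_trace = trace, converged = converged,
         iterations = list(outer = n_outer, inner = n_inner),
         feasibility_gap = max(abs(diff - pairs$delta)),
         tuning = list(lambda = lam, tau = tau, rho = rho),
         opts = opts),
    class = "dif_fit"
  )
}

#' @export
print.dif_fit <- function(x, ...) {
  cat("Penalized multi-group 2PL fit\n")
  cat(sprintf("  lambda = %g, tau = %g, rho = %g\n",
              x$tuning$lambda, x$tuning$tau, x$tuning$rho))
  cat(sprintf("  loglik = %.3f, converged = %s (%d outer / %d inner)\n",
              x$loglik, x$converged, x$iterations$outer, x$iterations$inner))
  cat(sprintf("  feasibility gap = %.2e\n", x$feasibility_gap))
  invisible(x)
}
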