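#' Item response function of the 2PL model
#'
#' Probability of a correct response given latent trait `theta`, slope `a`
#' and negative intercept `b`: `plogis(a * theta - b)`. Vectorized with the
#' usual recycling rules.
#'
#' @param theta latent trait value(s).
#' @param a item slope(s).
#' @param b item negative intercept(s); the item characteristic curve crosses
#'   0.5 at `theta = b / a`.
#' @return probabilities strictly inside (0, 1).
#' @examples
#' irf(0, a = 1, b = 0)      # 0.5
#' irf(1, a = 1, b = 0)      # 0.731...
#' @export
irf <- function(theta, a, b) {
  stats::plogis(a * theta - b)
}

# log(P) and log(1-P) of the 2PL, numerically stable at extreme logits
.log_irf <- function(logit) {
  list(lp = stats::plogis(logit, log.p = TRUE),
       lq = stats::plogis(-logit, log.p = TRUE))
}

#' Per-group Gauss-Hermite quadrature grid
#'
#' Builds a K-point Gauss-Hermite rule per group, affinely transformed so the
#' nodes/weights integrate against the group's latent-trait density
#' N(mu_s, sigma2_s). Weights are renormalized to sum to one per group.
#'
#' @param mu length-S vector of group latent means.
#' @param sigma2 length-S vector of group latent variances (positive).
#' @param K number of quadrature nodes (>= 2).
#' @return Object of class `quadrature_grid`: list with `nodes` and `weights`,
#'   both S x K matrices (row s is group s), plus `K`.
#' @export
build_quadrature <- function(mu, sigma2, K = 21) {
  if (K < 2) stop("K must be >= 2")
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  S <- length(mu)
  if (length(sigma2) != S) stop("mu and sigma2 lengths differ")
  gh <- pracma::gaussHermite(K)
  # gh integrates f(x) exp(-x^2); substitute theta = mu + sqrt(2 sigma2) x
  w <- gh$w / sqrt(pi)
  w <- w / sum(w)
  nodes <- outer(mu, rep(1, K)) + sqrt(2 * sigma2) %o% gh$x
  weights <- matrix(w, S, K, byrow = TRUE)
  structure(list(nodes = nodes, weights = weights, K = K),
            class = "quadrature_grid")
}

# Per-respondent log conditional likelihood at every node of the group's grid.
# Returns an N x K matrix; missing responses contribute nothing.
.cond_loglik_nodes <- function(data, params, grid) {
  N <- data$N; K <- grid$K
  out <- matrix(0, N, K)
  Y <- data$responses
  M <- !is.na(Y)
  Y0 <- Y; Y0[!M] <- 0
  for (s in seq_len(data$S)) {
    rows <- which(data$group_of == s)
    # J x K logits for this group's item parameters at its nodes
    logit <- params$a[, s] %o% grid$nodes[s, ] - matrix(params$b[, s], data$J, K)
    lg <- .log_irf(logit)
    out[rows, ] <- Y0[rows, , drop = FALSE] %*% lg$lp +
      (M[rows, , drop = FALSE] - Y0[rows, , drop = FALSE]) %*% lg$lq
  }
  out
}

#' Log marginal likelihood of the multi-group 2PL
#'
#' The latent trait is integrated out per respondent with the group's
#' quadrature rule; products run over observed responses only, so sparse
#' (adaptive-test) data are handled without imputation. A respondent with no
#' observed responses would contribute zero, but such rows are excluded by
#' construction of [response_data].
#'
#' @param data a [response_data] object.
#' @param params a [model_params] object.
#' @param grid a [build_quadrature] grid whose rows match the groups.
#' @return scalar log marginal likelihood (unpenalized).
#' @export
log_marginal_likelihood <- function(data, params, grid) {
  if (any(!is.finite(grid$nodes)) || any(grid$weights <= 0)) {
    stop("degenerate quadrature grid")
  }
  ll <- .cond_loglik_nodes(data, params, grid)
  lw <- log(grid$weights)[data$group_of, , drop = FALSE]
  z <- ll + lw
  m <- apply(z, 1, max)
  sum(m + log(rowSums(exp(z - m))))
}

#' E-step: posterior distribution of the latent trait over quadrature nodes
#'
#' Row i is proportional to the prior node weight times the conditional
#' likelihood of respondent i's observed responses; accumulation is in log
#' space with per-row max subtraction.
#'
#' @inheritParams log_marginal_likelihood
#' @return list with `post` (N x K matrix, rows sum to 1) and `loglik`, the
#'   log marginal likelihood at `params` (a free by-product of normalization).
#' @export
estep_posteriors <- function(data, params, grid) {
  ll <- .cond_loglik_nodes(data, params, grid)
  lw <- log(grid$weights)[data$group_of, , drop = FALSE]
  z <- ll + lw
  m <- apply(z, 1, max)
  ez <- exp(z - m)
  rs <- rowSums(ez)
  list(post = ez / rs, loglik = sum(m + log(rs)))
}

#' M-step update of the impact parameters
#'
#' Closed-form update of the latent means and variances: for each group s >= 2,
#' the new mean is the average posterior mean of theta over the group's
#' respondents, and the new variance the average posterior second central
#' moment about that new mean. Group 1 is pinned at (0, 1) for identification.
#'
#' @param post N x K posterior matrix (rows sum to 1), as from
#'   [estep_posteriors()].
#' @param grid the quadrature grid the posteriors were computed on.
#' @param data the [response_data].
#' @param var_floor lower bound applied to the updated variances; guards
#'   against collapse in very small groups.
#' @return list with `mu` and `sigma2`, length-S.
#' @export
mstep_impact <- function(post, grid, data, var_floor = 1e-4) {
  S <- data$S
  mu <- numeric(S)
  sigma2 <- rep(1, S)
  for (s in seq_len(S)) {
    if (s == 1) next
    rows <- which(data$group_of == s)
    if (length(rows) == 0) stop("empty group ", s)
    th <- grid$nodes[s, ]
    p <- post[rows, , drop = FALSE]
    mu[s] <- mean(p %*% th)
    sigma2[s] <- max(var_floor, mean(p %*% (th - mu[s])^2))
  }
  list(mu = mu, sigma2 = sigma2)
}

# Expected-count sufficient statistics from the E-step.
# Returns lists r, n of S matrices (J x K): r[[s]][j,k] expected number of
# correct responses to item j at node k among group-s respondents, n[[s]]
# the expected number of observed responses.
.estep_counts <- function(data, post) {
  Y <- data$responses
  M <- !is.na(Y)
  Y0 <- Y; Y0[!M] <- 0
  storage.mode(M) <- "double"
  r <- vector("list", data$S)
  n <- vector("list", data$S)
  for (s in seq_len(data$S)) {
    rows <- which(data$group_of == s)
    p <- post[rows, , drop = FALSE]
    r[[s]] <- crossprod(Y0[rows, , drop = FALSE], p)
    n[[s]] <- crossprod(M[rows, , drop = FALSE], p)
  }
  list(r = r, n = n)
}

# log(1 + exp(x)) without overflow
.log1pexp <- function(x) {
  out <- x
  big <- x > 0
  out[big] <- x[big] + log1p(exp(-x[big]))
  out[!big] <- log1p(exp(x[!big]))
  out
}

# Core of the penalized item-block objective for one item, on sufficient
# statistics. x = c(a_1..a_S, b_1..b_S); rj, nj are S x K expected-count
# matrices; nodes is the S x K node matrix; ca, cb are per-pair anchors
# delta - u; pm, pn index the pair members. Returns value and exact gradient.
.item_objective_core <- function(x, rj, nj, nodes, pm, pn, ca, cb, rho) {
  S <- nrow(nodes)
  a <- x[seq_len(S)]
  b <- x[S + seq_len(S)]
  logit <- a * nodes - b          # S x K, rows are groups
  val <- sum(nj * .log1pexp(logit) - rj * logit)
  resid <- nj * stats::plogis(logit) - rj   # d val / d logit
  ga <- rowSums(resid * nodes)
  gb <- -rowSums(resid)
  if (rho > 0 && length(pm) > 0) {
    da <- a[pm] - a[pn] - ca
    db <- b[pm] - b[pn] - cb
    val <- val + (rho / 2) * (sum(da^2) + sum(db^2))
    for (p in seq_along(pm)) {
      ga[pm[p]] <- ga[pm[p]] + rho * da[p]
      ga[pn[p]] <- ga[pn[p]] - rho * da[p]
      gb[pm[p]] <- gb[pm[p]] + rho * db[p]
      gb[pn[p]] <- gb[pn[p]] - rho * db[p]
    }
  }
  list(value = val, gradient = c(ga, gb))
}

#' Penalized item-block objective and gradient
#'
#' The function minimized in the item M-step for one item: the posterior
#' expectation of the complete-data negative log-likelihood restricted to the
#' item, plus the ADMM quadratic coupling
#' \eqn{(\rho/2) \sum_{m<n} (a_m - a_n - \delta + u)^2} (and the analog in b).
#' Exposed mainly for verification; [update_items()] drives it through L-BFGS.
#'
#' @param a,b length-S parameter vectors for the item.
#' @param item item index.
#' @param data,post,grid data, E-step posteriors, and quadrature grid.
#' @param pairs a `pair_state` data frame (see [init_pair_state()]) carrying
#'   delta and u for this item; may be `NULL` when `rho = 0`.
#' @param rho ADMM penalty parameter (>= 0).
#' @return list with `value` and `gradient` (length 2S, d/da then d/db).
#' @export
item_block_objective <- function(a, b, item, data, post, grid, pairs = NULL,
                                 rho = 0) {
  cnt <- .estep_counts(data, post)
  S <- data$S
  rj <- do.call(rbind, lapply(cnt$r, function(m) m[item, ]))
  nj <- do.call(rbind, lapply(cnt$n, function(m) m[item, ]))
  if (is.null(pairs) || rho == 0) {
    pm <- integer(0); pn <- integer(0); ca <- numeric(0); cb <- numeric(0)
  } else {
    pa <- pairs[pairs$item == item & pairs$kind == "a", ]
    pb <- pairs[pairs$item == item & pairs$kind == "b", ]
    pm <- pa$m; pn <- pa$n
    ca <- pa$delta - pa$u
    cb <- pb$delta - pb$u
  }
  .item_objective_core(c(a, b), rj, nj, grid$nodes, pm, pn, ca, cb, rho)
}

#' M-step update of the item parameters
#'
#' Each item's 2S-dimensional (slope, negative-intercept) block is updated by
#' a bounded-iteration L-BFGS minimization of [item_block_objective()],
#' warm-started at the current values. If the optimizer fails for an item the
#' previous block is kept and a warning is raised; the update never increases
#' an item's block objective.
#'
#' @param params current [model_params].
#' @param post,grid,data E-step posteriors, quadrature grid, data.
#' @param pairs `pair_state` with current delta and u (or `NULL` with
#'   `rho = 0` for an unpenalized M-step).
#' @param rho ADMM penalty parameter.
#' @param maxit L-BFGS iteration cap per item block.
#' @return updated [model_params].
#' @export
update_items <- function(params, post, grid, data, pairs = NULL, rho = 0,
                         maxit = 20) {
  cnt <- .estep_counts(data, post)
  S <- data$S
  pair_idx <- if (!is.null(pairs) && rho > 0) {
    split(seq_len(nrow(pairs)), list(pairs$item, pairs$kind))
  } else NULL
  a <- params$a; b <- params$b
  for (j in seq_len(data$J)) {
    rj <- do.call(rbind, lapply(cnt$r, function(m) m[j, ]))
    nj <- do.call(rbind, lapply(cnt$n, function(m) m[j, ]))
    if (!is.null(pair_idx)) {
      ia <- pair_idx[[paste0(j, ".a")]]
      ib <- pair_idx[[paste0(j, ".b")]]
      pm <- pairs$m[ia]; pn <- pairs$n[ia]
      ca <- pairs$delta[ia] - pairs$u[ia]
      cb <- pairs$delta[ib] - pairs$u[ib]
    } else {
      pm <- integer(0); pn <- integer(0); ca <- numeric(0); cb <- numeric(0)
    }
    x0 <- c(a[j, ], b[j, ])
    fn <- function(x) .item_objective_core(x, rj, nj, grid$nodes,
                                           pm, pn, ca, cb, rho)$value
    gr <- function(x) .item_objective_core(x, rj, nj, grid$nodes,
                                           pm, pn, ca, cb, rho)$gradient
    res <- tryCatch(
      stats::optim(x0, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = maxit)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value) || res$value > fn(x0) + 1e-10) {
      if (is.null(res)) {
        warning("L-BFGS failed for item ", j, "; keeping previous values")
      }
      next
    }
    a[j, ] <- res$par[seq_len(S)]
    b[j, ] <- res$par[S + seq_len(S)]
  }
  model_params(a, b, params$mu, params$sigma2)
}

#' Container for multi-group 2PL parameters
#'
#' @param a,b J x S matrices of slopes and negative intercepts (column s is
#'   group s).
#' @param mu,sigma2 length-S impact parameters; group 1 must be (0, 1) when
#'   `check_identification` is on.
#' @param var_floor lower bound enforced on `sigma2`.
#' @param check_identification enforce the group-1 (0, 1) constraint of the
#'   estimated metric; generating parameters of a simulation may live on
#'   another scale and switch this off.
#' @return object of class `model_params`.
#' @export
model_params <- function(a, b, mu, sigma2, var_floor = 1e-4,
                         check_identification = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("a and b shapes differ")
  S <- ncol(a)
  if (length(mu) != S || length(sigma2) != S) stop("impact length != S")
  if (check_identification &&
      (abs(mu[1]) > 1e-12 || abs(sigma2[1] - 1) > 1e-12)) {
    stop("identification requires mu[1] = 0, sigma2[1] = 1")
  }
  sigma2 <- pmax(sigma2, var_floor)
  if (!all(is.finite(a)) || !all(is.finite(b)) ||
      !all(is.finite(mu)) || !all(is.finite(sigma2))) {
    stop("non-finite parameter value")
  }
  structure(list(a = a, b = b, mu = as.numeric(mu),
                 sigma2 = as.numeric(sigma2)),
            class = "model_params")
}
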