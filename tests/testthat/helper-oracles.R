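# Independent oracles used to cross-check the implementation. These are
# deliberately coded from first principles (dense-grid integration, per-cell
# Newton-type fits, Floyd-Warshall closure) and share no internals with the
# package's quadrature/ADMM code paths.

# Log marginal likelihood by dense trapezoid integration on [-lim, lim].
oracle_loglik_dense <- function(data, params, npts = 20001, lim = 8) {
  th <- seq(-lim, lim, length.out = npts)
  h <- th[2] - th[1]
  total <- 0
  for (s in seq_len(data$S)) {
    rows <- which(data$group_of == s)
    logit <- outer(params$a[, s], th) - params$b[, s]  # J x npts
    lp <- stats::plogis(logit, log.p = TRUE)
    lq <- stats::plogis(-logit, log.p = TRUE)
    Y <- data$responses[rows, , drop = FALSE]
    M <- !is.na(Y)
    Y0 <- Y; Y0[!M] <- 0
    ll <- Y0 %*% lp + (M - Y0) %*% lq            # n_s x npts
    dens <- stats::dnorm(th, params$mu[s], sqrt(params$sigma2[s]))
    f <- exp(ll) * matrix(dens, nrow(ll), npts, byrow = TRUE)
    ints <- (rowSums(f) - 0.5 * (f[, 1] + f[, npts])) * h
    total <- total + sum(log(ints))
  }
  total
}

# Plain (unpenalized) multi-group 2PL EM: group-specific item parameters,
# free impact for groups >= 2, Gauss-Hermite integration, per-(item, group)
# two-parameter Newton steps via optim. No ADMM, no penalty.
oracle_plain_em <- function(data, K = 21, tol = 1e-4, max_iter = 2000,
                            start = NULL) {
  gh <- pracma::gaussHermite(K)
  S <- data$S; J <- data$J
  if (is.null(start)) {
    p <- colMeans(data$responses, na.rm = TRUE)
    a <- matrix(1, J, S); b <- matrix(-stats::qlogis(p), J, S)
  } else {
    a <- start$a; b <- start$b
  }
  mu <- rep(0, S); sigma2 <- rep(1, S)
  Y <- data$responses; M <- !is.na(Y); Y0 <- Y; Y0[!M] <- 0
  storage.mode(M) <- "double"
  for (iter in seq_len(max_iter)) {
    a_old <- a; b_old <- b; mu_old <- mu; s2_old <- sigma2
    for (s in seq_len(S)) {
      th <- mu[s] + sqrt(2 * sigma2[s]) * gh$x
      w <- gh$w / sqrt(pi); w <- w / sum(w)
      rows <- which(data$group_of == s)
      logit <- outer(a[, s], th) - b[, s]
      lp <- stats::plogis(logit, log.p = TRUE)
      lq <- stats::plogis(-logit, log.p = TRUE)
      z <- Y0[rows, , drop = FALSE] %*% lp +
        (M[rows, , drop = FALSE] - Y0[rows, , drop = FALSE]) %*% lq
      z <- z + matrix(log(w), nrow(z), K, byrow = TRUE)
      mx <- apply(z, 1, max)
      post <- exp(z - mx); post <- post / rowSums(post)
      # impact update (group 1 pinned)
      if (s > 1) {
        mu[s] <- mean(post %*% th)
        sigma2[s] <- max(1e-4, mean(post %*% (th - mu[s])^2))
      }
      # item updates: expected counts then 2-parameter minimization per item
      r <- crossprod(Y0[rows, , drop = FALSE], post)
      nn <- crossprod(M[rows, , drop = FALSE], post)
      for (j in seq_len(J)) {
        nll <- function(x) {
          lg <- x[1] * th - x[2]
          sum(nn[j, ] * log1p(exp(-abs(lg))) +
                nn[j, ] * pmax(lg, 0) - r[j, ] * lg)
        }
        gr <- function(x) {
          pr <- stats::plogis(x[1] * th - x[2])
          res <- nn[j, ] * pr - r[j, ]
          c(sum(res * th), -sum(res))
        }
        o <- stats::optim(c(a[j, s], b[j, s]), nll, gr, method = "BFGS")
        a[j, s] <- o$par[1]; b[j, s] <- o$par[2]
      }
    }
    ch <- max(abs(a - a_old), abs(b - b_old), abs(mu - mu_old),
              abs(sigma2 - s2_old))
    if (ch < tol) break
  }
  list(a = a, b = b, mu = mu, sigma2 = sigma2, iterations = iter)
}

# Constrained multi-group 2PL EM: one shared (a_j, b_j) across groups,
# group-specific impact for s >= 2.
oracle_constrained_em <- function(data, K = 21, tol = 1e-4, max_iter = 2000) {
  gh <- pracma::gaussHermite(K)
  S <- data$S; J <- data$J
  p <- colMeans(data$responses, na.rm = TRUE)
  a <- rep(1, J); b <- -stats::qlogis(p)
  mu <- rep(0, S); sigma2 <- rep(1, S)
  Y <- data$responses; M <- !is.na(Y); Y0 <- Y; Y0[!M] <- 0
  storage.mode(M) <- "double"
  w <- gh$w / sqrt(pi); w <- w / sum(w)
  for (iter in seq_len(max_iter)) {
    a_old <- a; b_old <- b; mu_old <- mu; s2_old <- sigma2
    r_all <- vector("list", S); n_all <- vector("list", S)
    th_all <- vector("list", S)
    for (s in seq_len(S)) {
      th <- mu[s] + sqrt(2 * sigma2[s]) * gh$x
      th_all[[s]] <- th
      rows <- which(data$group_of == s)
      logit <- outer(a, th) - b
      lp <- stats::plogis(logit, log.p = TRUE)
      lq <- stats::plogis(-logit, log.p = TRUE)
      z <- Y0[rows, , drop = FALSE] %*% lp +
        (M[rows, , drop = FALSE] - Y0[rows, , drop = FALSE]) %*% lq
      z <- z + matrix(log(w), nrow(z), K, byrow = TRUE)
      mx <- apply(z, 1, max)
      post <- exp(z - mx); post <- post / rowSums(post)
      if (s > 1) {
        mu[s] <- mean(post %*% th)
        sigma2[s] <- max(1e-4, mean(post %*% (th - mu[s])^2))
      }
      r_all[[s]] <- crossprod(Y0[rows, , drop = FALSE], post)
      n_all[[s]] <- crossprod(M[rows, , drop = FALSE], post)
    }
    for (j in seq_len(J)) {
      nll <- function(x) {
        v <- 0
        for (s in seq_len(S)) {
          lg <- x[1] * th_all[[s]] - x[2]
          v <- v + sum(n_all[[s]][j, ] * (log1p(exp(-abs(lg))) + pmax(lg, 0)) -
                         r_all[[s]][j, ] * lg)
        }
        v
      }
      gr <- function(x) {
        g <- c(0, 0)
        for (s in seq_len(S)) {
          pr <- stats::plogis(x[1] * th_all[[s]] - x[2])
          res <- n_all[[s]][j, ] * pr - r_all[[s]][j, ]
          g <- g + c(sum(res * th_all[[s]]), -sum(res))
        }
        g
      }
      o <- stats::optim(c(a[j], b[j]), nll, gr, method = "BFGS")
      a[j] <- o$par[1]; b[j] <- o$par[2]
    }
    ch <- max(abs(a - a_old), abs(b - b_old), abs(mu - mu_old),
              abs(sigma2 - s2_old))
    if (ch < tol) break
  }
  list(a = a, b = b, mu = mu, sigma2 = sigma2, iterations = iter)
}

# Log marginal likelihood of a shared-parameter fit (constrained oracle),
# by the same dense trapezoid rule.
oracle_constrained_loglik <- function(data, fit, npts = 20001, lim = 8) {
  params <- model_params(matrix(fit$a, data$J, data$S),
                         matrix(fit$b, data$J, data$S), fit$mu, fit$sigma2)
  oracle_loglik_dense(data, params, npts, lim)
}

# 1-D grid minimizer of (rho/2) (z - delta)^2 + w * lam * |delta|.
oracle_delta_grid <- function(z, w, lam, rho, lo = -2, hi = 2, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  obj <- (rho / 2) * (z - grid)^2 + w * lam * abs(grid)
  grid[which.min(obj)]
}

# Transitive closure of the zero-pair adjacency by Floyd-Warshall; returns
# the contiguous cluster membership in order of first appearance.
oracle_closure_membership <- function(zero_pairs, S) {
  adj <- diag(TRUE, S)
  if (NROW(zero_pairs) > 0) {
    for (i in seq_len(nrow(zero_pairs))) {
      m <- zero_pairs$m[i]; n <- zero_pairs$n[i]
      adj[m, n] <- TRUE; adj[n, m] <- TRUE
    }
  }
  for (k in seq_len(S)) {
    for (i in seq_len(S)) {
      if (adj[i, k]) adj[i, ] <- adj[i, ] | adj[k, ]
    }
  }
  comp <- integer(S)
  nxt <- 0L
  for (i in seq_len(S)) {
    if (comp[i] == 0) {
      nxt <- nxt + 1L
      comp[adj[i, ]] <- nxt
    }
  }
  comp
}

# Small random response dataset for oracle comparisons.
make_random_instance <- function(N = 20, J = 5, S = 2, seed = 1,
                                 missing_rate = 0) {
  set.seed(seed)
  g <- sort(rep_len(seq_len(S), N))
  a <- matrix(stats::rlnorm(J * S, 0, 0.3), J, S)
  b <- matrix(stats::rnorm(J * S, 0, 1), J, S)
  mu <- c(0, stats::runif(S - 1, -1, 1))
  sigma2 <- c(1, stats::runif(S - 1, 0.5, 1.5))
  th <- stats::rnorm(N, mu[g], sqrt(sigma2[g]))
  y <- matrix(stats::rbinom(N * J, 1,
                            stats::plogis(outer(th, rep(1, J)) *
                                            t(a[, g]) - t(b[, g]))), N, J)
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(N * J) < missing_rate, N, J)
    for (i in which(rowSums(!mask) == 0)) mask[i, sample.int(J, 1)] <- FALSE
    for (j in which(colSums(!mask) == 0)) mask[sample.int(N, 1), j] <- FALSE
    y[mask] <- NA
  }
  list(data = response_data(y, g),
       params = model_params(a, b, mu, sigma2, var_floor = 0))
}
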