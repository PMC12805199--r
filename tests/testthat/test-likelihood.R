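test_that("item response function matches the logistic form", {
  expect_equal(irf(0, 1, 0), 0.5)
  expect_equal(irf(0.5, 2, 1), 0.5)          # a*theta = b symmetry
  expect_equal(irf(1, 1, 0), 0.7310586, tolerance = 1e-7)
  th <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(irf(th, a = 1.3, b = 0.2)) > 0))  # monotone for a > 0
  expect_true(all(irf(c(-1e4, 1e4), 1, 0) >= 0 & irf(c(-1e4, 1e4), 1, 0) <= 1))
})

test_that("quadrature grids are correct Gaussian rules", {
  g <- build_quadrature(0, 1, K = 21)
  expect_equal(sum(g$weights[1, ]), 1, tolerance = 1e-12)
  expect_equal(g$nodes[1, ], -rev(g$nodes[1, ]), tolerance = 1e-12)
  expect_true(all(diff(g$nodes[1, ]) > 0))
  g2 <- build_quadrature(c(0, 2), c(1, 1), K = 21)
  expect_equal(g2$nodes[2, ], g$nodes[1, ] + 2, tolerance = 1e-12)
  # exact second moment of N(0,1)
  expect_equal(sum(g$weights[1, ] * g$nodes[1, ]^2), 1, tolerance = 1e-10)
  expect_error(build_quadrature(0, 1, K = 1), "K")
  expect_error(build_quadrature(0, -1), "positive")
})

test_that("marginal likelihood handles the slope-zero exact case", {
  # a = 0 makes the integrand constant: loglik = log P(y=1) = log plogis(-b)
  d <- response_data(matrix(1, 1, 1), groups = 1)
  p <- model_params(matrix(0, 1, 1), matrix(0.4, 1, 1), 0, 1)
  g <- build_quadrature(p$mu, p$sigma2, 21)
  expect_equal(log_marginal_likelihood(d, p, g), -0.9130153,
               tolerance = 1e-6)
})

test_that("missing responses contribute nothing to the likelihood", {
  # adding a respondent whose row is observed on a single item changes the
  # total by exactly that respondent's own one-item marginal; the missing
  # cells are an empty product
  inst <- make_random_instance(N = 10, J = 4, S = 2, seed = 8)
  g <- build_quadrature(inst$params$mu, inst$params$sigma2, 21)
  ll1 <- log_marginal_likelihood(inst$data, inst$params, g)
  d2 <- response_data(rbind(inst$data$responses, c(1, NA, NA, NA)),
                      c(inst$data$group_of, 1))
  ll2 <- log_marginal_likelihood(d2, inst$params, g)
  solo <- response_data(matrix(1, 1, 1), 1)
  solo_params <- model_params(inst$params$a[1, 1, drop = FALSE],
                              inst$params$b[1, 1, drop = FALSE], 0, 1)
  ll_solo <- log_marginal_likelihood(solo, solo_params,
                                     build_quadrature(0, 1, 21))
  expect_equal(ll2 - ll1, ll_solo, tolerance = 1e-10)
})

test_that("marginal likelihood is invariant to permuting respondents/items", {
  inst <- make_random_instance(N = 25, J = 6, S = 2, seed = 12,
                               missing_rate = 0.15)
  g <- build_quadrature(inst$params$mu, inst$params$sigma2, 21)
  ll <- log_marginal_likelihood(inst$data, inst$params, g)
  # permute respondents within groups so index assignment is unchanged
  pr <- unlist(lapply(1:2, function(s) sample(which(inst$data$group_of == s))))
  dp <- response_data(inst$data$responses[pr, ], inst$data$group_of[pr])
  expect_equal(log_marginal_likelihood(dp, inst$params, g), ll,
               tolerance = 1e-10)

  pj <- sample(inst$data$J)
  dj <- response_data(inst$data$responses[, pj], inst$data$group_of)
  pj_params <- model_params(inst$params$a[pj, ], inst$params$b[pj, ],
                            inst$params$mu, inst$params$sigma2, var_floor = 0)
  expect_equal(log_marginal_likelihood(dj, pj_params, g), ll,
               tolerance = 1e-10)
})

test_that("posteriors follow Bayes rule and normalize", {
  # flat likelihood (all slopes 0, b = 0): posterior equals the prior weights
  d <- response_data(matrix(c(1, 0, 1, 1), 2, 2), c(1, 2))
  p <- model_params(matrix(0, 2, 2), matrix(0, 2, 2), c(0, 0.5), c(1, 1))
  g <- build_quadrature(p$mu, p$sigma2, 15)
  es <- estep_posteriors(d, p, g)
  expect_equal(es$post[1, ], g$weights[1, ], tolerance = 1e-12)
  expect_equal(es$post[2, ], g$weights[2, ], tolerance = 1e-12)

  # two-node hand computation: prior (.5, .5), one item a=1 b=0, y=1
  toy_grid <- structure(list(nodes = matrix(c(-1, 1), 1, 2),
                             weights = matrix(0.5, 1, 2), K = 2L),
                        class = "quadrature_grid")
  toy <- response_data(matrix(1, 1, 1), 1)
  toy_p <- model_params(matrix(1, 1, 1), matrix(0, 1, 1), 0, 1)
  post <- estep_posteriors(toy, toy_p, toy_grid)$post
  expect_equal(as.vector(post), c(0.2689414, 0.7310586), tolerance = 1e-7)

  inst <- make_random_instance(N = 30, J = 5, S = 2, seed = 4,
                               missing_rate = 0.2)
  gi <- build_quadrature(inst$params$mu, inst$params$sigma2, 21)
  es2 <- estep_posteriors(inst$data, inst$params, gi)
  expect_equal(rowSums(es2$post), rep(1, 30), tolerance = 1e-10)
  expect_true(all(es2$post >= 0))
})

test_that("impact M-step computes posterior moments with group 1 pinned", {
  d <- response_data(matrix(c(1, 0, 1, 1), 4, 1), c(1, 1, 2, 2))
  g <- structure(list(nodes = rbind(c(-1, 0.2, 0.4), c(-1, 0.2, 0.4)),
                      weights = matrix(1 / 3, 2, 3), K = 3L),
                 class = "quadrature_grid")
  post <- rbind(c(1, 0, 0), c(1, 0, 0),
                c(0, 1, 0), c(0, 0, 1))  # group 2 degenerate at 0.2 and 0.4
  imp <- mstep_impact(post, g, d)
  expect_equal(imp$mu[1], 0)
  expect_equal(imp$sigma2[1], 1)
  expect_equal(imp$mu[2], 0.3)
  expect_equal(imp$sigma2[2], 0.01)

  # posteriors equal to a symmetric prior centered at c: mean = c
  gc <- build_quadrature(c(0, 0.7), c(1, 1), 15)
  dc <- response_data(matrix(c(1, 0), 2, 1), c(1, 2))
  prior_post <- rbind(gc$weights[1, ], gc$weights[2, ])
  imp2 <- mstep_impact(prior_post, gc, dc)
  expect_equal(imp2$mu[2], 0.7, tolerance = 1e-10)
})

test_that("item-block gradient matches central finite differences", {
  set.seed(31)
  inst <- make_random_instance(N = 40, J = 3, S = 3, seed = 31,
                               missing_rate = 0.1)
  g <- build_quadrature(inst$params$mu, inst$params$sigma2, 15)
  es <- estep_posteriors(inst$data, inst$params, g)
  pairs <- init_pair_state(3, 3)
  pairs$delta <- stats::rnorm(nrow(pairs), 0, 0.3)
  pairs$u <- stats::rnorm(nrow(pairs), 0, 0.1)
  for (j in 1:3) {
    a <- inst$params$a[j, ] + stats::rnorm(3, 0, 0.2)
    b <- inst$params$b[j, ] + stats::rnorm(3, 0, 0.2)
    ob <- item_block_objective(a, b, j, inst$data, es$post, g, pairs, rho = 3)
    fd <- numeric(6)
    h <- 1e-5
    for (k in 1:6) {
      xp <- c(a, b); xm <- c(a, b)
      xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
      fp <- item_block_objective(xp[1:3], xp[4:6], j, inst$data, es$post, g,
                                 pairs, rho = 3)$value
      fm <- item_block_objective(xm[1:3], xm[4:6], j, inst$data, es$post, g,
                                 pairs, rho = 3)$value
      fd[k] <- (fp - fm) / (2 * h)
    }
    expect_equal(ob$gradient, fd, tolerance = 1e-4)
  }
})

test_that("item M-step descends and EM ascends the marginal likelihood", {
  inst <- make_random_instance(N = 80, J = 5, S = 2, seed = 9)
  params <- model_params(matrix(1, 5, 2),
                         matrix(0, 5, 2), c(0, 0), c(1, 1))
  g <- build_quadrature(params$mu, params$sigma2, 21)
  es <- estep_posteriors(inst$data, params, g)
  pairs <- init_pair_state(5, 2)
  obj_before <- sum(vapply(1:5, function(j)
    item_block_objective(params$a[j, ], params$b[j, ], j, inst$data,
                         es$post, g, pairs, rho = 2)$value, numeric(1)))
  upd <- update_items(params, es$post, g, inst$data, pairs, rho = 2)
  obj_after <- sum(vapply(1:5, function(j)
    item_block_objective(upd$a[j, ], upd$b[j, ], j, inst$data,
                         es$post, g, pairs, rho = 2)$value, numeric(1)))
  expect_lte(obj_after, obj_before + 1e-10)

  # unpenalized EM never decreases the marginal likelihood
  ll_old <- -Inf
  for (it in 1:8) {
    g <- build_quadrature(params$mu, params$sigma2, 21)
    es <- estep_posteriors(inst$data, params, g)
    expect_gte(es$loglik, ll_old - 1e-8)
    ll_old <- es$loglik
    imp <- mstep_impact(es$post, g, inst$data)
    params <- update_items(params, es$post, g, inst$data, rho = 0)
    params$mu <- imp$mu
    params$sigma2 <- imp$sigma2
  }

})

test_that("single-group ML recovers generating item parameters", {
  # one group, ten items: enough items to identify the latent metric
  set.seed(77)
  n <- 500; J <- 10
  a_true <- c(1.5, runif(J - 1, 0.8, 2))
  b_true <- c(0.5, rnorm(J - 1, 0, 0.8))
  th <- stats::rnorm(n)
  y <- matrix(stats::rbinom(n * J, 1,
                            stats::plogis(outer(th, a_true) -
                                            matrix(b_true, n, J, byrow = TRUE))),
              n, J)
  d <- response_data(y, rep(1, n))
  params <- model_params(matrix(1, J, 1), matrix(0, J, 1), 0, 1)
  ch <- Inf
  for (it in 1:500) {
    g <- build_quadrature(params$mu, params$sigma2, 21)
    es <- estep_posteriors(d, params, g)
    upd <- update_items(params, es$post, g, d, rho = 0, maxit = 50)
    ch <- max(abs(upd$a - params$a), abs(upd$b - params$b))
    params <- upd
    if (ch < 1e-6) break
  }
  expect_lt(abs(params$a[1, 1] - 1.5), 0.25)
  expect_lt(abs(params$b[1, 1] - 0.5), 0.25)
  # and the EM fixed point is stationary: one more cycle barely moves
  es <- estep_posteriors(d, params, build_quadrature(0, 1, 21))
  upd <- update_items(params, es$post, build_quadrature(0, 1, 21), d,
                      rho = 0, maxit = 100)
  expect_lt(max(abs(upd$a - params$a), abs(upd$b - params$b)), 1e-4)
})
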