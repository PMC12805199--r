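#' Collapse groups connected by zero differences (union-find)
#'
#' Disjoint-set clustering of groups: each zero pair (m, n) merges the
#' clusters of m and n (the root of m's tree is pointed at the root of n's),
#' and the result is closed under transitivity. Lookups use path compression:
#' after `find(x)`, every group on the walked path points directly at the
#' representative.
#'
#' @param zero_pairs data frame (or matrix) with columns `m`, `n`
#'   (1 <= m < n <= S) of pairs whose parameter difference is zero; may have
#'   zero rows.
#' @param S number of groups.
#' @return object of class `group_clusters`: `parent` (the raw parent
#'   pointers after all unions and a compressing find on every group),
#'   `representative` (root per group), `membership` (contiguous cluster ids
#'   1..n_clusters in order of first group appearance), `n_clusters`.
#' @examples
#' cl <- collapse_clusters(data.frame(m = c(1, 2), n = c(2, 5)), S = 5)
#' cl$membership  # groups 1, 2, 5 share a cluster
#' @export
collapse_clusters <- function(zero_pairs, S) {
  parent <- seq_len(S)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) {   # path compression
      nxt <- parent[x]
      parent[x] <<- root
      x <- nxt
    }
    root
  }
  if (!is.null(zero_pairs) && NROW(zero_pairs) > 0) {
    zp <- as.data.frame(zero_pairs)
    zp$m <- as.integer(zp$m)
    zp$n <- as.integer(zp$n)
    if (any(zp$m < 1 | zp$n > S | zp$m >= zp$n)) {
      stop("invalid pair: need 1 <= m < n <= S")
    }
    for (i in seq_len(nrow(zp))) {
      rm_ <- find(zp$m[i])
      rn_ <- find(zp$n[i])
      if (rm_ != rn_) parent[rm_] <- rn_
    }
  }
  representative <- vapply(seq_len(S), find, integer(1))
  structure(
    list(parent = parent, representative = representative,
         membership = match(representative, unique(representative)),
         n_clusters = length(unique(representative))),
    class = "group_clusters"
  )
}

# Per-(item, kind) clusters from the near-zero deltas of a pair state.
# zero_tol absorbs numerical fuzz left by cluster averaging and I/O.
.item_clusters <- function(pairs, J, S, zero_tol = 1e-6) {
  out <- list(a = vector("list", J), b = vector("list", J))
  for (kind in c("a", "b")) {
    pk <- pairs[pairs$kind == kind, ]
    for (j in seq_len(J)) {
      pj <- pk[pk$item == j & abs(pk$delta) < zero_tol, c("m", "n")]
      out[[kind]][[j]] <- collapse_clusters(pj, S)
    }
  }
  out
}

#' Enforce transitivity of zero differences
#'
#' ADMM stops at an approximate stationary point, so delta(m,n) and
#' delta(n,l) may be exactly zero while delta(m,l) retains a small residual —
#' the updates never check transitivity explicitly. This repairs the pair
#' state: groups are clustered through the zero deltas (union-find) and every
#' within-cluster pair has its delta assigned exactly 0. All other deltas are
#' untouched; the operation is idempotent.
#'
#' @param pairs a `pair_state` data frame.
#' @param S number of groups.
#' @param zero_tol magnitude below which a delta counts as zero when building
#'   the clusters.
#' @return the repaired `pair_state`.
#' @export
enforce_transitivity <- function(pairs, S, zero_tol = 1e-6) {
  J <- max(pairs$item)
  cl <- .item_clusters(pairs, J, S, zero_tol)
  for (kind in c("a", "b")) {
    idx <- which(pairs$kind == kind)
    for (j in seq_len(J)) {
      mem <- cl[[kind]][[j]]$membership
      ij <- idx[pairs$item[idx] == j]
      same <- mem[pairs$m[ij]] == mem[pairs$n[ij]]
      pairs$delta[ij[same]] <- 0
    }
  }
  pairs
}

#' Pairwise DIF flags from the difference parameters
#'
#' An item shows DIF between groups m and n on a parameter kind iff the
#' corresponding difference parameter is nonzero; no DIF between the pair
#' iff both the slope and intercept differences are zero. Transitivity should
#' be enforced first.
#'
#' @param pairs a `pair_state`, normally after [enforce_transitivity()].
#' @return data frame with one row per (item, pair): `item`, `m`, `n`,
#'   logical `dif_a`, `dif_b`, `dif_any`.
#' @export
dif_flag_matrix <- function(pairs) {
  pa <- pairs[pairs$kind == "a", ]
  pb <- pairs[pairs$kind == "b", ]
  key <- order(pa$item, pa$m, pa$n)
  pa <- pa[key, ]
  pb <- pb[order(pb$item, pb$m, pb$n), ]
  stopifnot(all(pa$item == pb$item), all(pa$m == pb$m), all(pa$n == pb$n))
  data.frame(item = pa$item, m = pa$m, n = pa$n,
             dif_a = pa$delta != 0, dif_b = pb$delta != 0,
             dif_any = pa$delta != 0 | pb$delta != 0)
}

#' Distinct-parameter counts
#'
#' Number of distinct slope and intercept parameters after collapsing: each
#' item contributes one parameter per cluster, so
#' `p_kind = sum_j n_clusters(j, kind)`.
#'
#' @param clusters per-(item, kind) cluster list as built inside
#'   [postprocess()] (`list(a = , b = )` of `group_clusters`).
#' @return list with integer `p_a`, `p_b`.
#' @export
distinct_param_counts <- function(clusters) {
  list(p_a = sum(vapply(clusters$a, function(cl) cl$n_clusters, integer(1))),
       p_b = sum(vapply(clusters$b, function(cl) cl$n_clusters, integer(1))))
}

#' Bayesian information criterion for a collapsed fit
#'
#' `-2 * loglik + log(N) * (p_a + p_b + 2 * (S - 1))`: the distinct item
#' parameters plus the 2(S-1) free impact parameters. The impact term is
#' constant across candidate tuning values, so it never changes the argmin,
#' but reported BIC values are self-consistent model scores.
#'
#' @param loglik unpenalized log marginal likelihood (at cluster-averaged
#'   parameters).
#' @param p_a,p_b distinct slope / intercept parameter counts.
#' @param N total number of respondents.
#' @param S number of groups.
#' @return scalar BIC.
#' @export
bic_score <- function(loglik, p_a, p_b, N, S) {
  if (N < 1) stop("N must be >= 1")
  -2 * loglik + log(N) * (p_a + p_b + 2 * (S - 1))
}

# Replace each cluster's parameters by the group-size-weighted mean of its
# members' estimates, making the counted model and scored likelihood agree.
.collapse_params <- function(params, clusters, n_s) {
  a <- params$a
  b <- params$b
  J <- nrow(a)
  for (j in seq_len(J)) {
    mem <- clusters$a[[j]]$membership
    for (c_ in unique(mem)) {
      g <- which(mem == c_)
      a[j, g] <- sum(a[j, g] * n_s[g]) / sum(n_s[g])
    }
    mem <- clusters$b[[j]]$membership
    for (c_ in unique(mem)) {
      g <- which(mem == c_)
      b[j, g] <- sum(b[j, g] * n_s[g]) / sum(n_s[g])
    }
  }
  model_params(a, b, params$mu, params$sigma2)
}

#' Post-process a converged fit into a DIF report
#'
#' Applies the transitivity repair, clusters groups per (item, kind) with
#' union-find, derives the pairwise DIF flags and distinct-parameter counts,
#' collapses each cluster's parameters to their group-size-weighted mean,
#' re-evaluates the unpenalized log marginal likelihood at the collapsed
#' parameters, and scores the model by BIC.
#'
#' @param fit a `dif_fit` from [fit_single()].
#' @param data the [response_data] the fit was computed on.
#' @param zero_tol numerical-zero threshold for the deltas.
#' @return object of class `dif_report`: `flags` (flag data frame),
#'   `clusters`, `counts` (`p_a`, `p_b`), `params` (cluster-averaged),
#'   `loglik`, `bic`, and ready-to-write `param_table`, `flag_table`,
#'   `impact_table`, `metadata`.
#' @export
postprocess <- function(fit, data, zero_tol = 1e-6) {
  pairs <- enforce_transitivity(fit$pairs, data$S, zero_tol)
  clusters <- .item_clusters(pairs, data$J, data$S, zero_tol)
  flags <- dif_flag_matrix(pairs)
  counts <- distinct_param_counts(clusters)
  cparams <- .collapse_params(fit$params, clusters, data$n_s)
  grid <- build_quadrature(cparams$mu, cparams$sigma2, fit$opts$K)
  loglik <- log_marginal_likelihood(data, cparams, grid)
  bic <- bic_score(loglik, counts$p_a, counts$p_b, data$N, data$S)
  param_table <- data.frame(
    item = rep(data$item_ids, data$S),
    item_index = rep(seq_len(data$J), data$S),
    group = rep(data$group_labels, each = data$J),
    group_index = rep(seq_len(data$S), each = data$J),
    a = as.vector(cparams$a), b = as.vector(cparams$b),
    cluster_a = as.vector(vapply(seq_len(data$S), function(s)
      vapply(clusters$a, function(cl) cl$membership[s], integer(1)),
      integer(data$J))),
    cluster_b = as.vector(vapply(seq_len(data$S), function(s)
      vapply(clusters$b, function(cl) cl$membership[s], integer(1)),
      integer(data$J)))
  )
  flag_table <- flags
  impact_table <- data.frame(group = data$group_labels,
                             group_index = seq_len(data$S),
                             n = data$n_s,
                             mu = cparams$mu, sigma2 = cparams$sigma2)
  metadata <- list(
    lambda = fit$tuning$lambda, tau = fit$tuning$tau, rho = fit$tuning$rho,
    bic = bic, loglik = loglik, loglik_raw = fit$loglik,
    p_a = counts$p_a, p_b = counts$p_b,
    iterations = fit$iterations, converged = fit$converged,
    feasibility_gap = fit$feasibility_gap,
    seed = if (is.null(fit$opts$seed)) NA else fit$opts$seed
  )
  structure(
    list(flags = flags, clusters = clusters, counts = counts,
         params = cparams, loglik = loglik, bic = bic,
         param_table = param_table, flag_table = flag_table,
         impact_table = impact_table, metadata = metadata),
    class = "dif_report"
  )
}

#' @export
print.dif_report <- function(x, ...) {
  cat("DIF report\n")
  cat(sprintf("  BIC = %.3f (loglik %.3f, p_a %d, p_b %d)\n",
              x$bic, x$loglik, x$counts$p_a, x$counts$p_b))
  cat(sprintf("  items with any DIF: %d of %d\n",
              length(unique(x$flags$item[x$flags$dif_any])),
              max(x$flags$item)))
  invisible(x)
}

#' Default per-respondent lambda grid
#' @return numeric vector.
#' @export
default_lam_grid <- function() c(0.0025, 0.005, 0.01, 0.02, 0.04, 0.08)

#' Default tau grid
#' @return numeric vector.
#' @export
default_tau_grid <- function() c(0.05, 0.1, 0.2, 0.3, 0.5)

#' Grid search over (lambda, tau) with BIC selection
#'
#' Fits every combination of the grids. For each lambda, one fused-L1
#' (`tau = Inf`) run from the neutral start provides the shared warm start
#' for all tau values at that lambda. Every fit is post-processed and scored;
#' the fit with the lowest BIC wins, ties broken toward larger lambda, then
#' larger tau (the more parsimonious model).
#'
#' @param data a [response_data] object.
#' @param lam_grid penalty strengths on the per-respondent scale; the solver
#'   runs at `lambda = lam_user * N`.
#' @param tau_grid truncation thresholds.
#' @param opts a [solver_options].
#' @param rho ADMM penalty parameter (`NULL` = `N / 10`).
#' @return list: `best` (list with `fit` and `report`), `table` (one row per
#'   grid cell: lam, tau, loglik, p_a, p_b, bic, converged), `best_index`
#'   (row of `table` selected).
#' @export
select_model <- function(data, lam_grid = default_lam_grid(),
                         tau_grid = default_tau_grid(),
                         opts = solver_options(), rho = NULL) {
  if (length(lam_grid) == 0 || length(tau_grid) == 0) stop("empty grid")
  grid_tab <- expand.grid(lam = sort(lam_grid), tau = sort(tau_grid))
  grid_tab <- grid_tab[order(grid_tab$lam, grid_tab$tau), ]
  results <- vector("list", nrow(grid_tab))
  tab <- data.frame(grid_tab, loglik = NA_real_, p_a = NA_integer_,
                    p_b = NA_integer_, bic = NA_real_, converged = NA)
  for (lam in unique(grid_tab$lam)) {
    warm <- tryCatch({
      lp <- fit_single(data, tuning_config(lam * data$N, Inf, rho), opts,
                       init = .neutral_start(data))
      list(params = lp$params, pairs = lp$pairs)
    }, error = function(e) NULL)
    for (i in which(grid_tab$lam == lam)) {
      tau <- grid_tab$tau[i]
      res <- tryCatch({
        tuning <- tuning_config(lam * data$N, tau, rho)
        init <- if (is.null(warm)) NULL else warm
        fit <- fit_single(data, tuning, opts, init = init)
        list(fit = fit, report = postprocess(fit, data))
      }, error = function(e) e)
      results[[i]] <- res
      if (!inherits(res, "error")) {
        tab$loglik[i] <- res$report$loglik
        tab$p_a[i] <- res$report$counts$p_a
        tab$p_b[i] <- res$report$counts$p_b
        tab$bic[i] <- res$report$bic
        tab$converged[i] <- res$fit$converged
      }
    }
  }
  ok <- which(!is.na(tab$bic))
  if (length(ok) == 0) {
    err <- structure(class = c("select_model_error", "error", "condition"),
                     list(message = "all grid fits failed", call = NULL,
                          table = tab))
    stop(err)
  }
  best_i <- ok[order(tab$bic[ok], -tab$lam[ok], -tab$tau[ok])][1]
  list(best = results[[best_i]], table = tab, best_index = best_i)
}
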