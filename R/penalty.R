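#' Ordered group pairs
#'
#' All pairs (m, n) with 1 <= m < n <= S in lexicographic order; the pairwise
#' penalty, difference parameters, duals and DIF flags are all indexed by this
#' list, with differences always oriented as param(m) - param(n).
#'
#' @param S number of groups (>= 2).
#' @return data frame with integer columns `m`, `n` and S(S-1)/2 rows.
#' @examples
#' pair_index(4)   # 6 pairs, (1,2) first, (3,4) last
#' @export
pair_index <- function(S) {
  if (S < 2) stop("S must be >= 2")
  m <- rep(seq_len(S - 1), times = (S - 1):1)
  n <- unlist(lapply(seq_len(S - 1), function(i) (i + 1):S))
  data.frame(m = as.integer(m), n = as.integer(n))
}

#' Truncated L1 penalty
#'
#' `lam * min(|d|, tau)`: identical to the lasso for |d| <= tau, constant
#' `lam * tau` beyond, so large differences are not shrunk further
#' (approximating the L0 penalty without its discontinuity). `tau = Inf`
#' recovers the plain L1 penalty.
#'
#' @param d difference value(s).
#' @param lam penalty strength (>= 0).
#' @param tau truncation threshold (> 0, Inf allowed).
#' @return penalty value(s).
#' @export
tlp_value <- function(d, lam, tau) {
  if (any(lam < 0)) stop("lam must be >= 0")
  if (any(tau <= 0)) stop("tau must be > 0")
  lam * pmin(abs(d), tau)
}

#' Total group-pairwise TLP penalty of a parameter set
#'
#' Sums [tlp_value()] over every item, both parameter kinds, and every group
#' pair, with one common (lam, tau) for slopes and intercepts.
#'
#' @param params a [model_params] object.
#' @param lam,tau common tuning parameters.
#' @return scalar penalty.
#' @export
penalty_total <- function(params, lam, tau) {
  S <- ncol(params$a)
  if (S < 2) return(0)
  pr <- pair_index(S)
  da <- params$a[, pr$m, drop = FALSE] - params$a[, pr$n, drop = FALSE]
  db <- params$b[, pr$m, drop = FALSE] - params$b[, pr$n, drop = FALSE]
  sum(tlp_value(da, lam, tau)) + sum(tlp_value(db, lam, tau))
}

#' Initialize the pair state
#'
#' One row per (item, kind, pair): the difference parameter `delta`, the
#' scaled dual `u`, and the DC majorization weight `w`.
#'
#' @param J number of items.
#' @param S number of groups.
#' @return data frame of class `pair_state` with columns
#'   `item`, `kind` ("a"/"b"), `m`, `n`, `delta`, `u`, `w`;
#'   2 * J * S(S-1)/2 rows.
#' @export
init_pair_state <- function(J, S) {
  pr <- pair_index(S)
  base <- expand.grid(pair = seq_len(nrow(pr)), item = seq_len(J),
                      kind = c("a", "b"), stringsAsFactors = FALSE)
  st <- data.frame(item = base$item, kind = base$kind,
                   m = pr$m[base$pair], n = pr$n[base$pair],
                   delta = 0, u = 0, w = 1)
  class(st) <- c("pair_state", "data.frame")
  st
}

#' DC majorization weights
#'
#' The TLP is majorized at the current iterate by freezing the indicator of
#' the linear region: `w = 1` when `|delta| <= tau` (still being shrunk),
#' `w = 0` otherwise (penalty locally constant, no shrinkage). The boundary
#' `|delta| = tau` is kept in the penalized set, so `tau = Inf` gives `w = 1`
#' everywhere and the algorithm reduces to the fused-L1 case.
#'
#' @param pairs a `pair_state` data frame.
#' @param tau truncation threshold.
#' @return `pairs` with `w` recomputed.
#' @export
dc_weights <- function(pairs, tau) {
  pairs$w <- as.numeric(abs(pairs$delta) <= tau)
  pairs
}

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - t, 0)`, the proximal operator of `t * |.|`.
#'
#' @param z input value(s).
#' @param t threshold (>= 0).
#' @return thresholded value(s).
#' @export
soft_threshold <- function(z, t) {
  if (any(t < 0)) stop("threshold must be >= 0")
  sign(z) * pmax(abs(z) - t, 0)
}

#' Closed-form ADMM update of a difference parameter
#'
#' Minimizes `(rho/2) * (diff + u - delta)^2 + w * lam * |delta|` in delta:
#' soft-thresholding of `diff + u` at `w * lam / rho`. With `w = 0` the
#' difference is currently outside the truncation region and passes through
#' unshrunk.
#'
#' @param diff raw parameter difference `param_m - param_n`.
#' @param dual_u scaled dual variable.
#' @param w DC weight (0 or 1).
#' @param lam penalty strength.
#' @param rho ADMM penalty parameter (> 0).
#' @return updated delta value(s).
#' @export
delta_update <- function(diff, dual_u, w, lam, rho) {
  if (any(rho <= 0)) stop("rho must be > 0")
  soft_threshold(diff + dual_u, w * lam / rho)
}

#' Scaled dual update
#'
#' Adds the constraint residual: `u + (diff - delta)`. At a feasible point
#' (`diff == delta`) the dual is unchanged.
#'
#' @param dual_u current scaled dual.
#' @param diff raw parameter difference.
#' @param delta current difference parameter.
#' @return updated dual value(s).
#' @export
dual_update <- function(dual_u, diff, delta) {
  dual_u + diff - delta
}

# Raw pairwise differences param_m - param_n aligned with a pair_state
.pair_diffs <- function(params, pairs) {
  ia <- pairs$kind == "a"
  d <- numeric(nrow(pairs))
  d[ia] <- params$a[cbind(pairs$item[ia], pairs$m[ia])] -
    params$a[cbind(pairs$item[ia], pairs$n[ia])]
  d[!ia] <- params$b[cbind(pairs$item[!ia], pairs$m[!ia])] -
    params$b[cbind(pairs$item[!ia], pairs$n[!ia])]
  d
}
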