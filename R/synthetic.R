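#' Simulation configuration
#'
#' Describes a multi-group 2PL generating model with impact and a leading
#' block of DIF items, mirroring balanced and unbalanced group designs.
#' Baseline item parameters are shared across groups; the first
#' `n_dif_items` items additionally receive group-specific offsets on the
#' slope and/or intercept. Latent traits have group-specific means but a
#' common variance (impact varies means only).
#'
#' @param S number of groups.
#' @param group_sizes length-S respondent counts (scalar recycled).
#' @param J number of items.
#' @param n_dif_items how many leading items carry DIF.
#' @param dif_a,dif_b DIF offsets: either a scalar magnitude — expanded to a
#'   `n_dif_items x S` matrix with group 1 at 0 and groups 2..S alternating
#'   `+mag, -mag, +mag, ...` — or a full `n_dif_items x S` offset matrix.
#' @param base_a_dist,base_b_dist baseline parameter distributions, a list
#'   with `name` ("lognormal", "normal" or "uniform") and its parameters.
#' @param impact_means length-S latent means, first entry 0; default places
#'   groups 2..S evenly in `[-0.5, 0.5]`.
#' @param impact_var common latent variance.
#' @param missing_rate MCAR missingness fraction in `[0, 1)`.
#' @param seed integer seed; the dataset is a deterministic function of the
#'   configuration.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(S = 4, group_sizes = 500, J = 20, n_dif_items = 4,
                       dif_a = 0.5, dif_b = 1.0,
                       base_a_dist = list(name = "lognormal", meanlog = 0,
                                          sdlog = 0.25),
                       base_b_dist = list(name = "normal", mean = 0, sd = 1),
                       impact_means = NULL, impact_var = 1,
                       missing_rate = 0, seed = 1) {
  if (length(group_sizes) == 1) group_sizes <- rep(group_sizes, S)
  if (length(group_sizes) != S) stop("group_sizes must have length S")
  if (any(group_sizes < 1)) stop("group_sizes must be >= 1")
  if (n_dif_items > J) stop("n_dif_items > J")
  if (is.null(impact_means)) {
    impact_means <- if (S >= 2) c(0, seq(-0.5, 0.5, length.out = S - 1)) else 0
  }
  if (length(impact_means) != S) stop("impact_means must have length S")
  if (abs(impact_means[1]) > 1e-12) stop("impact_means[1] must be 0")
  if (impact_var <= 0) stop("impact_var must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate in [0, 1)")
  structure(list(S = S, group_sizes = as.integer(group_sizes), J = J,
                 n_dif_items = as.integer(n_dif_items),
                 dif_a = dif_a, dif_b = dif_b,
                 base_a_dist = base_a_dist, base_b_dist = base_b_dist,
                 impact_means = impact_means, impact_var = impact_var,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

.draw_dist <- function(dist, n) {
  switch(dist$name,
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    normal = stats::rnorm(n, dist$mean, dist$sd),
    uniform = stats::runif(n, dist$min, dist$max),
    stop("unknown distribution: ", dist$name)
  )
}

# Expand a scalar DIF magnitude to the default offset pattern: anchor group 1
# at 0, alternate the sign across the remaining groups.
.dif_offsets <- function(x, n_dif, S) {
  if (length(x) == 1) {
    signs <- c(0, (-1)^(seq_len(S - 1) + 1))   # 0, +1, -1, +1, ...
    matrix(x * signs, max(n_dif, 1), S, byrow = TRUE)[seq_len(n_dif), ,
                                                      drop = FALSE]
  } else {
    x <- as.matrix(x)
    if (!all(dim(x) == c(n_dif, S))) stop("offset matrix must be n_dif x S")
    x
  }
}

#' Generate a multi-group 2PL dataset with impact and DIF
#'
#' Baseline slopes and intercepts are drawn once and shared across groups;
#' DIF offsets are added to the leading block; latent traits are drawn per
#' group from N(impact mean, common variance); responses are Bernoulli draws
#' from the item response function; missingness is applied uniformly at
#' random (and repaired minimally so every respondent and item keeps at least
#' one observation).
#'
#' @param config a [sim_config].
#' @return object of class `simulated_dataset`: `data` ([response_data]),
#'   `true_params` ([model_params]), `true_flags` (pairwise truth as from
#'   [truth_flags()]), `theta` (generating latent traits), `config`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  S <- config$S; J <- config$J
  n_dif <- config$n_dif_items
  base_a <- .draw_dist(config$base_a_dist, J)
  base_b <- .draw_dist(config$base_b_dist, J)
  a <- matrix(base_a, J, S)
  b <- matrix(base_b, J, S)
  if (n_dif > 0) {
    a[seq_len(n_dif), ] <- a[seq_len(n_dif), , drop = FALSE] +
      .dif_offsets(config$dif_a, n_dif, S)
    b[seq_len(n_dif), ] <- b[seq_len(n_dif), , drop = FALSE] +
      .dif_offsets(config$dif_b, n_dif, S)
  }
  # generating impact: report relative to the group-1 scale (mu_1 = 0 by
  # design); sigma2_1 = impact_var must be 1 for the identified metric, which
  # the default is. Other common variances rescale the latent metric.
  group_of <- rep(seq_len(S), times = config$group_sizes)
  N <- length(group_of)
  theta <- stats::rnorm(N, config$impact_means[group_of],
                        sqrt(config$impact_var))
  logit <- outer(theta, rep(1, J)) * t(a[, group_of, drop = FALSE]) -
    t(b[, group_of, drop = FALSE])
  y <- matrix(stats::rbinom(N * J, 1, stats::plogis(logit)), N, J)
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(N * J) < config$missing_rate, N, J)
    # minimal repair: keep one observation in any fully-missing row/column
    for (i in which(rowSums(!mask) == 0)) mask[i, sample.int(J, 1)] <- FALSE
    for (j in which(colSums(!mask) == 0)) mask[sample.int(N, 1), j] <- FALSE
    y[mask] <- NA
  }
  true_params <- model_params(a, b, config$impact_means,
                              rep(config$impact_var, S), var_floor = 0,
                              check_identification = FALSE)
  data <- response_data(y, group_of)
  structure(list(data = data, true_params = true_params,
                 true_flags = truth_flags(config, true_params),
                 theta = theta, config = config),
            class = "simulated_dataset")
}

#' Ground-truth pairwise DIF flags
#'
#' A pair (m, n) truly has DIF on a parameter kind for item j iff the
#' generating values differ (exact comparison).
#'
#' @param config the [sim_config] (used only for shape checks; may be NULL).
#' @param true_params generating [model_params].
#' @return data frame: `item`, `m`, `n`, logical `a`, `b`.
#' @export
truth_flags <- function(config, true_params) {
  J <- nrow(true_params$a)
  S <- ncol(true_params$a)
  pr <- pair_index(S)
  np <- nrow(pr)
  data.frame(
    item = rep(seq_len(J), each = np),
    m = rep(pr$m, J), n = rep(pr$n, J),
    a = as.vector(t(true_params$a[, pr$m, drop = FALSE] !=
                      true_params$a[, pr$n, drop = FALSE])),
    b = as.vector(t(true_params$b[, pr$m, drop = FALSE] !=
                      true_params$b[, pr$n, drop = FALSE]))
  )
}

#' Pairwise true/false positive rates of a DIF analysis
#'
#' Rates are computed over all (item, group-pair) cells, separately for
#' slopes and intercepts: TPR = flagged-and-true / true,
#' FPR = flagged-and-not-true / not-true. An empty denominator yields `NA`
#' rather than an error.
#'
#' @param flags flag data frame from [dif_flag_matrix()] (columns `item`,
#'   `m`, `n`, `dif_a`, `dif_b`).
#' @param truth truth data frame from [truth_flags()].
#' @return list with `tpr_a`, `tpr_b`, `fpr_a`, `fpr_b`.
#' @export
tpr_fpr <- function(flags, truth) {
  key_f <- paste(flags$item, flags$m, flags$n)
  key_t <- paste(truth$item, truth$m, truth$n)
  ord <- match(key_t, key_f)
  if (anyNA(ord) || length(key_f) != length(key_t)) {
    stop("flags and truth do not cover the same (item, pair) cells")
  }
  flags <- flags[ord, ]
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(
    tpr_a = rate(sum(flags$dif_a & truth$a), sum(truth$a)),
    tpr_b = rate(sum(flags$dif_b & truth$b), sum(truth$b)),
    fpr_a = rate(sum(flags$dif_a & !truth$a), sum(!truth$a)),
    fpr_b = rate(sum(flags$dif_b & !truth$b), sum(!truth$b))
  )
}
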