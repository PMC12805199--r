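# pairdif

Reference-group-free detection of differential item functioning (DIF) in
multi-group two-parameter logistic (2PL) item response models, by penalizing
the item-parameter differences between **every pair of groups** with a
truncated L1 penalty (TLP).

## The problem

A test item shows DIF when respondents of equal latent ability but from
different groups have different probabilities of answering it correctly.
Classical regularized DIF detection designates one group as the reference and
shrinks every focal group toward it, which privileges the reference,
prevents direct focal-vs-focal comparisons, and (with a plain lasso) biases
large DIF effects toward zero. Those weaknesses bite hardest in modern
settings with many small groups — for example intersectional subgroups formed
by crossing native language with gender — where no single group is a natural
anchor.

`pairdif` treats all groups symmetrically. Under the multi-group 2PL, the
probability that respondent *i* of group *s* answers item *j* correctly is

    P(y_ij = 1 | theta_i) = logistic(a_js * theta_i - b_js),

with latent ability `theta_i ~ N(mu_s, sigma_s^2)` (group 1 fixed at N(0, 1)
for identification, so genuine group differences in ability — *impact* — are
separated from DIF). Estimation maximizes the penalized marginal
log-likelihood

    l(Theta) - sum_j sum_{m<n} [ J_tau(|a_jm - a_jn|) + J_tau(|b_jm - b_jn|) ],

where `J_tau(d) = lambda * min(d, tau)` is the TLP: lasso-like below the
truncation threshold `tau`, constant beyond it, so small spurious differences
are shrunk to exactly zero while genuine DIF is estimated without shrinkage
bias. Item *j* is DIF-free between groups *m* and *n* iff both fitted
differences are exactly zero.

The optimizer follows the method's difference-of-convex (DC) decomposition of
the TLP: an outer loop freezes the truncation indicator, and an inner ADMM
loop alternates (1) an EM cycle — Gauss–Hermite quadrature E-step, closed-form
impact update, L-BFGS update of each item's parameter block under the
augmented-Lagrangian quadratic — (2) a closed-form soft-threshold update of
the difference parameters, and (3) the scaled-dual update. A fused-L1 run
(`tau = Inf`) provides the warm start. After convergence, groups connected by
zero differences are collapsed with a union-find structure (with path
compression), which also repairs numerical violations of transitivity, and
`(lambda, tau)` are selected by BIC with the number of distinct item
parameters as the model size.

## Worked example

```r
library(pairdif)

# three groups of 400, ten items, the first two with cross-group DIF
sim <- simulate_dataset(sim_config(S = 3, group_sizes = 400, J = 10,
                                   n_dif_items = 2, seed = 2026))
sel <- select_model(sim$data, lam_grid = c(0.005, 0.01, 0.02),
                    tau_grid = c(0.2, 0.5))
sel$table
#>     lam tau    loglik p_a p_b      bic converged
#> 1 0.005 0.2 -6822.250  11  15 13857.20      TRUE
#> 4 0.005 0.5 -6822.250  11  15 13857.20      TRUE
#> 2 0.010 0.2 -6822.447  10  13 13836.33      TRUE
#> 5 0.010 0.5 -6878.790  10  11 13934.83      TRUE
#> 3 0.020 0.2 -6892.627  10  10 13955.42      TRUE
#> 6 0.020 0.5 -6892.627  10  10 13955.42      TRUE
sel$best$report
#> DIF report
#>   BIC = 13836.327 (loglik -6822.447, p_a 10, p_b 13)
#>   items with any DIF: 2 of 10
```

BIC picks `lambda = 0.01` (per respondent), `tau = 0.2`: `p_a = 10` distinct
slopes (no slope DIF anywhere — each item keeps one slope cluster) and
`p_b = 13` distinct intercepts (items 1 and 2 split into intercept clusters).
The pairwise flags name the groups involved:

```r
head(subset(sel$best$report$flag_table, dif_any))
#>   item m n dif_a dif_b dif_any
#> 1    1 1 2 FALSE  TRUE    TRUE
#> 2    1 1 3 FALSE  TRUE    TRUE
#> 3    1 2 3 FALSE  TRUE    TRUE
#> 4    2 1 2 FALSE  TRUE    TRUE
#> 6    2 2 3 FALSE  TRUE    TRUE
sel$best$report$impact_table
#>   group group_index   n         mu    sigma2
#> 1     1           1 400  0.0000000 1.0000000
#> 2     2           2 400 -0.4248170 1.1914576
#> 3     3           3 400  0.5535542 0.6506702
```

Against the generator's truth this run attains a pairwise intercept true
positive rate of 0.833 with zero false positives (`tpr_fpr(...)`). The
estimated impact recovers the generating means (0, -0.5, +0.5) up to
sampling error, showing ability differences being absorbed by impact rather
than mislabeled as DIF.

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/cli/pairdif.R simulate --config inst/extdata/balanced_s4.yaml --out sim/
Rscript inst/cli/pairdif.R fit --responses sim/responses.csv --id-col respondent \
    --lam-grid 0.005,0.01,0.02 --tau-grid 0.2,0.5 --seed 1 --out fit/
Rscript inst/cli/pairdif.R evaluate --flags fit/pairwise_flags.csv --truth sim/truth.csv
```

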