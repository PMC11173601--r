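# gzigpfa

Factor analysis for microbiome count tables that are high-dimensional,
over-dispersed, and full of zeros.

16S OTU tables routinely have far more taxa than samples, variances well
above their means, and 40–50% zero cells — some biological absences, some
artefacts of limited sequencing depth. Transform-then-PCA pipelines discard
the count nature of the data and depend on an arbitrary pseudo count;
Poisson or plain zero-inflated Poisson factor models cannot absorb the
over-dispersion. This package fits a **zero-inflated generalized Poisson
(ZIGP) factor model** directly to the counts:

    y_ij ~ phi_ij * I{y=0} + (1 - phi_ij) * GP(T_i * lambda_ij, alpha)
    log(Lambda) = F L'            (rank K)
    logit(phi_ij) = -tau * log(lambda_ij)

where `T_i` is the relative library size (row total / median row total), the
generalized Poisson has mean `mu` and variance `mu (1 + alpha mu)^2`, and a
single shape `tau` ties the structural-zero probability to the rate: rare
taxa are more likely to be structurally absent. Estimation alternates ZIGP
regressions for the loadings `L` (columns on `F`) and scores `F` (rows on
`L`), each an EM over the latent structural-zero indicators with shared
global `(tau, alpha)`, followed by an SVD re-identification; the rank is
chosen by entry-wise N-fold cross-validation on held-out ZIGP likelihood.
The package also ships the benchmark generator for the model's simulation
study (six zero-inflation scenarios) and a log-PCA baseline with
Frobenius-loss scoring. See `vignettes/gzigpfa-model.Rmd` for the full
model account.

## Worked example

```r
library(gzigpfa)

# a benchmark dataset: 200 samples x 100 taxa, rank-3 signal, ZIGP counts,
# zero link calibrated to the 20% inflation level
sim <- simulate_scenario(scenario_spec(scenario = 1, zero_target = 0.2, seed = 7))
mean(sim$Y == 0)
#> [1] 0.4544

fit <- gzigpfa(sim$Y, K = 3, T = sim$spec$T)
fit
#> Zero-inflated generalized Poisson factor model
#>   200 samples x 100 taxa, rank K = 3
#>   tau = 0.7599, alpha = 0.1875
#>   log-likelihood -45567.12 after 5 iterations (converged)
```

The fit recovers the generating shape (`tau` used in simulation: 0.754) and
dispersion (0.2). Accuracy against the known truth, on the
column-normalized Frobenius scale `||.||_F / sqrt(m)`:

```r
frobenius_loss(fit$F %*% t(fit$L), sim$logLambda_true) / sqrt(ncol(sim$Y))
#> [1] 5.691426

log_pca_est <- log_pca(sim$Y, K = 3)$logLambda_hat
frobenius_loss(log_pca_est, sim$logLambda_true) / sqrt(ncol(sim$Y))
#> [1] 10.44623
```

— roughly half the error of the pseudo-count log-PCA baseline on the same
draw. The fitted model also predicts where zeros should fall:

```r
P <- predicted_zero_matrix(fit)   # phi-hat + (1 - phi-hat) * GP zero mass
mean(P)                           # 0.457, vs observed zero fraction 0.454
```

Rank selection and broom-style summaries:

```r
cv <- cv_select_rank(sim$Y, ranks = 1:6, N = 10, seed = 7)   # minutes
glance(fit)    # one-row summary: K, tau, alpha, loglik, iterations
tidy(fit)      # long-form factor scores (or loadings)
```

A thin command-line front end over the same functions lives in
`inst/cli/gzigpfa.R` with subcommands `fit`, `rank`, `simulate`, `bench`,
and `zeromap`.

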