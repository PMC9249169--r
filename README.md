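# scLatentCor

Noise-aware estimation of the correlation between two molecular layers
measured in the same single cells — e.g. a gene's expression and the DNA
methylation (or chromatin accessibility) of its promoter or a nearby
enhancer. Raw Pearson/Spearman correlations on such data are attenuated
toward zero by sequencing noise, dropout and uneven coverage, which leaves
standard analyses under-powered. `scLatentCor` recovers the latent
association by modelling the noise explicitly and decides significance with
a posterior-probability rule under expected-FDR control.

## Model

For each feature *j* and cell *i*, a latent bivariate Gaussian state ties
the layers together, and each layer is observed through its own noise model:

    X_ij = (X_ij1, X_ij2)' ~ N(mu_j, Sigma_j),
    Sigma_j = [[sigma_j1^2,             rho_j sigma_j1 sigma_j2],
               [rho_j sigma_j1 sigma_j2, sigma_j2^2            ]]

    y_ij1 | X_ij1 ~ ZIP(s_i exp(X_ij1); pi_j)     (expression counts,
                                                   known cell factor s_i)
    y_ij2 | X_ij2 ~ Binomial(n_ij, Phi(X_ij2))    (methylated/open calls
                                                   out of coverage n_ij)

`rho_j` is the denoised cross-layer correlation. Priors: Beta(2, 8) on
`pi_j`, N(m, I) on the means, Inv-Gamma(2.5, 4.5) on the sigmas, and a
Beta(15, 15) rescaled to [-1, 1] on `rho_j` (symmetric, so no sign is
favoured). Each feature's posterior is sampled independently with a
No-U-Turn Hamiltonian sampler (Rcpp; 5000 iterations, 3000 burn-in, 0.65
target acceptance, split-R-hat diagnostics by default).

A feature is called significant when the tail posterior probability
`p_j(gamma) = P(|rho_j| >= gamma)` reaches a threshold `alpha`: `gamma` is
calibrated as the 90% quantile of posterior-median `|rho|` on
negative-control (permuted) data, and `alpha` is grid-searched so the
expected false discovery rate stays below 10%. Pearson/Spearman +
Benjamini-Hochberg baselines, DIC comparison of zero-inflated vs plain
Poisson likelihoods, QC filters, window-based feature aggregation
(BED/GTF), and a synthetic-data generator are included.

## Worked example

Simulate 40 features (20 null, 20 with true `rho = 0.7`) for 100 cells, fit
every feature, calibrate the rule on a permuted copy, and call:

```r
library(scLatentCor)

ds   <- generate_dataset(sim_config(n_cells = 100, n_features = 40,
                                    rho_source = "values",
                                    rho_values = c(0, 0.7), seed = 7))
fits <- fit_all(ds, config = mcmc_config(n_samples = 2000, n_burnin = 1000,
                                         n_chains = 2, seed = 7))
neg  <- make_negative_control(ds, seed = 8)
negf <- fit_all(neg, config = mcmc_config(2000, 1000, n_chains = 2, seed = 8))
decide(fits, negf, decision_config(gamma = "auto", target_efdr = 0.10))
```

```
<decision_result> 40 features, 25 significant
  gamma = 0.1208, alpha = 0.4260, achieved EFDR = 0.0900 (target 0.10)
```

All 20 truly correlated features are among the 25 calls; the permutation
calibration set `gamma` to the largest correlation magnitude expected by
chance (0.12 at this depth), and the achieved EFDR sits at 9% against the
10% target. The Pearson baseline at the same nominal FDR
(`baseline_correlations(ds)`) recovers 21. Per-feature output:

```
    feature_id posterior_median_rho tail_prob significant
1 feature_0001               0.0237     0.229           0
2 feature_0002               0.5526     1.000           1
```

The same pipeline is scriptable end to end:

```sh
Rscript -e 'scLatentCor::main()' simulate --out sim --seed 1
Rscript -e 'scLatentCor::main()' negctrl  --in sim --out neg --seed 2
Rscript -e 'scLatentCor::main()' fit      --in sim --out fit --seed 3
Rscript -e 'scLatentCor::main()' fit      --in neg --out negfit --seed 3
Rscript -e 'scLatentCor::main()' decide   --fit fit --negctrl-fit negfit \
                                          --out calls --gamma auto
```

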