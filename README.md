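# nsfkit

Probabilistic factor models for multivariate spatial count data, built
for spatial transcriptomics: transcript counts `Y` (N observations × J
genes) measured at known spatial coordinates `X` (N × D).

Classical dimension reduction (PCA/factor analysis) ignores the
coordinates and allows negative factors that are hard to read as tissue
"parts". `nsfkit` implements **nonnegative spatial factorization (NSF)**:

```
y_ij ~ Poi(nu_i * lambda_ij)
lambda_ij = sum_l w_jl * exp(f_il),    w_jl >= 0
f_l(.)   ~ GP(beta_0l + x' beta_1l,  Matérn-3/2 kernel)
```

a Gaussian-process-regularized, nonnegative analog of probabilistic NMF,
plus the **hybrid NSFH** in which only `T` of the `L` factors are
spatial and the rest have i.i.d. Gaussian priors
(`lambda_ij = sum_{l<=T} w_jl e^{f_il} + sum_{l>T} v_jl e^{h_il}`), and
the comparator families: PNMF (`T = 0`), real-valued spatial
factorization RSF, and factor analysis FA (Gaussian likelihood on
centered log-normalized data). Inference is sparse variational with
inducing points (whitened parameterization), Monte-Carlo ELBO with
analytic reparameterization gradients, and Adam.

Around the models the package provides the full working pipeline:

* **Preprocessing** — Poisson-deviance gene ranking, size factors,
  log-normalization/centering, seeded train/validation splits.
* **Postprocessing** — simplex projection of nonnegative factorizations
  (SPDE- and LDA-style), gene- and observation-level **spatial
  importance scores** in [0, 1], top-gene extraction.
* **Evaluation** — held-out mean Poisson deviance, RMSE, factor/loading
  recovery by matched absolute Pearson correlation, loadings sparsity,
  score-recovery distance, per-factor Moran's I.
* **Simulation** — generative scenario I (binary spatial patterns,
  one-hot loadings of 20, mean `0.2 + FW'`, negative binomial shape 10)
  and scenario II (plus Bernoulli(0.2) nonspatial factors; split or
  mixed 12/8 loadings) on a 36×36 grid, with full ground truth.
* **IO / CLI** — Matrix Market + TSV dataset bundles, JSON model
  checkpoints, hashed result manifests, and a thin command-line wrapper
  (`inst/cli/nsfkit.R`) with `simulate`, `preprocess`, `fit`,
  `postprocess` and `evaluate` subcommands.

## Worked example

Simulate hybrid (spatial + nonspatial) count data with known truth, fit
NSFH, and ask which genes are spatially driven:

```r
library(nsfkit)

sim <- simulate_scenario2("quilt", "mixed", n_features = 500, seed = 1)
sp  <- split_train_validation(nrow(sim$data$Y), 0.05, seed = 1)
mask <- rep(FALSE, 1296); mask[sp$train] <- TRUE
d <- count_dataset(sim$data$Y, sim$data$X, train_mask = mask)

fit <- nsf_fit(d, "nsfh", L = 7, T = 4, M = 144, ip_strategy = "kmeans",
               config = fit_config(max_iter = 600, learning_rate = 0.02,
                                   seed = 1))

fac   <- model_factors(fit$model)              # posterior factor means
gamma <- gene_spatial_scores(fac$W, fac$V, fac$F, fac$H)

mean(sim$truth$true_gene_scores)               # truth: scores cluster near 0.6
#> [1] 0.6014349
score_recovery_distance(gamma, sim$truth$true_gene_scores)
#> [1] 0.2644897

Yv <- as.matrix(sim$data$Y[sp$validation, ])
mean_poisson_deviance(Yv, predicted_counts(fit$model, sim$data$X[sp$validation, ]))
#> [1] 2548.48
```

The truth scores in mixed mode cluster near 0.6 (each gene carries a
spatial loading of 12 and a nonspatial loading of 8 on components of
similar total activity); the fitted NSFH scores land within a Euclidean
distance of ~0.26 of the truth over all 500 genes, versus baselines of
√500 ≈ 22.4 (all-zero, i.e. PNMF) and ≈ 8.9 (all-one, i.e. NSF) on the
same replicate. Held-out deviance for NSFH (≈ 2548) is below both NSF
(≈ 2672) and PNMF (≈ 4456) at matched `L`, as expected when the data
genuinely mix spatial and nonspatial variation.

See `vignettes/nsfkit-methods.Rmd` for the models, the inference scheme,
every tunable default, and the design decisions.

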