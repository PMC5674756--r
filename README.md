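# pathfactor

Sparse Bayesian factor analysis of single-cell (and bulk) expression with
pathway-informed priors.

Single-cell RNA-seq variation mixes biological drivers with technical
confounders acting on the same genes. `pathfactor` models them jointly: it
decomposes a cells × genes expression matrix as

```
Y = X Wᵀ + ψ
```

where the columns of `X` are, in order, observed cell covariates,
**annotated factors** guided by pathway gene sets (MSigDB/REACTOME GMT
files), **sparse unannotated factors** (compact, putatively biological),
and **dense unannotated factors** (broad, confounder-like). Every weight
carries a spike-and-slab prior `w_{g,k} | z_{g,k}=1 ~ N(0, 1/α_k)` with a
point mass at zero otherwise; for annotated factors the gene-set
annotation enters the likelihood through assumed error rates
(FNR = 0.001, FPR = 0.01, replicated per cell), so the indicator
posterior `γ_{g,k} = P(z_{g,k}=1)` refines gene sets in a data-driven way.
An ARD prior `α_k ~ Γ(a,b)` deactivates unused factors; the posterior mean
of `1/α_k` — the expected variance explained on regulated genes — ranks
factors by **relevance**. Inference is coordinate-ascent variational Bayes
(cost `O(N·G·K)` per sweep, linear in cells and genes), with Gaussian,
hurdle (zero-inflated/dropout) and Poisson observation models handled
through locally tightened Gaussian bounds.

The package is aimed at analysts who want interpretable factors — which
pathways drive heterogeneity, which genes a pathway should gain or lose,
which cells a factor separates — plus residual matrices with confounders
regressed out.

## Worked example

Simulate a benchmark dataset — 3 active pathways, 5 inactive "negative"
pathways, one broad confounder, annotation corrupted at 10% false-negative
and 5% false-positive rates — and fit the model on the corrupted
annotation:

```r
library(pathfactor)

cfg <- pf_sim_config(n_cells = 100, n_genes = 1000, n_active_pathways = 3,
                     n_negative_pathways = 5, set_size_range = c(20, 60),
                     n_confounders = 1, confounder_gene_range = c(200, 400),
                     fnr_sim = 0.1, fpr_sim = 0.05, seed = 42)
sim <- simulate_dataset(cfg)
fit <- pathfactor(sim$Y, sim$corrupted_annotation, n_sparse = 0, n_dense = 2,
                  seed = 42, control = pf_control(max_iter = 300))
fit
#> Pathway-informed sparse factor model (gaussian noise)
#>   100 cells x 1000 genes, 10 factors (8 annotated, 2 dense)
#>   converged after 96 sweeps; ELBO 66064.5185
#>   top factors by relevance: pathway3, pathway1, pathway2, dense1, pathway8

head(factor_relevance(fit), 5)
#>     factor              kind    relevance n_annotated n_gained n_lost rank
#> 1 pathway3         annotated 1.0158939314          19        0      0    1
#> 2 pathway1         annotated 0.9101862118          53        0      0    2
#> 3 pathway2         annotated 0.8784926890          42        0      0    3
#> 4   dense1 dense_unannotated 0.5798359415          NA       NA     NA    4
#> 5 pathway8         annotated 0.0004449771          26        0      0    5
```

The three simulated drivers rank first with relevance near 1 (the
simulated weight variance); the dense factor absorbing the confounder
comes next; the five inactive pathways collapse to relevance ~4·10⁻⁴.
Downstream:

```r
aug <- augmentation_recovery(fit$state$logodds[, 1:8],
                             sim$corrupted_annotation, sim$true_annotation)
aug$auc_added     # ranking of wrongly deleted genes among non-members
aug$auc_removed   # ranking of wrongly inserted genes among members

res <- residual_expression(fit, sim$Y, remove = "dense1")  # confounder out
states <- export_factor_states(fit, c("pathway1", "dense1"))
```

`read_gmt()` + `build_annotation_matrix()` bring real GMT collections onto
a matrix; `size_factor_normalize()` and `filter_variable_genes()` cover
the recommended preprocessing; `write_results()` exports relevance,
factor-state, weight and refinement tables plus a JSON run log. A thin
command-line front end (`inst/cli/pathfactor-cli.R`, subcommands `fit`,
`simulate`, `benchmark`, `refine`, `residuals`) wraps the same functions.

See the methods vignette (`vignettes/pathfactor-methods.Rmd`) for the full
model, the variational updates, and every numerical choice.

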