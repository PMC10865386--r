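# pdmdc

Dynamic mode decomposition with control (DMDc) and its parametric extension
(pDMDc) for time-resolved postprandial metabolomics.

## The problem

A dietary challenge study measures M metabolites at T time points in I
individuals after each of D meals — a four-way response tensor.  Two questions
such data raise:

1. **Prediction** — given only a person's pre-meal baseline and the
   composition of a *new* meal, what will the full multivariate metabolite
   time course look like?
2. **Metabotyping** — which individuals share the same postprandial dynamics,
   i.e. belong to the same metabolic subtype?

`pdmdc` answers both with one model class: each response is a discrete linear
dynamical system driven by a single meal impulse,

    x[t+1] = A x[t] + B z[t],      z[1] = diet composition, z[t>1] = 0,

identified from snapshot matrices by a truncated-SVD least-squares fit
(`[A B] = X' W S^-1 U^T`).  Concatenating many responses (all diets of an
individual, or all individual x diet observations for a pooled model) makes
the fit *parametric* in the diet.  Because the data are baseline-subtracted,
the initial state is zero and predictions follow from the impulse alone —
baseline + diet composition genuinely suffice.  For metabotyping, one shared
orthonormal output map (SVD of all data) makes every individual's latent state
trajectories comparable; individuals are clustered per latent state by the
cosine similarity of those trajectories, with an unconstrained
CANDECOMP/PARAFAC decomposition as comparator.

A fully seeded synthetic-population generator reproduces the structure of the
study designs (a 79 x 8 x 17 x 3 crossover intervention; a 90-diet prediction
benchmark; a 100-individual two-cluster metabotype design), so every pipeline
is testable end to end without restricted data.

## Worked example

```r
library(pdmdc)

pop <- synthetic_preset("measured-like", seed = 42)  # 79 x 8 x 17 x 3 design
x   <- subtract_baseline(pop$tensor)

fit <- pdmdc(x, pop$diets, method = "pooled", rank = 40)
print(fit)
#> Parametric DMDc fit (pooled)
#>   data: 79 metabolites, 8 time points, 17 individuals, 3 diets
#>   truncation rank V = 40 (usable rank 82), fit residual = 9.896

summary(fit)
#> pDMDc pooled fit; rank V = 40
#>   training rollout R2 over 51 observations: mean 0.856 (range 0.794..0.908)
#>   leading singular values: 539.1, 98.3, 29.03, 5.602, 3.525, 2.645

# predict the response to a diet from baseline + composition alone
pred <- predict(fit, diet = pop$diets$inputs[, "baked_beef"], horizon = 8)

# the full evaluation protocol: resampled 60/20/20 splits, rank selection by
# the 30% validation-RMSE rule, R2 on held-out observations
rep <- resampling_experiment(x, pop$diets, n_iter = 10, seed = 42)
print(rep)
#> <experiment_report> 10 iterations, mean R2 = 0.8567
#> selected ranks: 4, 5
```

Each of the 51 (individual, diet) responses counts as one observation; the
report's `mean R2` is the average explained variance of held-out responses
predicted from baseline and diet composition only.  On this synthetic
population (5 latent states, ~5% measurement noise) the rule selects rank 4-5
and explains ~86% of held-out variance.

Metabotyping uses the shared-basis fit:

```r
shared <- pdmdc(x, pop$diets, method = "shared", latent_dim = 4)
ts     <- simulate(shared)                       # latent state trajectories
sim    <- cosine_similarity_matrix(ts, state = 1, diet = 1)
labels <- cluster_similarity(sim, k = 2)         # candidate metabotypes
```

or, end to end, `run_metabotyping_workflow(workflow_config(...))`, which adds
the CP comparator, cluster overlap, scree diagnostics and (when a clinical
table is supplied) ANOVA associations.

## Package layout

| Path | Contents |
|---|---|
| `R/tensor.R` | response tensor, diet/clinical tables, I/O, preprocessing |
| `R/dmdc.R` | snapshots, truncated SVD, DMDc fit, latent reduction, simulation |
| `R/pdmdc_fit.R` | diet concatenation, shared basis, per-individual/pooled fits, prediction |
| `R/pdmdc_class.R` | the `pdmdc()` front-end and its S3 methods |
| `R/eval.R` | splits, R², rank selection, resampling and diet-count experiments |
| `R/metabotype.R` | trajectories, cosine similarity, clustering, scree, CP-ALS, ANOVA |
| `R/synthetic.R` | population spec, ground-truth sampler, presets |
| `R/workflows.R` | validated config, end-to-end prediction/metabotyping pipelines |

The methods vignette (`vignettes/pdmdc-methods.Rmd`) documents the model, the
generator's design and its limits, and every numerical choice.
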