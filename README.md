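# npemorph

Supervised Neighbourhood Preserving Embedding (NPE) for multi-metric
brain morphometry.

`npemorph` is for researchers modelling neuroanatomical variation across
development from structural MRI derivatives.  Given per-subject feature
matrices for up to three morphometric metrics — voxel-wise tissue volume
(log-Jacobian) maps, vertex-wise cortical thickness and vertex-wise
cortical surface area — plus a metadata table (age, sex, acquisition
site, global covariates), it learns a low-dimensional linear manifold per
metric whose neighbour graph is supervised by the metadata, concatenates
the per-metric coordinates, and predicts age (Gaussian-process
regression) and sex (linear discriminant analysis) under leakage-safe
10-fold cross-validation.  A synthetic multi-site cohort generator with
known ground truth makes the whole pipeline testable without
access-restricted data.

## The model

NPE seeks a linear transformation *P* mapping a high-dimensional n × D
dataset *X* into an n × d subspace *Y = X P* (d ≪ D) that preserves each
point's locally linear neighbourhood structure:

1. **Supervised graph.**  Per metric, rows are mean-centred and reduced
   by SVD (retaining 95% of variance).  Image similarity
   *A*ᵢⱼ = exp(−‖xᵢ − xⱼ‖²/σ²) and age similarity
   *a*ᵢⱼ = exp(−(ageᵢ − ageⱼ)²/τ²) are combined as the elementwise
   product *A∘a*, with *A*ᵢⱼ = 0 where sexes differ (Sᵢ ≠ Sⱼ) and,
   optionally, where sites coincide (sᵢ = sⱼ).  Each subject keeps its
   k = 10 strongest neighbours.
2. **Reconstruction weights.**  Weights *W* (rows summing to 1, support
   on the graph) minimize ‖xᵢ − Σⱼ Wᵢⱼ xⱼ‖², solved per row from the
   local Gram system with a conditioned ridge.
3. **Projection.**  *P* solves the generalized eigenproblem
   XᵀMX p = λ XᵀX p with M = (I−W)ᵀ(I−W), taking the d = 3 smallest
   eigenpairs.  The solution is linear, so unseen subjects are projected
   without re-embedding, and each manifold axis has an explicit length-D
   feature-weight map (`embedding_vectors()`).
4. **Joint manifold and prediction.**  Each metric's coordinates are
   rotated so axis 1 aligns with age and axis 2 with sex, then
   concatenated, Y_c = (Y_v, Y_t, Y_a); a GP regressor (squared
   exponential + noise, marginal-likelihood fitted) predicts age and LDA
   predicts sex from Y_c.

See the methods vignette
(`vignettes/supervised-npe-methods.Rmd`) for assumptions, parameter
defaults, numerical choices and the generator's calibration.

## Worked example

```r
library(npemorph)

cohort <- generate_cohort(generator_spec(
  n_subjects = 120, n_features = c(volume = 60, thickness = 60, area = 60),
  seed = 3))
cfg    <- npe_config(n_folds = 5, random_seed = 2)
report <- crossval_evaluate(cohort$table, cohort$matrices, cfg)
report
#> evaluation_report: n=120, 5 folds
#>   age:  MAE = 1.047 y, Pearson r = 0.963
#>   sex:  accuracy = 92.5%
#>   site ANOVA: F(3,116) = 0.56, p = 0.64
```

The report says: pooled out-of-fold age predictions are off by about one
year on average and track chronological age closely (r = 0.96); sex is
classified correctly for 92.5% of subjects; and absolute age error shows
no site effect (p = 0.64), i.e. the supervised graph has not let scanner
identity leak into the embedding.

Training and out-of-sample projection are separate steps when needed:

```r
model <- npe_fit(cohort$table, cohort$matrices, cfg)   # full-cohort fit
write_model(model, "model.json")                       # text archive
pred  <- npe_predict(read_model("model.json"),
                     cohort$matrices, table = cohort$table)
```

A command-line wrapper with `simulate`, `fit`, `predict` and `evaluate`
subcommands is installed at
`system.file("cli", "npemorph", package = "npemorph")`.

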