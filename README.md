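# habsuit

Habitat-suitability mapping for migratory waterbirds from GPS telemetry and
multi-band satellite imagery, in two stages:

1. **Stopover detection.** GPS fixes are scored with a Gaussian-influence
   spatio-temporal density and clustered into stopovers — the places where
   migrating birds pause to rest, feed or molt — by a DBSCAN-style
   expansion whose core criterion is the density, not a neighbour count.
2. **Patch classification.** Stopovers label 16×16-pixel patches of six-band
   raster scenes. A dual-branch convolutional network — a 2-D image branch
   with parallel 1×1/3×3/5×5 filters and a 1-D branch over a 15-day
   temperature window — is trained on the labelled patches; its 512-unit
   penultimate features train an RBF support vector machine, and per-patch
   probabilities are quantized into a five-level ordinal suitability map.

The package is aimed at movement ecologists who have telemetry for a
colonial species and want spatially explicit suitability maps without a
field-survey occurrence dataset. It ships the comparison baselines
(grey-level co-occurrence texture features + SVM, an image-only CNN, a
simplified three-block DenseNet), an evaluation harness
(accuracy/F1/AUC/precision/recall), and seeded synthetic generators for
trajectories, scenes and station temperatures, so the entire pipeline runs
and is tested end-to-end without any external data.

## The model

Each fix `p = (loc, t)` on trajectory `T` is scored

```
f(p) = f_traj(p) + α · f_global(p),          α ∈ [0, 1]

f_traj(p)   = Σ exp(−d(x, p)² / 2σ²)   over x ∈ T with |t_x − t| ≤ ξ_t
f_global(p) = Σ exp(−d(x, p)² / 2σ²)   over x ∉ T with d(x, p) ≤ ξ_d
```

with great-circle distances by default (σ = 1000 m, ξ_t = 24 h,
ξ_d = 5000 m, α = 0.5). Fixes with `f ≥ τ` (default: the 80th percentile)
are core points; clusters are connected components of core points within
ξ_d, with nearby non-core fixes attached. The global term encodes
gregariousness: a fix surrounded by *other* animals' fixes is stronger
stopover evidence than a solitary dwell.

The network applies rectified cross-correlations (1-D and 2-D), batch
normalization and max pooling, fuses both branches in a 512-unit fully
connected layer, and trains with Adam on softmax cross-entropy under
normalized (Glorot) initialization. The convolution engine is implemented
in R over BLAS matrix products and is checked against naive nested-loop
oracles and finite-difference gradients in the test suite.

## Worked example

```r
library(habsuit)

cfg    <- sim_config()                  # 3 animals, 5 planted stopovers
tracks <- gen_trajectories(cfg)
stops  <- cluster_stopovers(tracks, density_params())
glance(stops)
#>   n_stopovers n_points n_core n_noise   tau
#> 1           5     1110    222     259  36.2
tidy(stops)
#>   stop_id n_points   lon   lat t_start             t_end
#> 1 C01          168  98.3  36.3 2009-03-02 10:00:00 2009-03-07 02:00:00
#> 2 C02          174  98.5  36.5 2009-03-08 02:00:00 2009-03-13 00:00:00
#> 3 C03          172  98.7  36.7 2009-03-14 00:00:00 2009-03-18 20:00:00
#> 4 C04          170  98.9  36.9 2009-03-19 20:00:00 2009-03-24 14:00:00
#> 5 C05          167  99.1  37.1 2009-03-25 16:00:00 2009-03-30 08:00:00
```

All five planted stopovers are recovered; each centroid lands within ~150 m
of its planted centre and every dwell fix joins the matching cluster
(`augment(stops)` holds the per-fix assignments; `autoplot(stops)` draws
them).

Training the classifier on a synthetic patch set whose class signal is
split between image texture and temperature (2000 samples, 70/20/10
train/validation/test, 5 epochs, seed 11):

```r
samples <- gen_fusion_samples(cfg, 2000) |>
  split_samples(70, 20, 10, seed = 11)
mcnn <- train_mcnn(build_mcnn(seed = 11), samples,
                   train_config(epochs = 5, seed = 11))
test  <- dplyr::filter(samples, split == "test")
evaluate(predict(mcnn, test, type = "prob")$prob_positive, test$label)$accuracy
#> [1] 0.905
```

The image-only ablation reaches 0.830 on the same split and seed, and an
RBF-SVM trained on the dual-branch model's validation-split features scores
0.925 — the dual-branch > image-only ordering, and the gain from the SVM
head, are what the acceptance checks assert across three seeds. A trained
model plus SVM turn any scene into a map with
`predict_map(scene, mcnn, svm, temps)`; `autoplot()` renders the five-level
legend.

The full pipeline (simulate → clean → cluster → build-samples → train →
evaluate → predict-map) also runs from the command line:

```sh
Rscript inst/cli/habsuit all --out run1 --seed 7
```

## Layout

* `R/` — generators (`synthetic.R`), track ingest (`trajectory.R`),
  clustering (`dbic.R`), patch building (`samples.R`, `scene.R`), the
  network engine and model (`nn.R`, `mcnn.R`), SVM/metrics/maps
  (`suitability.R`), baselines (`baselines.R`), pipeline (`pipeline.R`).
* `tests/testthat/` — unit, property and acceptance tests with independent
  brute-force oracles in `helper-oracles.R`.
* `vignettes/habitat-suitability-methods.Rmd` — the methods notes: model
  assumptions, parameter defaults and rationale, numerical choices, what
  the synthetic system does and does not demonstrate.
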