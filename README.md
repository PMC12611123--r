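# vegrestore

Predicting ecological-restoration outcomes from multivariate
environmental time series with a hybrid **rule-tree → BiGRU →
self-attention** architecture, plus the tooling a study of this kind
needs around it: a synthetic high-plateau monitoring-panel generator
with known ground truth, a leakage-guarded preprocessing and evaluation
pipeline, Shapley-value attribution, and an irrigation dose-response
analysis for arid sites.

The package is aimed at quantitative ecologists and methods researchers
who want a fully inspectable, desk-scale implementation of this model
family — every layer, including the gradients, is plain R that can be
read, tested and modified.

## The model

For a window of `T = 30` monthly steps of `D = 6` covariates
(temperature, precipitation, soil moisture, fractional vegetation cover,
irrigation volume, planting density), the predictor chains:

1. **Cubist/M5-style rule tree** — greedy standard-deviation-reduction
   partitioning (`sd(parent) − Σ (n_c/n)·sd(child_c)`), at most 14 rule
   regions with per-leaf linear models and a global backup model; each
   time step becomes a 16-vector of rule indicators plus the local and
   global predictions.
2. **Two-layer bidirectional GRU** (64 units/direction, dropout 0.3
   between layers) over the per-step rule features:
   `z_t = σ(W_z x_t + U_z h_{t−1} + b_z)`, `r_t = σ(W_r x_t + U_r h_{t−1} + b_r)`,
   `h̃_t = tanh(W_h x_t + U_h (r_t ⊙ h_{t−1}) + b_h)`,
   `h_t = (1−z_t) ⊙ h_{t−1} + z_t ⊙ h̃_t`, with forward and backward
   states concatenated per step.
3. **Scaled dot-product self-attention** — `A = rowsoftmax(QKᵀ/√d_k)`
   over time steps, per-row contexts `AV` fused by row-averaging, and an
   affine regression head.

Training minimizes MSE on standardized targets with Adam (lr 0.001,
batch 32), early-stopping on validation loss (patience 10).  Metrics:
RMSE, MAPE, R², and the within-±10%-relative-error prediction accuracy;
paired t-tests compare model variants on shared test windows.

The default target is the **vegetation restoration rate**, the relative
FVC change over the window, `(FVC_end − FVC_start) / max(FVC_start,
0.05)`; a survival-rate task is available via `make_windows(task =
"survival")`.

## Worked example

```r
library(vegrestore)

# 104 sites x 60 months, three altitude bands, 25% arid sites
panel <- generate_panel(scenario_config(seed = 42))

# clean -> window -> chronological 70/20/10 split -> train-only statistics
prep <- prepare_splits(panel, train_config(max_epochs = 30, seed = 42),
                       max_windows = 3217)
model <- train_model(prep, "full")
ev <- evaluate_split(model, prep, "test")
ev$metrics
#> RMSE 0.0323 | MAPE 3.81% | R2 0.9059 | accuracy(+-10%) 95.0% | n = 322

round(vapply(ev$by_band, `[[`, 0, "accuracy"), 1)
#>     <3500m 3500-4500m     >4500m
#>       91.4       98.7       91.8
```

The metrics say: on the held-out (chronologically last) 322 windows the
model predicts the 30-month restoration rate with a mean absolute
percentage error under 4%, 95% of predictions fall within ±10% of the
truth, and every altitude band stays above 91%.

The irrigation dose-response over arid sites recovers the planted
ground truth:

```r
dr <- dose_response(panel)
dr$gain_per_10pp   # ~15 percentage points survival per +10 pp irrigation
dr$fitted          # fitted survival at 40% irrigation: ~60%
```

Shapley attribution of a trained model (`attribute_model`,
`global_importance`) ranks variable contributions; the generator's
dominant drivers (temperature, then precipitation) head the ranking.

A command-line front end wrapping simulate / train / explain lives at
`inst/cli/vegrestore.R`; every command writes a JSON manifest (resolved
configuration, seed, input/output hashes) next to its outputs.

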