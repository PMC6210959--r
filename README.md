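# elmbloom

Extreme learning machine (ELM) models for predicting weekly chlorophyll-a
concentration — the standard proxy for algal-bloom intensity — at river
monitoring stations, with special support for weir pairs: does the
*upstream* station's chlorophyll-a improve *downstream* prediction?

The package is aimed at water-quality modellers working with weekly
monitoring series of air temperature (AT, °C), rainfall (RF, mm/week),
solar radiation (SR, MJ/m²), total nitrogen (TN, mg/L), total phosphorus
(TP, mg/L), their ratio (NP) and chlorophyll-a (Chla, µg/L).

## The model

An ELM is a single hidden layer feedforward network

f_L(x) = Σᵢ βᵢ G(wᵢ, bᵢ, x),   i = 1 … L,

whose hidden weights wᵢ and biases bᵢ are drawn at random and never
updated; only the output weights β are estimated, in a single pass, by the
minimum-norm least-squares solution β̂ = H⁺T, where H is the hidden output
matrix and H⁺ its Moore–Penrose pseudoinverse. Hidden nodes may be
sigmoid (default), Gaussian RBF, or sine.

Around this core the package provides:

* the two feature designs for a weir pair — `ELM1` (7 drivers + lagged own
  chlorophyll) and `ELM2` (+ lagged upstream chlorophyll) —
  with a 50/50 chronological train/test split (`assemble_features()`,
  `split_half()`);
* hidden-node selection by a 2–30 validation sweep
  (`select_hidden_nodes()`);
* skill metrics: RMSE, Nash–Sutcliffe-form R², Gaussian-form AIC, and the
  feature-design improvement percentages (`rmse()`, `r_squared()`,
  `aic_score()`, `improvement_percent()`);
* comparison baselines: multiple linear regression, a backpropagation
  neural network (learning rate 0.001, 1000 epochs), and ANFIS with fuzzy
  c-means rules — one-pass LSE consequents plus the hybrid-learning curve
  experiment (`fit_linear_regression()`, `train_nn_bp()`,
  `build_anfis_fcm()`, `train_anfis_hybrid()`);
* a calibrated synthetic weir-pair generator so the full pipeline is
  testable without monitoring-network access (`synth_config()`,
  `generate_pair()`);
* pipeline drivers reading a YAML config and writing CSV artifacts
  (`cmd_simulate()`, `cmd_fit()`, `cmd_compare()`).

See the methods vignette (`vignettes/algal-bloom-elm-methods.Rmd`) for the
full model account, parameter meanings and design rationale.

## Worked example

Generate four years of coupled weekly data, build the upstream-augmented
design, select the hidden-node count, and compare against linear
regression:

```r
library(elmbloom)

pair  <- generate_pair(synth_config(seed = 1))
set2  <- assemble_features(pair$down, variant = "ELM2", up = pair$up)
split <- split_half(set2)                     # first half trains
sweep <- select_hidden_nodes(split$train, split$test, 2:30, seeds = 1:10)
elm2  <- evaluate_elm_seeds(split, L = sweep$selected_L, seeds = 1:30,
                            label = "ELM (ELM2)")
lr    <- evaluate_model(fit_linear_regression(split$train), split,
                        label = "Multiple LR")
sweep; elm2; lr
```

```
Hidden-node sweep (sigmoid, 10 seed(s) per candidate)
  candidates 2..30, selected L = 30 (test RMSE 5.256)
ELM (ELM2)  (capacity 30, 30 seeds)
  R2    train 0.97  test 0.91
  RMSE  train 2.5  test 5.3
  AIC   train 246.4  test 400.7
Multiple LR  (capacity -, 1 seed)
  R2    train 0.94  test 0.91
  RMSE  train 3.6  test 5.4
  AIC   train 284.8  test 364.3
```

The sweep picks 30 hidden nodes; the seed-averaged ELM reaches a test RMSE
of 5.3 µg/L against 5.4 µg/L for the linear baseline — the nonlinear
driver response (temperature-gated growth diluted by storm washout) is
what the random-feature expansion captures and a linear fit cannot.

Quantifying what the upstream covariate buys:

```r
set1  <- assemble_features(pair$down, variant = "ELM1")
elm1  <- evaluate_elm_seeds(split_half(set1), L = sweep$selected_L,
                            seeds = 1:30, label = "ELM (ELM1)")
improvement_percent(elm1, elm2)
```

```
     metric    before     after improvement_pct
   r2_train 0.9659342 0.9711248             0.5
    r2_test 0.8830324 0.9110918             3.2
 rmse_train 2.6708544 2.4601246             7.9
  rmse_test 6.0787862 5.2859111            13.0
```

Positive percentages mean the upstream covariate improved the metric —
here a 13% lower test RMSE, the expected effect when upstream-to-downstream
transfer is present (`coupling = 0.5` in the generator; at `coupling = 0`
the two designs are statistically indistinguishable).

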