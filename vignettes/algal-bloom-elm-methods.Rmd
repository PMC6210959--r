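---
title: "Methods: extreme learning machines for weekly chlorophyll-a prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extreme learning machines for weekly chlorophyll-a prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elmbloom)
```

## The problem

Regulated rivers with sequential weirs experience recurrent summer
cyanobacterial blooms. The operational proxy for bloom intensity is the
chlorophyll-a concentration (ug/L) measured weekly at each monitoring
station, together with weather (air temperature, rainfall, solar radiation)
and nutrient chemistry (total nitrogen, total phosphorus and their ratio).
`elmbloom` builds one-week-ahead regression models of downstream
chlorophyll-a from these drivers, with particular attention to whether the
*upstream* station's chlorophyll-a — biomass that will be transported over
the weir — improves downstream prediction.

## The model

The core estimator is the extreme learning machine (ELM): a single hidden
layer feedforward network

$$f_L(x) = \sum_{i=1}^{L} \beta_i \, G(w_i, b_i, x),$$

in which the hidden-node parameters $(w_i, b_i)$ are drawn at random once
and never updated, and only the output weights $\beta$ are estimated. With
the hidden output matrix $H_{ij} = G(w_j, b_j, x_i)$, the fit is the
one-pass least-squares estimate

$$\hat\beta = H^{+} T,$$

the minimum-norm solution via the Moore–Penrose pseudoinverse (equal to
$(H'H)^{-1}H'T$ whenever $H'H$ is nonsingular). There is no iterative
training. Hidden nodes may be `sigmoid` (default), Gaussian `rbf`, or
`sine`.

Design choices where the method leaves freedom:

* **Random-weight law.** Weights and additive biases are i.i.d. uniform on
  $[-1, 1]$; RBF inverse widths are uniform on $(0, 1]$ so they are
  strictly positive. Uniform bounded draws keep pre-activations in the
  responsive part of the sigmoid after standardization.
* **Input standardization.** Features are z-scored with *training*
  statistics (on by default). Raw scales here span five orders of magnitude
  (mm of rain next to mg/L of phosphorus); without standardization sigmoid
  nodes saturate.
* **Pseudoinverse.** SVD-based; singular values below
  $\max(N,L)\,\epsilon\,\sigma_{\max}$ are truncated, so rank-deficient
  hidden matrices are handled where the normal equations are not.
* **Nested node draws.** For a fixed seed, the first $L$ nodes of a larger
  layer coincide with the $L$-node layer (draws are consumed node by node).
  Enlarging the layer therefore only widens the span of $H$, and training
  error is exactly non-increasing in $L$ seed-for-seed — a property the
  test suite asserts rather than approximates.
* **Seed averaging.** Because a single random draw of the hidden layer is
  itself a source of variance, reported metrics are by default means over
  30 hidden-layer seeds (`evaluate_elm_seeds()`); a single-seed mode is the
  `seeds = <one seed>` special case.

## Feature designs and data conventions

For target week $t$, the base design (**ELM1**, $d = 7$) uses the
contemporaneous drivers $AT(t), RF(t), SR(t), TN(t), TP(t), NP(t)$ plus
the one-week-lagged chlorophyll $Chla(t-1)$. The upstream-augmented design
(**ELM2**, $d = 8$) appends $Chla_u(t-1)$, the upstream station's
chlorophyll lagged one week.

Conventions the weekly-data literature leaves open, fixed here once:

* **Lags.** Only the chlorophyll terms are lagged ("7 days prior");
  exogenous drivers enter at the target week. This keeps the
  autoregressive term causal and the driver response contemporaneous.
  The upstream covariate uses the same one-week lag as the downstream
  autoregression, matching the weekly transport timescale of a weir pair.
* **Alignment.** Sites are aligned by calendar week-start date; the lagged
  value must come from the week exactly 7 days earlier, so gaps do not
  silently shift lags.
* **Missing data.** Assembled rows with any missing predictor or target
  are dropped (listwise); no imputation.
* **Split.** The 50/50 train/test split is chronological by default
  (first half trains). For an autocorrelated seasonal series a random
  split leaks information across the boundary; the random mode is kept
  for sensitivity analyses.

## Model selection

`select_hidden_nodes()` sweeps $L = 2, \dots, 30$, averaging train and
test RMSE over hidden-layer seeds, and selects the $L$ minimizing mean
test RMSE, breaking ties toward the smaller (more parsimonious) count.
Candidates at or above the training-set size are flagged as unstable
(interpolation regime) but still swept.

## Metrics

* **RMSE** in ug/L.
* **$R^2$** is implemented in the efficiency form
  $1 - \sum(Y-\hat Y)^2 / \sum(Y-\bar Y)^2$ (the Nash–Sutcliffe
  coefficient): 1 is perfect, 0 matches the observed mean, negative is
  worse than the mean. Parts of the water-quality literature print this
  formula under the label "Pearson correlation coefficient"; the formula,
  not the label, is authoritative here. A squared-Pearson variant is
  available via `r_squared(..., method = "pearson")`.
* **AIC** in the Gaussian least-squares form $n \ln(SSE/n) + 2k$, with
  $k$ the fitted-parameter count: $L$ for an ELM (only output weights are
  estimated), $d+1$ for linear regression, $r(d+1)$ for a first-order
  ANFIS. Published AIC values computed with undocumented constants are not
  comparable across software; within-package comparisons are.
* **Improvement percentages** between feature designs:
  $(after-before)/before \times 100$ for $R^2$ and
  $(before-after)/before \times 100$ for RMSE, so positive means improved.
  Displayed at one decimal, stored at full precision.

## Baselines

* **Multiple linear regression** (`fit_linear_regression()`): OLS with
  intercept through `stats::lm.fit`; constant columns get zero slope, other
  rank deficiencies fall back to the minimum-norm pseudoinverse with a
  warning.
* **NN-BP** (`train_nn_bp()`): one sigmoid hidden layer with linear
  output, trained by full-batch gradient descent on the SSE at learning
  rate 0.001 for 1000 epochs (the conventional comparison settings), on
  z-scored inputs and target. The hidden width defaults to the
  ELM-selected node count so capacities match.
* **ANFIS-FCM** (`build_anfis_fcm()`): a first-order Takagi–Sugeno system
  whose rules come from fuzzy c-means clustering of the z-scored inputs.
  Antecedents are per-feature Gaussians centered at the cluster centers
  with spreads equal to the membership-weighted standard deviation (floored
  at $10^{-3}$ of the feature range); consequents are fitted in one pass by
  least squares on the rule-weighted design. Rule counts with
  $r(d+1) \ge N$ are refused — the consequent fit must stay
  overdetermined; in the weekly regime ($d = 7$–$8$, $N \approx 100$
  training rows) this admits $r = 2, 3$ and excludes larger rule bases.
  FCM is implemented in the package because the invariant tests need the
  per-iteration objective trace; the test suite cross-checks the optimum
  against `e1071::cmeans`.
* **Hybrid learning** (`train_anfis_hybrid()`): the classical forward
  (LSE consequent refit) / backward (gradient step on centers and spreads)
  loop, with fixed step 0.01 and global gradient-norm clipping at 3. On
  short noisy series the training curve falls while the test curve rises —
  the overfitting diagnosis that motivates using the one-pass fit for
  reporting.

## The synthetic weir-pair generator

No public dataset accompanies the monitoring campaign this package is
designed around, so `generate_pair()` produces statistically analogous
upstream/downstream weekly series; every pipeline stage and every
empirical claim in the test suite runs on these.

What it emulates, with defaults calibrated to published monitoring
envelopes (annual rainfall ~1050–1450 mm with a July–August monsoon,
annual mean air temperature ~14 °C, solar radiation ~14.4 MJ/m², TN mean
2.6–3.7 mg/L, TP ~0.055 mg/L, downstream chlorophyll-a long-run mean in
the 19–26 ug/L band with maxima well below 150 ug/L):

* sinusoidal annual cycles for temperature and solar radiation with
  Gaussian noise;
* Gamma-distributed weekly rainfall (right-skewed, non-negative) whose
  scale inflates around the monsoon peak;
* mean-reverting AR(1) nutrients with storm-loading pulses and positivity
  clamps;
* chlorophyll as the recursion
  $x(t) = \left[f(t) + a\,x(t-1) + c\,x_u(t-\ell)\right]
  e^{-\kappa\,RF(t)} + \varepsilon(t)$, clamped at 0.1 ug/L, where
  $f = $ base $+$ growth $\times$ logistic temperature gate $\times$
  Monod phosphorus limitation $\times$ solar modulation.

The washout factor $e^{-\kappa RF}$ is multiplicative because dilution
acts on the standing concentration: a storm removes a *fraction* of the
biomass present, not a fixed amount. Scientifically this is the standard
first-order washout model; statistically it creates rainfall-by-stock
interactions that no linear model can represent, which is precisely what
makes the ELM-vs-LR comparison informative on synthetic data. The
recursion is stable because $a\,e^{-\kappa RF} < 1$ whenever the
autocorrelation $a < 1$.

The `coupling` parameter $c$ transfers lagged upstream biomass downstream.
At the default $c = 0.5$ the upstream covariate carries genuine predictive
signal (the upstream-augmented design should win); at $c = 0$ it is pure
noise (the two designs should tie). The test suite asserts exactly this
contrast with a paired sign test over 50 generated pairs.

What it does **not** emulate: hydrodynamics and residence time, multi-weir
cascades, sensor error structure, missing-data patterns, long-term trends,
or ecological regime shifts. Tests passing on these series therefore
demonstrate that the pipeline's algorithms behave as specified under the
assumed statistical structure — not that any model here is adequate for a
particular real river.

## Problem sizes and numerical conventions

The suite and the acceptance script use: 208-week series (about 4 years)
for pipeline runs; 50 generated pairs for the upstream-covariate contrast
(fixed $L = 12$, 5 seeds per model, which keeps the paired comparison
sharp and cheap); 20 replicates of the hybrid-ANFIS experiment on an
i.i.d. 60-point, 4-feature linear-plus-noise sample (30 train / 30 test,
50% relative noise) — a set on which rule localization can only chase
noise, so the overfitting pattern is structural rather than incidental;
200 random instances for the least-squares oracle comparison; and 100
seeds for the interpolation check. These sizes are the package's own
reporting choices.

Degenerate inputs are errors, not silent results: constant observed
targets (undefined $R^2$), zero or negative SSE in the AIC, all-identical
points in FCM, fewer than 4 rows in the splitter, non-finite inputs
anywhere in the linear algebra. Model serialization (`elm_save()` /
`elm_load()`) writes JSON at full double precision, so a round trip
reproduces predictions exactly.

## Known limitations

* The ELM's random features make single-draw performance noticeably
  variable at the $N \approx 100$ scale; always read the seed-averaged
  reports, and expect heavy-tailed single-seed test errors at large $L$.
* The chronological split confounds generalization with the slow drift of
  the nutrient processes; that is deliberate (it mirrors forecasting
  practice) but it makes test metrics conservative.
* AIC values are only comparable within this package's convention.
* The generator's parameters are calibrated to published summary
  envelopes, not fitted to any monitoring series; it supports method
  verification, not ecological inference.
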