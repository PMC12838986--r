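---
title: "Breathprint simulation and BI-RADS 4 risk stratification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breathprint simulation and BI-RADS 4 risk stratification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

BI-RADS 4 ("suspicious") mammography findings are referred to biopsy, yet
most of these biopsies return benign. A breath test with high sensitivity
and high negative predictive value (NPV) could act as a *rule-out* layer:
a negative result in a low-prevalence subgroup (4A, 4B) would support
surveillance instead of an immediate invasive procedure. `breathstrat`
implements the full computational side of such a study: a generative
model of electronic-nose (eNose) breathprints with a plantable malignancy
signal, the device quality-control (QC) and cohort exclusion rules, the
normalization and fold-construction stage, a dual-input
autoencoder-classifier, and a nested cross-validation (CV) ensemble
evaluation that reports per-subgroup sensitivity, specificity, NPV and
PPV as mean ± SD over repeated runs.

Everything runs from synthetic data: the generator's defaults encode the
reference study population (176 enrolled; 125 analyzed participants with
437 QC-passing breathprints; 85 BI-RADS 4 participants with 309
breathprints at malignancy rates 6% / 13% / 49% in 4A / 4B / 4C). No
clinical data are included or required.

## The sensor and cohort generator

A breathprint is a 32-channel resistance time series at 1 Hz over three
phases: ambient sampling (30 s), breath capture (5–15 s, drawn uniformly
per replicate), sensor recovery (250 s). Each film `i` follows
first-order sorption kinetics:

* ambient: `R_i(t) = R0_i`;
* capture (onset `t_on`):
  `R_i(t) = R0_i (1 + A_i (1 - exp(-(t - t_on)/tau_ads_i)))` with
  `A_i = sum_j S_ij c_j`;
* recovery (onset `t_rec`, peak response `P_i`):
  `R_i(t) = R0_i (1 + P_i ((1 - rho) exp(-(t - t_rec)/tau_des_i) + rho))`.

`S` is a 32 × K gain matrix (K = 8 compound classes by default) drawn
log-normally with random signs — cross-reactive films, no two alike; `c`
is the latent VOC concentration vector; `rho` (default 5%) is a slow
residual fraction that leaves healthy records below the 20% recovery
threshold while an injected `incomplete_recovery` failure (40% tail)
exceeds it. Multiplicative Gaussian noise is applied throughout with
relative SD `1e-5`. That noise floor is a calibration choice: the QC
ambient-stability rule demands a relative span below 0.01% over 30
samples, so the device noise must sit well under `1e-4/4` for a healthy
record to pass; `1e-5` leaves an order-of-magnitude margin while still
exercising the noise-referenced breath-capture test.

Malignancy enters as a mean shift of `effect_size` within-class SDs on a
designated subset of compound classes (default: 2 SDs on 4 of 8). Both
classes share the covariance, so `effect_size = 0` makes the two classes
literally the same generative law — the null pipeline. Within-class
variance splits into a participant-level component and a
replicate-level component (`replicate_var_frac = 0.3`): replicates of
one participant are correlated, which matters for fold construction and
for the drift check below.

What the generator does *not* emulate: real VOC chemistry, humidity or
temperature confounders, capnography gating, inter-device variation and
long-term sensor aging. Passing tests therefore demonstrate that the
pipeline recovers a planted signal under the study's geometry — not that
the real assay works.

## Quality control and exclusions

The four record-level criteria run in a fixed order and short-circuit:

1. **Ambient stability** — relative span `(max - min)/mean` of every
   channel over the ambient window strictly below `1e-4` (0.01%).
2. **Breath capture** — the maximum absolute ambient-referenced response
   during capture plus early recovery must exceed `theta = 5` ambient
   noise SDs on at least `m = 3` channels. On noiseless records the
   floor is machine epsilon, so zero signal still fails.
3. **Data integrity** — no time-axis gaps at the declared rate, no
   missing values.
4. **Recovery** — each of the `q = 5` most-responsive channels must end
   recovery strictly below 20% of its own peak.

The ordering resolves a degenerate case: a record with no captured
breath has near-zero peaks and would pass the recovery ratio vacuously;
it never reaches criterion 4. Participants are excluded by BI-RADS
status first (inconclusive / unreported / ineligible category), then by
all-attempts-failed among the eligible, so each exclusion occupies one
bucket and `enrolled = analyzed + sum(exclusions)` holds exactly.

**Drift check.** For each QC-passing breathprint the signed extremum of
the normalized response is computed; records are split into four
chronological subsets and consecutive subsets compared by two-sided
Welch t-tests. Two design points: (i) the test runs on *participant
means* within each subset, because replicate extrema are clustered
(ICC ≈ 0.3 under the generator defaults) and a breathprint-level t-test
is anti-conservative — roughly a fifth of perfectly stationary cohorts
would be flagged; (ii) a stationarity check belongs on a signal-free
cohort: with a planted class signal, enrollment-order imbalance in
case mix shifts the extremum distribution between subsets and the test
would partly measure epidemiology rather than the device. A degenerate
zero-variance comparison with equal means returns p = 1.

## Preprocessing and fold construction

Each record is normalized per channel as `v_i(t) = (R_i(t) - R0_i)/R0_i`
with `R0_i` the mean over the settled last 10 s of the ambient window —
the reference statistic is a package choice; the tail avoids any
residual equilibration at window start. Series are cropped or edge-padded
at the tail to 295 samples (30 + 15 + 250 at 1 Hz); the ambient phase and
capture onset sit at fixed offsets, so alignment is preserved.

Folds partition *participants*, never breathprints: replicates of one
participant always share a fold. Splitting them would let the model
re-identify a participant across train and test and inflate every
metric. Stratification is by the joint (BI-RADS category, outcome)
stratum; members of each stratum are dealt to the currently least-loaded
folds, so per-stratum and total fold sizes both stay within one. Defaults
are `k_out = 5` outer folds, `k_in = 3` inner folds; each repetition
re-randomizes folds and model initializations from an independent
sub-seed.

## The fusion model

Two encoders map the breathprint tensor `d` (32 × 295) and the one-hot
BI-RADS category `c` into a shared latent vector `z` (16 units); from
`z`, one decoder reconstructs the breathprint, a second reconstructs the
category distribution, and a small MLP head predicts malignancy. The
composite loss is

```
L = lambda_task * L_Task + lambda_bp * L_Breathprint + lambda_birads * L_BIRADS
```

with `L_Breathprint` the mean squared error on `d`, `L_BIRADS` the
categorical cross-entropy on `c`, and `L_Task` a class-weighted binary
cross-entropy whose malignant-example weight is multiplied by an extra
false-negative penalty (`fn_penalty_multiplier = 3`; class weights are
inverse prevalence by default). All three `lambda` default to 1.

The breathprint branch starts with a *fixed* average-pooling of each
channel into 16 temporal bins (~18 s each), and the decoder reconstructs
the binned representation, expanded back to the full series as a
piecewise-constant curve. Because the bins partition the time axis, the
full-series MSE decomposes exactly into a bin-weighted MSE on the pooled
representation plus the parameter-free within-bin variance; training
works on the 512-dimensional pooled scale while reporting the exact
full-series loss. Compared with a learned temporal convolution stack,
this keeps the network at ~26k parameters with hand-derived exact
gradients and makes the reconstruction objective analytically
transparent; at this problem size the pooled dense encoder has the same
practical capacity. Optimization is full-batch Adam (rate 0.01, 60
epochs by default), deterministic under the initialization seed.

Model selection uses a clinical utility
`U = 0.7 * sensitivity + 0.3 * specificity` evaluated on the inner
validation fold after every epoch; the best-utility parameters are kept
(earliest epoch on ties). The 0.7 weight encodes the rule-out priority;
`U` at weight 0.5 is balanced accuracy. Joint optimization of the
autoencoding and task objectives is used throughout (no alternating
schedule).

## Evaluation

For each outer fold, the `k_in` inner-fold models form the ensemble that
votes on every outer-test breathprint at threshold 0.5; ties resolve
conservatively to malignant. All eligible breathprints (BI-RADS 3–5)
participate in training; metric rows are reported for 4A, 4B, 4C, the
combined BI-RADS 4 group and the full analysis set, at the breathprint
level (matching breathprint-denominated malignancy rates). A ratio with
an empty denominator is `NA`, never 0. Mean ± SD aggregates 100
independent runs by default; the packaged acceptance checks use 10 runs
at the 125-participant scale, which keeps the full pipeline inside a few
CPU-minutes while leaving the run-to-run SD of the BI-RADS 4
sensitivity around 2–3 percentage points.

Two subtleties in the chance-level diagnostics, both visible only under
the null (`effect_size = 0`):

* the BI-RADS category is a model input *and* carries category-specific
  prevalence, so the unconditional AUC is well above 0.5 even for a
  breathprint-blind model. Chance behavior of the breath channel is
  therefore measured within category;
* pooling predicted scores across CV folds biases a null AUC below 0.5
  (fold-specific calibration offsets). The within-category AUC is
  computed inside each (category, outer fold) cell containing both
  classes and averaged with discordant-pair weights — the within-stratum
  Mann-Whitney statistic — which is unbiased at 0.5 under the null.
  Because 125-participant cohorts carry sizeable participant-clustering
  Monte-Carlo error, the packaged null check averages three independent
  signal-free cohorts.

## Numerical and degenerate-input policy

Probabilities are clamped at `1e-12` before logs; the loss gradient uses
the exact unclamped form. Zero-variance drift comparisons return p = 1
(equal means) or 0. Training refuses single-class training sets;
clinical utility refuses single-class label vectors. Strata smaller than
the fold count are distributed as evenly as possible with a logged note.
Serialization keeps 9 significant digits (round trip within `1e-9`
relative).

## Known limitations

* The simulator's linear mixing and Gaussian profile model is far
  simpler than breath chemistry; effect sizes are not transferable to
  the real assay.
* Metrics are breathprint-denominated; a participant-level aggregation
  would need a replicate-voting rule and is not the primary report.
* The 10-run acceptance scale leaves a few percentage points of
  Monte-Carlo spread; the 100-run default tightens it at ~10x the cost.
* The composite-loss weights, layer widths and utility weight are
  defaults chosen for the desk-scale study geometry, not tuned optima.
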