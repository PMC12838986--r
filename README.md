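# breathstrat

Breath-based risk stratification for suspicious (BI-RADS 4) mammography
findings, end to end and fully synthetic: simulate electronic-nose
breathprints with a plantable malignancy signal, apply device quality
control and cohort exclusion accounting, train a dual-input
autoencoder-classifier, and evaluate it with a nested cross-validation
ensemble that reports per-subgroup sensitivity, specificity, NPV and PPV.

## Who this is for

Researchers prototyping rule-out diagnostics on electronic-nose (eNose)
time-series data: the package provides a tested reference implementation
of the full analysis chain — generator, QC, preprocessing, model,
evaluation — whose statistical structure mirrors a BI-RADS 4 breath
study (176 enrolled → 125 analyzed participants, 437 breathprints, 85
BI-RADS 4 participants with subgroup malignancy rates 6% / 13% / 49%),
without requiring any clinical data.

## The model

A breathprint is a 32-channel chemiresistive time series `R_i(t)` over
three phases (ambient 30 s, capture 5–15 s, recovery 250 s at 1 Hz).
Records are normalized as `v_i(t) = (R_i(t) − R0_i)/R0_i` against the
ambient baseline. The classifier is a semi-supervised autoencoder: two
encoders map the breathprint `d` and the one-hot BI-RADS category `c`
into a shared latent `z`; two decoders reconstruct `d̂` and `ĉ`, and an
MLP head predicts malignancy `ŷ`, trained jointly under

    L = λ_task·L_Task + λ_bp·L_Breathprint + λ_birads·L_BIRADS

where `L_Breathprint` is the reconstruction MSE, `L_BIRADS` the
categorical cross-entropy, and `L_Task` a class-weighted binary
cross-entropy with an extra false-negative penalty (missed cancers cost
more than false alarms). Model selection maximizes the clinical utility
`U = 0.7·sensitivity + 0.3·specificity` on inner validation folds.
Evaluation is nested CV: the inner-fold models of each outer fold vote
on the outer test breathprints by majority, ties resolved conservatively
to malignant; metrics aggregate as mean ± SD over repeated runs.

See `vignette("breathstrat-methods")` for the full account, including
the sorption-kinetics generator and the QC criteria.

## Worked example

Build the reference-margin cohort, run QC and exclusions, and evaluate a
small 2-run pipeline:

```r
library(breathstrat)

cohort <- reference_cohort(seed = 1, effect_size = 2)
excl <- apply_exclusions(cohort, qc_cohort(cohort))
excl$report
#> <qc_report> 176 enrolled; excluded: 15 inconclusive, 13 unreported,
#> 6 ineligible category, 17 all-attempts-failed; 125 analyzed (437 breathprints)
#>         outcome
#> category benign malignant
#>       3       7         0
#>       4A    103         7
#>       4B    124        18
#>       4C     29        28
#>       5       7       114

ev <- evaluate_cohort(excl$analysis_set, model_config(),
                      k_out = 5, k_in = 3, n_runs = 2, seed = 11)
subset(ev$summary, subgroup == "4A+4B+4C",
       c(subgroup, sensitivity_mean, specificity_mean, npv_mean, ppv_mean))
#>   subgroup sensitivity_mean specificity_mean  npv_mean  ppv_mean
#> 4 4A+4B+4C        0.9056604          0.96875 0.9802047 0.8588761
```

The QC report reproduces the enrollment accounting exactly (the margins
are constructed, not estimated); the evaluation rows show that with a
planted 2-SD signal on 4 of 8 VOC channels the ensemble recovers high
sensitivity and NPV in the BI-RADS 4 group. With `effect_size = 0` the
same pipeline sits at chance (within-category AUC ≈ 0.5). A YAML-driven
end-to-end run is available via `run_pipeline()` or the thin wrapper
`inst/cli/breathstrat-pipeline.R`.

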