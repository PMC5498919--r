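# lungpanel

Training and blinded validation of serum-protein classifiers for
indeterminate pulmonary nodules.

Most lung nodules found on imaging are benign, but telling the malignant
minority apart currently costs many unnecessary biopsies. A candidate
adjunct is a serum biomarker panel: a handful of circulating proteins
combined into a single malignancy score. `lungpanel` implements the complete
statistical workflow for building such a panel and measuring, honestly, how
well it survives contact with an independent screening population:

1. **Pre-analytical stability screen** — per-marker relative change of serum
   levels after 4 h / 24 h blood clotting versus a 0.5 h baseline;
   markers whose mean change exceeds 20% are deselected before any model is
   fitted (`relative_change()`, `deselect_markers()`).
2. **Elasticnet panel training** — penalized logistic regression of case
   status with a lasso-dominant penalty (α = 0.95),

   minimize  (1/n) Σᵢ [log(1 + e^ηᵢ) − yᵢηᵢ] + λ(α‖β‖₁ + (1−α)/2 ‖β‖₂²),

   fitted along a decreasing λ path by proximal-Newton coordinate descent in
   C++, with solutions verified against the exact-objective KKT conditions
   (`feature_matrix()`, `fit_path()`). The penalty is selected by
   **stratified bootstrap out-of-bag AUC** (10,000 iterations at study
   scale): resample cases and controls separately, fit the path in-bag,
   score out-of-bag, pick the λ with the greatest mean OOB AUC
   (`select_penalty()`, `final_fit()`). Internal accuracy is estimated by a
   second bootstrap (`bootstrap_validate()`).
3. **Blinded validation** — the frozen model (text file, checksummed) is
   applied unchanged to an independent matched case–control cohort:
   DeLong ROC summaries for the panel and each marker per radiographic
   finding stratum, tumor-stage and histology subgroups, sensitivity at 90%
   specificity, and per-marker train-to-validation AUC attenuation
   (`validate_cohort()`, `delong_summary()`, `delong_paired_test()`,
   `sensitivity_at_specificity()`, `auc_delta_table()`).

A tested synthetic-cohort generator (`generate_cohort()`,
`generate_clotting_series()`) reproduces the study's structure — log-normal
marker levels, 5 informative of 8 trainable markers, 95/186 training
subjects, 1:1 matched validation pairs (119 nodule / 50 mass / 28 other)
with exact stage/histology stratum counts, and attenuated validation effect
sizes — so the whole pipeline runs without restricted clinical data.

## Worked example

The repository is organised as an analysis workflow; the numbered drivers
under `analysis/` run the three stages over synthetic study-sized data and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R   # clotting series + cohorts
Rscript analysis/02_stability_screen.R   # pre-analytical screen
Rscript analysis/03_train_panel.R        # penalty selection + frozen model
Rscript analysis/04_validate_panel.R     # blinded validation report
```

The screen reports (seed 1):

```
    marker mean_rel_change_4h mean_rel_change_24h consistent_4h consistent_24h
       CEA              +5.0%               -3.5%          TRUE          FALSE
 CYFRA21_1              -2.9%               -5.1%         FALSE          FALSE
 ...
       MDK             -28.0%              -47.5%          TRUE           TRUE
deselected (|mean change| > 20%): MDK
```

MDK loses roughly a quarter of its signal by 4 h and half by 24 h of
clotting — unusable across heterogeneous serum-collection protocols — and is
dropped; the remaining 8 markers enter training. Training then prints:

```
<penalty_selection> 2000 bootstrap iterations (0 fully skipped); selected lambda = 0.01659 (mean OOB AUC 0.910) of 100 grid points
<enet_model> lambda = 0.01659, alpha = 0.95, panel of 7 marker(s): CEA, CYFRA21_1, OPN, SCC, TFPI, MMP2, SLPI
apparent training AUC 0.928 [0.897-0.958], p = 6.3e-165
bootstrap-validated AUC 0.910 [0.860-0.955] (2000 iterations)
```

All five informative markers (CEA, CYFRA 21-1, OPN, SCC, TFPI) are in the
panel; the bootstrap estimate sits below the apparent AUC, as an honest
internal validation should. Blinded validation of the frozen model then
shows the expected attenuation — e.g. the nodule-stratum panel AUC falls to
0.699 [0.633–0.766], single markers drop by ≈ 0.13 AUC on average, later
tumor stages separate better than stage IA, and the panel delivers 26.9%
sensitivity at 90% specificity — the pattern that matters when judging
whether such a test can reach clinical utility.

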