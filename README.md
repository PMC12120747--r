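# organovote

Label-free, image-based patient classification from patient-derived
organoid (PDO) morphometrics — and the statistics of why it works on a
uniform organoid platform and fails on a heterogeneous one.

Colorectal-cancer organoids grown in an arrayed embedded-bioprinting
platform ("Eba") are uniform in size and shape within a patient (day-21
area CV ≈ 0.18), while conventional dome cultures ("Std") are not
(CV ≈ 0.71). On the uniform platform, three bright-field morphometric
features per organoid — cross-sectional area (µm²), perimeter (µm) and
circularity 4πA/P² — suffice to classify each organoid as coming from a
High- or Low-CEA patient (serum CEA above/below 2.5 ng/mL) with a random
forest, and a **majority-vote aggregation** of a 49-organoid panel turns
mediocre per-organoid accuracy into a reliable patient-level call. The
mechanism is the Condorcet jury theorem: with per-organoid accuracy *p*
and panel size *n*, the patient call is correct with probability
P[X > n/2], X ~ Binomial(n, p) — ≈98% at p = 0.64, n = 49, but ≈3% at
p = 0.37, where voting amplifies the *errors* of a below-chance
classifier on heterogeneous organoids.

The package implements the full chain, exercised end to end on a
synthetic cohort generator (no external data needed):

| stage | functions |
|---|---|
| synthetic cohorts and images | `generator_config()`, `generate_cohort()`, `calibrate_separation()`, `render_pdo_image()` |
| segmentation and morphometrics | `segment_largest_object()`, `measure_features()`, `extract_features()`, `coefficient_of_variation()`, `pearson_r()` |
| per-organoid classification | `train_classifier()`, `evaluate_classifier()`, `save_model()` |
| patient-level voting | `iqr_filter()`, `majority_vote()`, `predict_patient()`, `predict_cohort()` |
| voting-accuracy theory | `exact_majority_accuracy()`, `mc_majority_accuracy()`, `accuracy_curve()` |
| drug response | `survival_fraction()`, `auc_drc()`, `compare_group_auc()` |
| end-to-end pipeline | `run_reference_experiment()`, `inst/scripts/organovote.R` |

## Worked example

```r
library(organovote)

# exact patient-level accuracy of 49-organoid strict-majority panels
round(100 * exact_majority_accuracy(p = 0.64, n = 49))   # 98
round(100 * exact_majority_accuracy(p = 0.37, n = 49))   # 3

# synthetic day-21 cohorts reproduce the platform dispersion
eba <- generate_cohort(generator_config(platform = "Eba",
                                        pdos_per_patient_per_batch = 2000,
                                        seed = 0))
coefficient_of_variation(eba$area_um2)                   # 0.1799

# the full experiment: 5 training + 7 external patients, both platforms
report <- run_reference_experiment(seed = 0)
print(report)
```

The report prints (seed 0):

```
Reference experiment (seed 0, calibrated accuracy 0.75)
  Eba_training     per-organoid acc High 100.0%  Low 100.0%
  Eba_validation   per-organoid acc High  78.9%  Low  57.1%
  Eba_external     per-organoid acc High  68.7%  Low  60.7%
  Std_training     per-organoid acc High 100.0%  Low 100.0%
  Std_validation   per-organoid acc High  76.9%  Low  29.6%
  Std_external     per-organoid acc High  72.1%  Low  34.2%
  patient-level correct-call fraction:
    Eba  external   1.00
    Std  external   0.43
    Eba  training   1.00
    Std  training   1.00
    Eba  validation 1.00
    Std  validation 0.60
```

Read it bottom-up: per-organoid accuracy on held-out organoids is modest
on the uniform platform (57–79%), yet every patient is called correctly
once 49 votes are aggregated. On the heterogeneous platform the same
absolute class signal is drowned by the 4× larger size dispersion; the
classifier drifts below chance on Low-CEA organoids (30–34%), and voting
then locks in the wrong call for most Low-CEA patients — uniformity of
the platform, not the classifier, decides patient-level success.

The command-line front end mirrors the pipeline one to one:

```sh
Rscript inst/scripts/organovote.R generate --platform Eba --pdos 49 --seed 0 --out cohort --images
Rscript inst/scripts/organovote.R extract  --images cohort/images --pixel-size 2 --out features.csv
Rscript inst/scripts/organovote.R train    --features cohort/features.csv --out model.rds
Rscript inst/scripts/organovote.R predict  --model model.rds --features cohort/features.csv --out calls.csv
Rscript inst/scripts/organovote.R simulate --p 0.64 --n-max 49 --reps 100000 --out curve.csv
Rscript inst/scripts/organovote.R reference --seed 0 --out report/
```

See `vignettes/organovote-methods.Rmd` for the generator's statistical
model (log-normal areas, calibrated class separation, patient random
effects), the sub-pixel perimeter estimator, and the reasoning behind
every tunable default.

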