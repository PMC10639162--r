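# gwobesity

Obesity in a large city is shaped by factors at two levels that demand two
different models. Individual factors — survey answers about body-shape
awareness, weight-control history, blood pressure, diet, income — attach to
people whose BMI is known, so they support supervised classification and
per-factor attribution. Social/environmental factors — green-park area,
land price, transport utilization, health budgets — exist only as
district-level aggregates with no individual label, and their effects
plausibly vary across space. `gwobesity` implements both tracks as one
tested, deterministic pipeline for epidemiologists and urban-health
analysts, together with a synthetic-data generator with retained ground
truth so every methodological claim is checked by recovery.

## What is inside

**Individual track.** BMI = weight/height² with the obesity label at the
25 kg/m² dividing line; listwise exclusion of no-response records; random
oversampling to 1:1 applied *inside* training folds only. Feature screening
by iterative variance-inflation-factor pruning (`VIF_j = 1/(1−R²_j)`,
threshold 30, worst-first) followed by a joint OLS relevance screen at
p ≤ 0.05. Four candidate classifiers (logistic regression, random forest,
xgboost, classical gradient boosting) compared on identical stratified
folds with pooled confusion-table metrics. Per-district factor ranking by
exact tree-path Shapley values (TreeSHAP), computed in double precision by
the package's own C++ recursion so the local-accuracy identity holds to
machine precision.

**District track.** A geographically weighted lasso, written from scratch:
for district *i*,

    y_i = β₀(u_i, v_i) + Σ_k x_ik β_k(u_i, v_i) + ε_i

estimated by minimizing `Σ_j w_ij (y_j − β₀ − x_j'β)² + λ_i Σ_k |β_k|`
per district, where `w_ij` is a Gaussian kernel in the Euclidean distance
between district centroids (bandwidth = median pairwise distance by
default). The solver is cyclic coordinate descent with soft-thresholding;
`λ_i` is selected per district from 30 log-spaced values in [0.001, 0.03]
by leave-one-out weighted prediction error. Solutions are certified by the
KKT conditions and cross-checked against `glmnet` and closed forms in the
tests. Coefficients are reported on the standardized scale (comparable
across factors) and the raw scale, with min/mean/max and POS/NEG counts
across districts.

## Worked example

```r
library(gwobesity)

truth     <- synthetic_truth(seed = 1)           # retained generating truth
districts <- generate_districts(25, seed = 1)
panel     <- generate_district_panel(districts, truth)

fit <- fit_gwlasso(panel)                        # gaussian kernel, LOO-selected lambda
summarize_coefficients(fit)
#>           feature           min          mean          max pos neg
#> 1 green_park_area -0.0693930761 -0.0584866545 -0.049784001   0  25
#> 2      land_price -0.0535083054 -0.0521478615 -0.051089330   0  25
#> 3        bus_rate  0.0662708513  0.0746765409  0.078141499  25   0
#> 4    bicycle_rate -0.0822338275 -0.0774889919 -0.070652901   0  25
#> 5   health_budget  0.0008598789  0.0060346491  0.009623276  25   0
#> 6   bus_rush_rate -0.0034169676 -0.0007465712  0.002198619   5  14
```

The four factors generated with non-zero spatially varying effects come
back with the correct sign in every district (standardized coefficients:
raw effects of ≈ ±0.3–0.6 times a covariate sd of 0.15). The two
true-null factors hover near zero — an order of magnitude below the real
effects, with some districts shrunk exactly to 0 by the L1 penalty, which
is why their `pos + neg` need not reach 25. (At n = 25 a null factor's
local estimates are correlated across districts, so a single panel can
give a null factor one consistent, small sign, as `health_budget` shows;
recovery over repeated seeds is what the tests assert.)

```r
records <- generate_individual_records(2500, truth, districts = districts)
cv <- kfold_cv(records, model_spec("random_forest", trees = 200), k = 10, seed = 1)
cv$pooled
#> accuracy 0.8920 | precision 0.7803 | recall 0.8693 | f1 0.8224

mod <- fit_classifier(model_spec("gradient_boosting"), records, seed = 1)
head(rank_features(compute_shap(mod, records)), 3)
#>   rank              feature mean_abs_shap
#> 1    1 body_shape_awareness     2.4540037
#> 2    2       weight_control     1.1068919
#> 3    3              high_bp     0.7386976
```

The pooled 10-fold accuracy of 0.892 sits just under the generating
model's Bayes accuracy (≈ 0.91), and the Shapley ranking recovers the
generating effect order (3.6, 1.8, 1.2, ...) on the log-odds scale.

The whole pipeline — synthesis, preprocessing, screening, model
comparison, per-district metrics, top-5 Shapley tables, and the
geographically weighted lasso — runs from one configuration:

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
```

writing `metrics.json`, `top5.csv`, `gwlasso_summary.csv`,
`coefficients.geojson` and a run log; identical configurations produce
byte-identical artifacts. A thin CLI over the same functions lives at
`inst/cli/gwobesity.R` (`synth` and `pipeline` subcommands).

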