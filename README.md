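# nucmorph

Quantitative nuclear morphometrics for subtyping primary intestinal
T-cell lymphoma (PITL). The package is written for computational
pathologists and biostatisticians who have segmented nuclear contours
(instance masks or QuPath-style GeoJSON annotations) from high-power
fields (HPFs) and want to turn them into an interpretable, case-level
classification of **MEITL** (monomorphic epitheliotropic intestinal
T-cell lymphoma: uniform small/medium nuclei, CD8+/CD56+) versus
**ITCL-NOS** (pleomorphic medium/large nuclei) — a separation that is
genuinely hard at the microscope.

## What it computes

Per nucleus, seven attributes: axis ratio and orientation of the
second-central-moment equivalent ellipse, equal-area-disk overlap
circularity, 8-bit intensity entropy (bits), shoelace area (µm²),
centroid-distance irregularity on an arc-length-resampled boundary
(µm²), and perimeter (µm). Per HPF, the population is summarised by four
moments of each attribute,

    x_bar,  m2 = (1/n) Σ (x - x̄)²,  g1 = m3 / m2^{3/2},  kurt = m4 / m2²,

giving a frozen 28-feature vector; case profiles are means over the
case's HPFs. Cases are classified by gradient-boosted trees (XGBoost)
with iterative zero-split-weight feature elimination, random-search
tuning, and 3-fold cross-validation stratified at case level, with
borderline cases held out of every fold and scored by the final model.
The statistical layer provides the AUC with DeLong variance and the
paired DeLong test, a per-feature repeated-measures nested ANOVA
(Y_ij = µ + α_type + π_case + ε, F = MS_type / MS_case-within-type), and
detection average precision at an IoU threshold. A synthetic cohort
generator (star-shaped nuclei r(θ) = R(1 + Σ a_k cos(kθ + φ_k)) with
class-conditional size/waviness/elongation/texture laws) emulates the
monomorphic-versus-pleomorphic contrast so the whole pipeline is testable
without clinical images.

## Worked example

```r
library(nucmorph)

cfg   <- cohort_config(preset = "strong", seed = 1)   # 26 + 10 + 4 cases, 10 HPFs each
feats <- simulate_cohort_features(cfg)                # per-HPF 28-feature table
cases <- aggregate_cases(feats$hpf_features, feats$manifest)

fm    <- build_feature_matrix(cases)                  # 36 x 28; 4 borderline held out
model <- tune_and_crossvalidate(fm, seed = 1)
model
#> <subtype_model> 36 cases, 3-fold case-level CV
#>   out-of-fold AUC = 0.9577 (95% CI 0.8855-1.0000)
#>   final feature set: 10 features

head(feature_importance_gain(model), 3)
#> # A tibble: 3 × 5
#>   feature                 gain cover frequency  rank
#>   <chr>                  <dbl> <dbl>     <dbl> <int>
#> 1 perimeter_variance    0.554  0.457     0.431     1
#> 2 irregularity_variance 0.194  0.170     0.144     2
#> 3 area_variance         0.0773 0.115     0.114     3

predict_borderline(model)
#> # A tibble: 4 × 3
#>   case_id probability predicted
#>   <chr>         <dbl> <chr>
#> 1 T37          0.946  ITCL-NOS
#> 2 T38          0.0206 MEITL
#> 3 T39          0.0206 MEITL
#> 4 T40          0.0210 MEITL
```

The out-of-fold AUC is the pooled cross-validated discrimination between
the two subtypes; the gain table says which features carried the split
decisions (here the dispersion features — the quantitative reading of
pleomorphism); borderline probabilities are the ITCL-NOS-side score of
the four cases that never entered training. On real contours, start from
`read_label_mask()` / `read_polygon_annotations()` and
`compute_morphometrics()` instead of the simulator, then follow the same
chain. `feature_anova()` produces the per-feature subtype comparison
table, and `plot_variance_scatter()`, `autoplot()` the standard figures.

(The exact numbers above are from one seeded run of the strong-preset
synthetic cohort; your values depend on the seed.)

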