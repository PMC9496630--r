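# emlscreen

Serum metabolomics screening of endometrial cancer (EC) with an ensemble
machine-learning (EML) voting score, implemented as a tested R pipeline over
GC-MS peak tables.

## The problem and the method

Endometrial cancer is the most common gynecological malignancy in high-income
countries and has no validated screening test; diagnosis relies on invasive
endometrial sampling. Untargeted GC-MS metabolomics of serum offers a
minimally invasive alternative: a blood sample yields a peak table (one sample
per row, one metabolite signal per column, plus an internal-standard peak
used for normalization), and a classifier trained on case-control cohorts
turns that profile into a screening call.

This package implements the full analysis chain:

1. **Batch QC** — GC-MS batches of 25 samples carry four control injections
   (solvent blank, 15-molecule standard mix, pooled sample, duplicate
   injection). A batch is accepted only if the blank has no peaks, every
   standard analyte is within 10% of its expected normalized area, the
   duplicate's top-100 peaks deviate < 15% from the first injection, and the
   pooled injection sits within 5% of the running pooled centroid.
2. **Preprocessing** — features kept only if present in ≥ 80% of samples;
   peak areas normalized to the internal standard, log-transformed, and
   autoscaled (per-feature mean 0, sd 1), with the transform parameters
   fitted on training samples and frozen.
3. **Univariate reporting** — volcano analysis: a metabolite is a hit when
   its EC/CTRL geometric-mean fold change FC > 2 or FC < 0.5 with p < 0.05.
4. **Feature screening and selection** — correlation, stability and
   missing-data filters, then a genetic-algorithm wrapper maximizing
   cross-validated accuracy.
5. **Seven classifiers** — Naive Bayes, ridge logistic regression (GLM),
   linear large-margin (FLM), a small neural network (DL), CART (DT), random
   forest (RF), and PLS-DA (with VIP scores, R²/Q², and a permutation test),
   each tuned by grid search and admitted to the ensemble only with CV
   accuracy > 65% and CV AUC > 0.85 and no overfitting.
6. **The EML score** — each admitted model *m* votes on a sample *x*:

   ```
   vote_m(x) = sign_m(x) · 100 · accuracy_m · confidence_m(x)
   EML(x)    = Σ_m vote_m(x)
   ```

   with `sign = +1` for an EC prediction and `−1` for CTRL, `accuracy` the
   model's cross-validation accuracy, and `confidence ∈ [0, 1]` its
   distance-from-boundary measure (0 on the boundary, 1 at certainty). A
   balanced panel of votes gives exactly 0; a seven-model ensemble is bounded
   by ±700. The decision threshold is chosen by the Youden index
   (J = sensitivity + specificity − 1) on held-out scores, with the AUC and
   its 95% CI computed by DeLong's method, and the call is EC exactly when
   the score exceeds the threshold.

Because the underlying patient sera are not public, the package ships a
synthetic cohort generator (`generate_cohort()`) that emulates the data
structure: log-normal peak areas, an internal standard, batch structure with
the four QC injections, missingness, and a planted 12-metabolite signature —
glycerol, 3-hydroxybutyric acid and stearic acid raised in EC; glycine,
phenyl pyruvic acid, serine, valine, urea, oxyproline, phenylalanine,
glyceraldehyde 3-phosphate and gluconic acid lowered.

## Worked example

```r
library(emlscreen)

cohort <- generate_cohort(cohort_config(n_ctrl = 200, n_ec = 200, seed = 2024))
res <- run_eml_pipeline(cohort, seed = 2024)
print(res$threshold)
print(res$panel)
print(res$summary)
```

prints (abridged):

```
<threshold_result> threshold -276.7 (J = 0.967; S = 1.000, Sp = 0.967); AUC 0.999 (95% CI 0.992-1.000)
<diagnostic_panel> TP=60 FP=2 TN=58 FN=0
  S = 1.00  Sp = 0.97  PLR = 30.00  NLR = 0.00
  PPV = 0.97  NPV = 1.00  A = 0.98
 class  n   mean    sd    min   max error_rate
  CTRL 60 -610.4 193.5 -688.4 555.0    0.03333
    EC 60  635.0 117.3 -200.7 688.5    0.00000
```

All seven base models pass the admission gates on this strongly separated
synthetic cohort; on the held-out 30% the ensemble calls every EC sample
correctly (sensitivity 1.00) at 0.97 specificity, and the per-class score
summary shows the EC scores concentrated high above the Youden cut. The
univariate side of the same cohort (see `analysis/03_univariate_plsda.R`)
recovers exactly the planted 3-raised / 9-lowered metabolite partition.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → batch QC → volcano/PLS-DA → ensemble) and write their
tables under `results/`.

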