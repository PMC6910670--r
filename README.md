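# deltarad

Delta-radiomics analysis for small longitudinal imaging cohorts:
3D radiomic texture extraction, relative-change (delta) features between
imaging time points, two-step Cox + machine-learning feature selection,
and pooled-ROC leave-one-out evaluation of a grid of classifiers.

## The scientific problem

For patients whose tumor is imaged before and after treatment (here:
pre-treatment, one-week and two-month post-treatment T1 and T2-FLAIR MRI
with a shared gross-tumor-volume mask), the question is whether the
*change* of quantitative image texture inside the tumor predicts a
dichotomized survival outcome (overall survival < 12 vs >= 12 months)
better than any single-time-point image does. The package is aimed at
methodologists who want a tested, reproducible implementation of that
workflow at desk scale, together with a synthetic multi-timepoint cohort
generator with a plantable, tunable texture-change signal.

## The method

Per volume and mask, 61 radiomic features are extracted after re-binning
the ROI to 64 grey levels: 22 grey-level co-occurrence (GLCOM), 11
run-length (GLRLM), 13 size-zone (GLSZM), 5 neighbourhood grey-tone
difference (NGLDM), 6 morphological and 4 intensity-histogram features.
Delta features are the relative changes

```
dF1 = (F_post1 - F_pre) / F_pre        dF2 = (F_post2 - F_pre) / F_pre
```

giving five feature categories (F_pre, F_post1, F_post2, dF1, dF2), each
z-scored over the whole dataset. Inside every leave-one-out fold,
features are selected in two steps — a univariate Cox
proportional-hazards screen (likelihood-ratio p < 0.1) followed by one of
three importance rankers (random-forest out-of-bag permutation,
neural-network input ablation, L1-logistic-regression weights) keeping
the top N in 1..3 — and one of seven classifiers (RF, L1-LR, L2-LR,
linear SVM, RBF SVM, 3-layer neural network, naive Bayes) scores the
held-out patient. The n pooled held-out scores are thresholded at every
distinct score and the ROC area is computed by trapezoid (equal to the
tie-corrected Mann-Whitney statistic). Each of the 3 x 7 = 21 model
combinations is repeated 50 iterations; categories are compared by
paired-sample t-tests across the 21 combinations.

## Worked example

Simulate a 12-patient cohort with a planted post-treatment texture
effect, extract features, and evaluate the pre-treatment and one-week
delta categories:

```r
library(deltarad)

cohort <- generate_cohort(cohort_config(effect_size = 2, seed = 42))
feats  <- extract_cohort(cohort$patients)
res <- run_study(feats, cohort$survival,
                 categories = c("F_pre", "dF1"),
                 iterations = 10, base_seed = 42)
print(subset(res$summary, category == "dF1"),
      row.names = FALSE, digits = 3)
```

```
 category selector classifier N mean_auc  sd_auc
      dF1     L1LR       KSVM 1    1.000 0.00000
      dF1     L1LR       L1LR 1    1.000 0.00000
      dF1     L1LR       L2LR 1    1.000 0.00000
      dF1     L1LR       LSVM 1    1.000 0.00000
      dF1     L1LR         NB 1    1.000 0.00000
      dF1     L1LR         NN 3    0.956 0.06703
      dF1     L1LR         RF 1    1.000 0.00000
      dF1       NN       KSVM 3    1.000 0.00000
      dF1       NN       L1LR 2    1.000 0.00000
      dF1       NN       L2LR 3    1.000 0.00000
      dF1       NN       LSVM 3    1.000 0.00000
      dF1       NN         NB 2    1.000 0.00000
      dF1       NN         NN 3    0.944 0.05708
      dF1       NN         RF 3    0.965 0.01180
      dF1       RF       KSVM 3    0.994 0.01171
      dF1       RF       L1LR 3    0.997 0.00878
      dF1       RF       L2LR 3    0.997 0.00878
      dF1       RF       LSVM 3    0.994 0.01171
      dF1       RF         NB 3    0.972 0.04536
      dF1       RF         NN 3    0.919 0.06734
      dF1       RF         RF 3    0.961 0.03514
```

Each row is one selector-classifier combination with the best mean
pooled-LOOCV AUC over N = 1..3 selected features: at this effect size
the planted one-week texture change is recovered almost perfectly by
every combination. The paired comparison against the (label-independent)
pre-treatment category across the 21 combinations:

```r
a <- subset(res$summary, category == "dF1")$mean_auc
b <- subset(res$summary, category == "F_pre")$mean_auc
cat("mean AUC dF1:", round(mean(a), 3), " F_pre:", round(mean(b), 3), "\n")
out <- paired_auc_test(a, b)
cat(sprintf("paired t = %.2f (df = %d), p = %.2g, mean difference = %.3f\n",
            out$t_statistic, out$df, out$p_value, out$mean_difference))
```

```
mean AUC dF1: 0.986  F_pre: 0.527
paired t = 14.84 (df = 20), p = 2.9e-12, mean difference = 0.459
```

The delta category dominates the pre-treatment category across the
21 combinations. A command-line driver covering the same stages
(`simulate`, `extract`, `run`, `report`, `all`) is installed at
`inst/cli/deltarad.R`.

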