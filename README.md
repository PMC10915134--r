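# pbmScore

Multiple myeloma (MM) is a plasma-cell malignancy whose established staging
systems (ISS, R-ISS, R2-ISS) leave much of the variability in patient outcome
unexplained. `pbmScore` implements a single-sample, rank-based **plasma-cell
malignancy (PBM) score** for bulk CD138+ expression profiles, together with
the complete downstream machinery used to evaluate such a score: survival
analysis, staging-system augmentation, disease-stage discrimination,
MGUS→MM progression prediction, immune-microenvironment clustering of paired
whole-bone-marrow profiles, and mutation-burden association. A synthetic
cohort generator with known ground truth makes every stage testable without
access to restricted patient data.

## The score

For a sample with expression vector *x* over a gene universe of size *N*,
genes are ranked by expression (descending, lexicographic tie-break). For a
marker set *S* of size *m*, walk the ranking and track

- *F(i)* — fraction of marker genes among the top *i* ranks,
- *B(i)* — fraction of background genes among the top *i* ranks.

The enrichment statistic is *ES = F(i\*) − B(i\*)* at the position *i\** of
maximal |*F − B*| (earliest on ties), a signed Kolmogorov–Smirnov-type
running-sum in [−1, 1]: +1 when the markers occupy exactly the top ranks,
−1 when they occupy the bottom. *ES* is normalized against the null of
uniformly random marker placements (exhaustive when C(*N*, *m*) ≤ 10 000,
otherwise ≥ 1000 seeded Monte-Carlo draws):

  *z* = (*ES* − mean₀) / sd₀

Healthy plasma cells express their marker program strongly; malignant ones
perturb (predominantly depress) it. The PBM score is therefore the
sign-flipped plasma-signature z-score, **PBM = −z**, so that higher = more
perturbed = more malignant. Being rank-based, it is invariant to any
strictly monotone transform of a sample's expression values. The same
statistic scores any immune cell-type signature, which is how the
whole-bone-marrow immune microenvironment (TIME) is profiled.

## Worked example

```r
library(pbmScore)

sim <- simulateCohort(n = 300, seed = 7)      # expression + clinical + truth
scores <- scoreSignatures(sim$expr, list(PlasmaB = sim$signature),
                          plasmaSignature = "PlasmaB", nPerm = 1000, seed = 7)
scores
#> SignatureScores: 300 samples x 1 signatures
#>   plasma signature: 'PlasmaB' (PBM = -z)
#>   PBM range: [-4.842, -1.470]

pbm <- pbmScores(scores)
grp <- medianSplit(pbm)                       # high = PBM above the median
lr  <- kmLogrank(sim$clinical$os_time, sim$clinical$os_event, grp)
cox <- coxFit(sim$clinical$os_time, sim$clinical$os_event,
              data.frame(pbm_high = as.integer(grp == "high")))
sprintf("log-rank chi-square = %.2f (p = %.4f)", lr$chisq, lr$p_value)
#> "log-rank chi-square = 7.42 (p = 0.0064)"
print(cox$coefficients, digits = 3)
#>   covariate  coef   hr ci_lower ci_upper p_value
#> 1  pbm_high 0.372 1.45     1.11      1.9 0.00674

trendTest(pbm, sim$clinical$stage_label)$p_value
#> 4.21e-56   # PBM rises across Healthy < MGUS < SMM < NDMM < RRMM
```

The high-PBM half of this simulated cohort dies faster (HR 1.45, 95% CI
1.11–1.90), and the score orders the five disease stages — exactly the
behaviour the score is designed to capture, here recovered from data whose
ground truth is known.

Key entry points per analysis: `scoreSignatures()`/`computePBM()` (scoring),
`cvCompareModels()` with `stageISS()`/`stageRISS()`/`stageR2ISS()`
(staging-model augmentation), `stageDiscrimination()` and
`progressionEval()` (ROC analyses), `estimateTIME()` → `filterCellTypes()` →
`zNormalize()` → `clusterTIME()` → `clusterAssociations()` (TIME), and
`computeTMB()`/`mutationPbmAssociation()`/`stratifiedSurvival()`
(mutations). `runPipeline()` orchestrates an end-to-end run from a YAML
config (`inst/scripts/pbm-pipeline.R` is a command-line wrapper). Readers
for the standard formats: `readGMT()`, `readExpression()` (TSV/GCT),
`readClinical()`, `readMAF()`.

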