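---
title: "Methods: the PBM score and its evaluation pipeline"
author: "pbmScore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PBM score and its evaluation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbmScore)
```

## The problem

Multiple myeloma arises from malignant plasma cells, and the spectrum of
plasma-cell dyscrasias is ordered: healthy controls, MGUS, smoldering MM,
newly diagnosed MM, relapsed/refractory MM. Malignant transformation
perturbs — predominantly depresses — the expression of the normal
plasma-cell marker program in CD138+ (plasma-cell-enriched) bone marrow
samples. The PBM score turns that perturbation into a single number per
sample, usable as a continuous prognostic covariate alongside the clinical
staging systems (ISS, R-ISS, R2-ISS) and as a discriminator of disease
stage and MGUS→MM progression.

## The scoring statistic

Within one sample, genes are ranked by expression, descending; ties break
by ascending gene identifier (C locale), so the ranking is a deterministic
function of the data. For a marker set of size $m$ in a universe of $N$
genes, let $F(i)$ be the fraction of marker genes and $B(i)$ the fraction
of background genes among the top $i$ ranks. The enrichment statistic is

$$ES = F(i^*) - B(i^*), \qquad i^* = \arg\max_i |F(i) - B(i)|,$$

the earliest such position on ties. This is a signed Kolmogorov–Smirnov
running-sum statistic in $[-1, 1]$. Internally both $F - B$ and the
maximization are computed on the integer numerator $h_i(N - m) - (i -
h_i)m$ (where $h_i$ counts marker genes in the top $i$), so the maximum
and its tie-break are exact — no floating-point accumulation can flip the
selected position.

**Normalization.** $ES$ depends on $N$ and $m$, so raw values are not
comparable across signatures. The score is the z-statistic of $ES$ against
the null distribution of uniformly random marker placements in a ranking
of the same size. When $\binom{N}{m} \le 10\,000$ every placement is
enumerated; otherwise `n_perm` (default 1000, minimum 100) seeded draws
are used. The null depends only on $(N, m)$ — never on expression values —
so one null serves every sample of a matrix, which is both fast and makes
scores comparable across samples by construction. The null standard
deviation is the population (divide-by-$n$) form; with it, the exhaustive
4-choose-2 case gives the top placement $z = 1/\sqrt{0.5} = \sqrt 2$.

**Orientation.** Healthy plasma cells rank their markers near the top
($ES > 0$); malignancy drags them down. The PBM score is $-z$ of the
plasma signature, so higher = more perturbed = more malignant. The flip is
a config flag (`flipSign`) for users whose signatures are oriented the
other way.

**Weighted variant.** A weight exponent $\alpha \ge 0$ is exposed: for
$\alpha > 0$ the foreground running sum weights each marker gene by
$|x_g - \mathrm{median}(x)|^\alpha$. The default is $\alpha = 0$
(unweighted); the knob exists because expression-magnitude-weighted
variants of running-sum statistics are common, and switching one on must
not change the API. The permutation null is always unweighted; for
$\alpha > 0$ the z-scores remain comparable across samples but are no
longer exactly standard under the null.

**Degenerate inputs.** A signature that misses the universe entirely, or
covers it, is an error (the background is undefined). Markers absent from
the matrix are dropped with a message; scoring requires at least 5
remaining (configurable), relaxed automatically for toy universes.

## Statistical kernel

Group comparisons use Wilcoxon's rank-sum test (exact by enumeration for
$n \le 20$ without ties; otherwise the tie-corrected normal approximation
with continuity correction). The trend across ordered stages is a
Cuzick-type Wilcoxon extension with equally spaced group scores — the
trend test itself is not standard in base R, so it is implemented here,
with an exact permutation mode for $n \le 8$ used as its own oracle.
Fisher's exact test uses the minimum-likelihood two-sided convention.
Multiple testing is Benjamini–Hochberg throughout. Gene–score correlation
defaults to Spearman (the scores are rank-derived; Pearson is exposed),
with constant genes assigned $\rho = 0$, $p = 1$ rather than NA so that
downstream BH vectors stay aligned. Gene-set over-representation is the
one-sided hypergeometric tail against a user-supplied universe; no
ontology databases are shipped or consulted.

## Survival machinery

Kaplan–Meier, log-rank and Cox fits delegate to the `survival` package
(Efron ties by default; Breslow available, and used by the brute-force
partial-likelihood oracle in the tests). Median splits send values equal
to the median to "low" — a deterministic policy that matters for odd
cohort sizes. Harrell's C follows the explicit pair contract: a pair is
usable when the strictly smaller time carries an event; risk ties count
one half; tied times are unusable.

Staging-model comparison mirrors the repeated cross-validation design:
each of `repeats` (default 100) repeats makes a 5-fold split stratified by
event status (so no fold is event-free by construction), fits each
candidate Cox model on the training folds, and records held-out C. Models
are compared by a *paired* Wilcoxon test on the per-fold C values — pairing
was an open choice (pooled comparison was the alternative); per-fold
pairing is more powerful and reflects that both models see identical
folds. The fold assignment is a pure function of the seed, and rows are
canonicalized by name first, so the result is invariant to input order.

Staging rules are encoded from the standard definitions: ISS III at
β2-microglobulin ≥ 5.5 mg/L, ISS I below 3.5 mg/L with albumin ≥ 3.5
g/dL; R-ISS refines with high-risk cytogenetics (del(17p), t(4;14),
t(14;16)) and LDH; R2-ISS is the additive score (ISS II = 1, ISS III =
1.5, del(17p) = 1, high LDH = 1, t(4;14) = 1, 1q gain = 0.5) with groups
Low / Low-Int / Int-High / High. Units are fixed (mg/L, g/dL) and missing
inputs propagate as missing stages.

## ROC analyses

AUC is the tie-corrected Mann–Whitney probability computed from mid-ranks;
the curve is evaluated at every distinct threshold and its trapezoidal
area equals the AUC exactly. The operating cutoff maximizes Youden's
$J = \text{sens} + \text{spec} - 1$ over midpoints between adjacent
distinct scores — the criterion behind published single-cutoff reports is
rarely stated, and Youden is the dominant convention; midpoints guarantee
the cutoff never coincides with an observed score, making $>$ versus
$\ge$ immaterial. Ties in $J$ resolve to the smallest cutoff. Progression
analysis splits at the cutoff (high = score strictly above), tabulates
progression 2×2, and reports the Fisher p plus the high/low rate ratio.
Stage discrimination computes one AUC per ordered stage pair, with the
later stage as the positive class.

## TIME profiling

Whole-bone-marrow profiles are scored with the same signature engine over
the immune cell-type signatures — the package deliberately reuses its own
scoring machinery rather than shipping a regression deconvolution; score
columns are not fractions and must not be read as percentages. The
1%-mean abundance filter therefore applies only when the user supplies an
external fraction-scale matrix (non-negative, row sums ≤ 1 — enforced by
a scale guard); the named exclusions (osteoblast, osteoclast, adipocyte)
apply on any scale. Retained columns are standardized to mean 0, sd 1
(sample sd, idempotent to 1e-12), then clustered by Ward (ward.D2)
agglomeration on Euclidean distances, cut at $k = 5$. The clustering
algorithm was an open choice; Ward is deterministic (no seed sensitivity)
and standard for z-scored profiles. Cluster labels are assigned by
descending size, deliberately outcome-blind; the association report then
identifies which cluster carries the highest PBM and compares the others
against it.

## The synthetic-cohort generator

A latent malignancy level $\lambda \in [0, 1]$ per sample drives every
data modality, so parameter-recovery tests can compare estimates against
known truth:

- **Expression** (`simulateExpression`): 2000 genes × $n$ samples;
  background gene means $\sim N(6, 1.5)$ on the log2 scale with residual
  sd 0.5 — magnitudes typical of log-scale microarray intensities; 50
  marker genes sit +2 above background at $\lambda = 0$ and shift by
  $-\lambda\Delta$ with $\Delta = 2$ (80% of markers) or $+\lambda\Delta$
  (20%), because malignancy *perturbs* rather than uniformly suppresses
  the program. All fractions and magnitudes are configurable.
- **Survival** (`simulateSurvival`): exponential times with rate
  $0.02\,e^{\beta\lambda}$ (median ≈ 35 months at $\lambda = 0$, a
  realistic MM scale), default $\beta = \log 1.72$; independent uniform
  censoring whose upper bound is calibrated by root-finding to the target
  censoring fraction (default 30%).
- **Stages** (`simulateStages`): thresholds 0.1/0.3/0.5/0.7 on $\lambda$
  map to Healthy/MGUS/SMM/NDMM/RRMM.
- **Mutations** (`simulateMutations`): driver carriage
  $\sim \text{Bernoulli}(\text{logit}^{-1}(a_g + b_g\lambda))$ plus a
  passenger count $\sim \text{Poisson}(e^{c + d\lambda})$, so TMB rises
  with malignancy.
- **Whole bone marrow** (`simulateWBM`): cell fractions are Dirichlet
  draws whose log-concentration is tilted by planted cluster patterns and
  by per-cell-type couplings on $\lambda - 1/2$; expression is the
  fraction-weighted mixture of archetype profiles (each over-expressing
  its own markers by +3) plus noise.
- **Progression** (`simulateProgressionCohort`): 358 patients, 39
  progressors; non-progressor scores $N(0,1)$, progressors $N(\delta,1)$
  with $\delta = 1.07$, whose closed-form binormal AUC
  $\Phi(\delta/\sqrt 2) \approx 0.776$ matches the discrimination level
  such a cohort is expected to show.
- `simulateCohort` bundles these and draws ISS *independently* of
  $\lambda$, so the score carries prognostic signal the staging system
  does not — the condition under which adding PBM to ISS should help.

What the generator does **not** emulate: probe-level microarray noise,
batch effects, gene–gene correlation beyond the marker/archetype
structure, informative censoring, competing risks, or real marker gene
identities. Tests passing on these cohorts demonstrate that the
implementation recovers known structure under its stated model — not that
the score is clinically validated on real data.

## Numerical and design choices

- Integer-numerator arithmetic for the running sum (exact maxima and
  tie-breaks); earliest-position tie policy everywhere a running maximum
  is taken.
- Population-sd null normalization (matches the exhaustive worked
  example; the Monte-Carlo/exhaustive switch is at 10 000 placements).
- Duplicate expression rows collapse by per-sample maximum — a common
  microarray convention; the rule is logged and any deterministic
  alternative would serve. Re-reading collapsed output is a no-op.
- Median-split ties to "low"; TMB median split likewise.
- Cox separation is reported (convergence flag, diverged sign), never
  silently truncated.
- Mutation-stratified survival splits PBM at the *global* median, not
  per stratum.
- The nonsynonymous vocabulary is the standard MAF set (missense,
  nonsense, nonstop, frameshifts, in-frame indels, splice site,
  translation start); unknown classes are excluded with a message, or are
  an error in strict mode.
- Problem sizes in the shipped tests and acceptance script — cohorts of
  200–800, 100 × 5-fold CV at $n = 600$, 250-sample WBM simulations with
  300 permutations — were chosen so the full suite completes in a few
  minutes on one CPU while keeping every recovery band comfortably
  powered.

## Known limitations

The permutation null assumes exchangeability of gene labels within a
ranking; strong gene–gene correlation in real data widens the true null,
so absolute z magnitudes should be interpreted within a cohort, not
across platforms. The TIME module's signature scores are monotone in, but
not equal to, cell-type fractions — compositional analyses requiring true
fractions need an external deconvolution. EFS analyses reuse the OS
machinery on `(efs_time, efs_event)`; no competing-risk handling is
attempted. The weighted ($\alpha > 0$) variant shares the unweighted
null, a documented approximation.

## A small end-to-end run

```{r example}
sim <- simulateCohort(n = 150, seed = 7)
sc <- scoreSignatures(sim$expr, list(PlasmaB = sim$signature),
                      plasmaSignature = "PlasmaB", nPerm = 300, seed = 7)
pbm <- pbmScores(sc)
grp <- medianSplit(pbm)
kmLogrank(sim$clinical$os_time, sim$clinical$os_event, grp)$p_value
trendTest(pbm, sim$clinical$stage_label)$p_value
```
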