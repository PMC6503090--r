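---
title: "Umbrella trends in baroreflex-HRV correlations across blood-pressure groups"
author: "barotrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Umbrella trends in baroreflex-HRV correlations across blood-pressure groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific question

The cardiac baroreflex buffers beat-by-beat blood-pressure fluctuations by
adjusting heart period. Its gain can be estimated non-invasively in the
frequency domain as the alpha index (ms/mmHg): the average square root of
the ratio of RR-interval to systolic-pressure spectral power in the LF and
HF bands. Heart-rate-variability (HRV) indices are far cheaper to obtain —
they need only a tachogram — so a clinically important question is how well
they track the baroreflex, and whether that relationship itself depends on
the blood-pressure state of the subject.

`barotrend` implements a complete, robust, fully non-parametric pipeline
for that question. Subjects are classed by clinic systolic arterial
pressure (SAP) into normotensive (Nt, SAP < 130 mmHg), pre-hypertensive
(preHt, 130–139 mmHg) and hypertensive (Ht, ≥ 140 mmHg) groups, and the
correlation between the alpha index and each of 13 autonomic proxies plus
the composite ANSI index is examined for *monotonic* trends (strength
rising or falling from Nt to Ht) and *umbrella* trends (peaking or
bottoming in preHt — concave ∩ or convex ∪ patterns). The working
hypothesis the pipeline is designed to probe is that pre-hypertension is a
transition state in which the coupling between baroreflex gain and
autonomic indices transiently strengthens.

## The synthetic cohort

No subject-level data ship with the package; a generator stands in for a
study population of n = 1154 healthy subjects. The generator reproduces:

* **Stratum structure.** Seven SAP strata with fixed counts — Nt1 [80,100):
  84, Nt2 [100,110): 158, Nt3 [110,120): 282, Nt4 [120,130): 254, preHt
  [130,140): 144, Ht1 [140,160): 167, Ht2 [160,220]: 65 (the last interval
  closed above, all others half-open). Clinic SAP is uniform within the
  stratum interval. Strata are exact: every generated cohort has these
  counts, every seed.
* **Demographic cells.** Gender × age-class × group counts fixed to the
  reference composition (e.g. 204 female Nt subjects aged 17–30; 646
  females in all, 55.98% of the cohort). Age classes are 17–30 / 31–49 /
  50–86 with integer ages uniform within class. Cells are paired with
  strata at random within each group.
* **Age/gender effects.** Additive cell shifts per variable
  (`default_effects()`): vagal indices decline with age, pressures and
  LF-type indices rise, with modest gender offsets and a mild interaction,
  each expressed as a fraction of the variable's SD. Marginal
  locations/scales (`default_scales()`) are documented physiological
  placeholders; every downstream statistic is invariant to them.
* **Correlation structure.** Within each group, standardized scores come
  from a single-factor construction: proxy_i = L_i·α + √(1−L_i²)·ε_i. This
  guarantees corr(α, proxy_i) = L_i exactly and a positive-semidefinite
  joint matrix with corr(proxy_i, proxy_j) = L_i·L_j. Proxy–proxy
  correlations are therefore *not* independently controllable — an accepted
  simplification.
* **Contamination.** By default 1% of subjects have a random subset of
  proxies (never all 13) displaced by 6 SD with random sign — subjects with
  outlying values on several but not all measures, the failure mode that
  motivates Winsorized correlation. A master seed spawns named substreams
  (demographics, factors, contamination) so each component is reproducible
  in isolation.

### Calibrating the ANSI correlation

ANSI is a composite: each of RR Mean, RR TP and ΔRR LFnu is freed of age
and gender effects, percent-ranked (midrank, `100·(rank−0.5)/n`), averaged,
and the average re-ranked to 0–100. Because of the rank steps, the map from
the common component loading L to the population α–ANSI Pearson correlation
has no closed form, and the global re-rank couples the three groups.
`calibrate_ansi_loadings()` therefore inverts the map by Monte Carlo in the
full mixture (population = 200× the design counts, fixed internal seed
20260920, common random numbers so each coordinate objective is smooth and
monotone, `uniroot` per group with two sweeps). The frozen solution for the
default targets 0.5 / 0.618 / 0.444 is L = 0.3308 / 0.4269 / 0.2897; it was
verified at design time to recover the targets within 0.01 over 200
independent cohorts. A consequence: the three component proxies cannot also
match arbitrary individual targets of their own (their loadings are tied to
the ANSI targets); whole-cohort targets for other proxies (e.g. α–RR TP)
are exercised with uniform-across-group calibrations instead.

## Adjustment and ANSI

"Adjusted" variables are residuals from a *saturated* two-way ANOVA (gender
× age-class, main effects + interaction). The saturated model fits each
cell's mean exactly, so residuals are deviations from cell means — no
design matrix or inversion, exact orthogonality to every cell indicator,
and idempotence by construction. Adjustment is refit from scratch inside
every bootstrap replicate.

Numerical conventions: midranks for all ties; percent ranks use
`100·(rank−0.5)/n`, so a fully tied vector maps to exactly 50 and values
stay inside (0, 100). Because components are adjusted *before* ranking,
ANSI is invariant to increasing affine transforms of a component, not to
arbitrary monotone transforms (those reorder residuals).

## Winsorized correlation

`wincorr(x, y, γ)` independently clamps each vector at its tail order
statistics — with g = ⌊γ·n⌋, the g smallest values are replaced by the
(g+1)-th order statistic and the g largest by the (n−g)-th — then applies
the Pearson formula. γ = 0.1 is the default throughout, a compromise
between leaving outliers in (γ = 0.05) and censoring too much in the
smallest group (γ = 0.2). γ = 0 reduces exactly to Pearson. A zero
winsorized variance raises an error rather than returning a silent 0.

## Stratified balanced bootstrap

Replicates preserve the SAP stratum counts exactly (stratification), and
across all B replicates every subject appears exactly B times (balance),
which removes the first-order Monte-Carlo component of the simulation
error. Both properties are achieved simultaneously by a per-stratum
permute-and-slice construction: concatenate B copies of the stratum's
indices, permute the m·B entries once, cut into B blocks of size m. Because
groups are unions of strata, per-replicate group counts are exact too, and
group membership travels with the resampled subjects.

On each replicate the adjustment and ANSI are recomputed from scratch
(including the percentile reference — the closest reading of per-replicate
recomputation), and the γ-Winsorized correlation of adjusted alpha against
the 13 adjusted proxies + ANSI is computed in 4 scopes (overall + 3
groups): a B × 14 × 4 ensemble. Degenerate cells are flagged and excluded
from aggregation, never imputed. The ensemble is summarized by medians
(midpoint convention), which resist anomalous replicates better than
means.

## Inference

* **BCa intervals** (default 95%): bias-correction z₀ from the fraction of
  bootstrap values below the reference point (counts clamped to [1, B−1]),
  acceleration a from the jackknife skewness, endpoints as
  normal-scale-interpolated order statistics of the bootstrap values. The
  reference point is the original-data Winsorized correlation (not the
  bootstrap median — a deliberate choice where either reading is
  defensible). Jackknife values are leave-one-out `wincorr` on the adjusted
  original data; the adjustment is not refit per deletion, which perturbs
  residuals only at O(1/n_cell) and is immaterial at n = 1154. With z₀ =
  a = 0 the interval reduces exactly to the percentile interval.
* **Permutation test of zero correlation**: y is permuted within the scope
  (within-group for group scopes), two-sided p = (1 + #{|T*| ≥ |T|}) /
  (n_perm + 1), so p can never undercut 1/(n_perm+1). Winsorization
  commutes with permutation, so both vectors are winsorized and
  standardized once and each permutation costs one inner product.
* **Hettmansperger–Norton trend test** against four score patterns on
  (Nt, preHt, Ht): increasing (1,2,3), decreasing (3,2,1), concave (1,2,1),
  convex (2,1,2). The statistic is T = Σ cᵢ·R̄ᵢ with scores centered so
  Σ nᵢcᵢ = 0, standardized by its *exact* permutation moments:
  E[T] = R̄·Σcᵢ and Var(T) = σ_R²·N/(N−1)·(Σcᵢ²/nᵢ − (Σcᵢ)²/N). The
  correction terms vanish for equal group sizes — the pipeline's use, where
  the three samples are the within-group bootstrap distributions (n = B
  each, so pseudoranks coincide with plain ranks) — but make the
  standardization exact for unequal sizes as well, which the test suite
  verifies by full enumeration of all small allocations. Applying a rank
  test to B-sized bootstrap distributions makes the effective n enormous;
  p-values are correspondingly extreme and should be read as strong
  pattern support, not literal error rates.
* **Multiple testing**: 0.05 per test, uncorrected, with the number of
  significant overall-scope comparisons reported alongside.

The Jonckheere–Terpstra and Mack–Wolfe tests are deliberately absent: they
lose their distribution-free character under variance heterogeneity, which
within-group bootstrap correlation distributions exhibit.

## Trend classification

Per comparison: the monotonic label is the significant increasing or
decreasing pattern (smaller p wins), with Nt and Ht endpoints described as
`+`, `-` or `~0` from the within-group permutation verdicts; the umbrella
label is ∩ or ∪ when the corresponding test is significant (larger z wins
if both), otherwise "---"; the strongest group is the argmax of |median
WINcorr| with exact ties reported as `tie`, never silently broken. Strength
bands: |r| < 0.2 negligible, 0.2–0.4 weak, 0.4–0.6 medium, ≥ 0.6 strong —
anchored to 0.4 as the medium-strong boundary of clinical interest.

## Problem sizes and runtime choices

The `analysis/` drivers run the full design (n = 1154, B = 5000,
n_perm = 5000; about 90 s on one core). The test suite keeps most
distributional checks on a 72-subject miniature design with the same
three-group structure, B in the low hundreds, and 200-cohort calibration
recovery at full n; these sizes give Monte-Carlo standard errors well
inside the asserted tolerances. Degenerate inputs (constant vectors,
all-tied ranks, empty strata, unseen demographic cells) raise classed
errors rather than producing silent numbers.

## What the synthetic cohort does not show

The generator emulates index-level structure only: no ECG/pressure signal
simulation, no autoregressive spectral estimation, no proxy–proxy
correlation beyond the single-factor product, Gaussian margins before
contamination, uniform SAP within stratum, and an ANSI construction that
approximates the published composite (the original synthesis weights are
not public). Passing tests therefore demonstrate that the *statistical
machinery* — adjustment, robust correlation, balanced resampling, BCa,
permutation and trend testing — behaves as specified under a faithful
population design, not that real cohorts satisfy the generator's
distributional assumptions. Correlations between the alpha index and HRV
proxies, however strong, are observational; no causal reading is
supported.
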