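# barotrend

Robust, fully non-parametric trend analysis of the correlation between the
cardiac baroreflex gain (the frequency-domain **α index**, ms/mmHg) and a
panel of heart-rate-variability / autonomic nervous system proxies, across
systolic-arterial-pressure (SAP) groups: normotensive (**Nt**, SAP < 130
mmHg), pre-hypertensive (**preHt**, 130–139 mmHg) and hypertensive (**Ht**,
SAP ≥ 140 mmHg).

The package is written for biostatisticians and autonomic-physiology
researchers who want to ask: does the coupling between baroreflex gain and
HRV indices change *monotonically* with blood pressure, or does it follow
an *umbrella* pattern — peaking (∩) or bottoming (∪) in the
pre-hypertensive transition state?

## What it computes

For a cohort of subjects with clinic SAP, age, gender, α and 13 ANS proxies
(HR, RR Mean, RR TP, RR LFa, RR HFa, RR LFnu, RR HFnu, RR LF/HF, ΔRR LFnu,
SAP, DAP, SAP Mean, SAP LFa):

1. **Adjustment** — every variable is replaced by its residual from a
   saturated gender × age-class two-way ANOVA (deviation from cell means),
   and the composite **ANSI** index (percent-ranked synthesis of RR Mean,
   RR TP, ΔRR LFnu) is appended.
2. **Robust correlation** — the γ-Winsorized correlation (γ = 0.1): each
   vector is clamped at its ⌊γn⌋ tail order statistics before the Pearson
   formula, resisting subjects with outlying values on some measures.
3. **Stratified balanced bootstrap** — B = 5000 replicates preserving the
   seven SAP stratum counts exactly, with every subject drawn exactly B
   times across the ensemble; adjustment and ANSI are recomputed on every
   replicate, yielding a B × 14 × 4 ensemble of WINcorr values (overall +
   3 groups), summarized by medians.
4. **Inference** — 95% BCa confidence intervals; permutation tests of zero
   correlation, two-sided p = (1 + #{|T\*| ≥ |T|})/(n_perm + 1); the
   Hettmansperger–Norton patterned-trend test T = Σ cᵢ R̄ᵢ (exact
   permutation standardization) against increasing, decreasing, concave
   (1,2,1) and convex (2,1,2) score patterns over (Nt, preHt, Ht).
5. **Synoptic classification** — per comparison: monotonic direction,
   umbrella shape (∩ / ∪ / ---), strongest group by |median WINcorr|, and
   a strength band (|r| ≥ 0.4 = medium-strong).

Because no subject-level data are deposited anywhere, the package includes
a first-class synthetic cohort generator (`generate_cohort()`) reproducing
the reference composition — 1154 subjects, strata 84/158/282/254/144/167/65,
gender × age-class cells with a 55.98% female share — with a per-group
single-factor correlation structure calibrated so the α–ANSI correlation
is 0.5 / 0.618 / 0.444 in Nt / preHt / Ht, and 1% contaminated subjects.

## Worked example

The `analysis/` directory holds the numbered workflow; run it from the
repository root:

```sh
Rscript analysis/01_simulate.R   # cohort -> results/cohort.csv
Rscript analysis/02_adjust.R     # adjusted variables + ANSI
Rscript analysis/03_analyze.R    # B = 5000 bootstrap + inference
Rscript analysis/04_report.R     # figures -> results/figures/
```

Step 2 prints the adjusted within-group α–ANSI correlations of the
simulated cohort (one random realization of the calibrated targets
0.5 / 0.618 / 0.444):

```
Pearson correlation of adjusted alpha with ANSI:
  overall: 0.496
  Nt:    0.516
  preHt: 0.551
  Ht:    0.402
```

Step 3 runs the full bootstrap analysis and classifies the trends:

```
Permutation rejections at 0.05 (overall scope): 14 of 14

alpha-ANSI medians with 95% BCa intervals:
  overall  0.482  [0.438, 0.532]
  Nt       0.506  [0.452, 0.563]
  preHt    0.534  [0.398, 0.640]
  Ht       0.379  [0.260, 0.490]

 comparison  monotonic umbrella strongest   band
         hr increasing   convex     preHt medium
       ansi decreasing  concave     preHt medium
       ...
preHt strongest in 10 of 14 comparisons
```

Read: every α-vs-proxy correlation differs from zero overall; the α–ANSI
correlation follows a concave umbrella — it strengthens in the
pre-hypertensive group (median WINcorr 0.534, the largest of the three) and
weakens in hypertensives — and the pre-hypertensive group carries the
strongest correlation in 10 of the 14 comparisons. The negative α–HR
correlation shows the mirror-image convex pattern.

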