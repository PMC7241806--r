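---
title: "Reference-gene stability: classic algorithms, consensus ranking, and mixed-model ICC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability: classic algorithms, consensus ranking, and mixed-model ICC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative RT-qPCR quantification reports every gene of interest (GOI) as a
ratio to a *normalisation factor* (NF) built from one or more reference
("housekeeping") genes. If the references drift with the experimental
condition, that drift is transferred — inverted — onto every GOI fold
change. Choosing stable references is therefore the step on which the whole
analysis rests, and it has to be re-validated for every tissue, injury
model and treatment design.

refstab covers the full workflow: replicate QC, efficiency-corrected
relative quantification, inter-plate correction, the four classic
stability algorithms, consensus ranking across them, and a mixed-effects
intraclass-correlation (ICC) stability measure for gene *combinations*
that adds confidence intervals, a systematic-effect test, a stopping rule
for the number of genes, and sample-size planning.

## Input model and preprocessing

Input is tidy, one well per row: `sample, group, plate, run, gene,
replicate, cq`. Missing Cq is an explicit `NA`, never a sentinel cycle
number — the mixed-model stage tolerates randomly missing data, and
sentinels would silently poison it.

**Replicate QC** (`aggregate_replicates`) averages technical replicates
(arithmetic mean of Cq = geometric mean of quantities) and flags records
instead of dropping them: `spread_exceeded` when the replicate range is
above `max_spread` (default 1 cycle — the bench rule would be to
re-assay, which software cannot do, so the record is excluded from
stability input by default but kept in the QC report), `above_max_cq`
when the mean exceeds `max_cq` (default 34 cycles, the practical
quantification limit for reference genes), `missing_replicate` below
`min_replicates` (default 2).

**Relative quantification** (`relative_quantity`) converts Cq to relative
quantity with the gene- and plate-specific amplification efficiency
`E ∈ (1, 2]`:

* calibrator mode: `RQ_s = E^(Cq_min − Cq_s)`, so the per-gene maximum is 1;
* nq mode: `RQ_s = N_q / E^(Cq_s)` with the plate's quantification
  threshold `N_q` — an absolute per-plate scale that composes cleanly with
  plate correction, and is therefore preferred when thresholds are
  available.

**Inter-plate factor correction** (`plate_factor_correction`) removes a
multiplicative session effect per gene. On the log scale the factor of a
plate is the deviation of the plate's per-gene geometric mean from the
overall geometric mean, re-centred so the factors' geometric mean across
plates is exactly 1 (tolerance 1e-6). This is the least-squares solution
for a multiplicative plate effect; when plate composition is balanced the
correction also conserves each gene's overall geometric mean exactly
(both properties are asserted in the test suite). With unbalanced plate
loadings the unit-geometric-mean constraint is kept and conservation
holds only approximately — a deliberate choice, since the constraint is
what makes factors comparable across genes.

## The four classic algorithms

All logarithms are base 2: Cq is already a log2-type scale, and
expression ratios are conventionally reported in log2 units.

* **geNorm** (`genorm`): `M_j` is the mean over partners `k` of the SD
  (n−1) of `log2(RQ_j/RQ_k)`. Stepwise elimination removes the arg-max M
  until two genes remain. Pairwise variation `V_n = SD(log2(NF_n/NF_{n+1}))`
  between normalisation factors of the top `n` and `n+1` genes drives the
  "how many genes" heuristic: `V_n < 0.15` means adding gene `n+1` buys
  nothing. The per-gene M reported in summaries is the first-pass
  (all-genes) value, which is what comparison tables conventionally print.
* **NormFinder** (`normfinder`): a variance-decomposition model on
  sample-centred log2 expression; per group, inter-group differences are
  estimated, bias-corrected intra-group variances computed, the
  differences shrunk by an empirical-Bayes factor, and stability is
  `mean_groups(|d̃| + sqrt(Var(d̂)))`. With one group it reduces to the
  square root of the bias-corrected centred variance; the best two-gene
  NF for a single group is scored by the SD of the averaged pair,
  `sqrt(mean(σ²)/2)` — the natural single-group reduction, since the
  multi-group combination formula is undefined there. All intermediate
  quantities are exposed in the result for audit.
* **BestKeeper** (`bestkeeper`): descriptive dispersion on the Cq scale.
  Its "SD (± Cq)" is the *mean absolute deviation* around the arithmetic
  mean (the original tool's convention, not RMS); genes with SD > 1 cycle
  are flagged unreliable. The BestKeeper index is the per-sample geometric
  mean Cq of all candidates, and each gene is scored by Pearson r against
  the index. No automatic outlier removal by default; `drop_outliers`
  removes samples whose index deviates more than 3×MAD from the median.
* **Comparative ΔCq** (`comparative_delta_cq`): mean over all pairs
  containing a gene of the SD of the per-sample Cq difference. On a common
  log2 scale this is algebraically the same mean-pairwise-SD construction
  as geNorm's M, a relationship the test suite checks on random matrices.

Ties in any score are broken by input gene order (stable sort) so results
are deterministic. Missing values are handled pairwise (geNorm, ΔCq,
BestKeeper) or by group omission (NormFinder).

## Consensus ranking

The four algorithms rarely agree exactly. `brute_force_aggregate`
minimises the Spearman footrule objective — the summed absolute rank
displacement of each gene against each list. Because the objective
decomposes over (gene, position) pairs, the global minimiser over all G!
permutations is found exactly as a linear assignment problem (Hungarian
algorithm); full enumeration is retained only as an independent test
oracle. The weighted variant replaces rank positions with each list's
orientation-normalised stability scores (min–max scaled to [0, 1], 0 =
most stable), so that displacing a gene across positions with nearly
equal scores costs almost nothing. The exact weight normalisation used in
published consensus tables is generally not stated, so the unweighted
objective is always reported alongside.

`ce_aggregate` is the stochastic alternative for large panels: a
cross-entropy scheme over a position-probability matrix (defaults: 2000
samples/iteration, 10% elite, 0.7 multiplicative smoothing, stop after 5
stalled iterations), reproducible for a fixed seed. On small panels it
attains the assignment optimum, which the acceptance suite verifies on 50
random 5-gene ensembles.

## Mixed-model ICC stability of gene combinations

The combination-level stability measure treats the genes of a candidate
combination as repeated "raters" of each sample. On `y = log2 RQ` (or
`−Cq` via `lmm_spec(response = "neg_cq")` for efficiency-1 workflows; the
log scale is what makes variance components comparable across genes):

```
y ~ gene + group + gene:group + (1 | sample),   samples nested in groups
```

fitted by REML. The ICC is `ρ = σ²_sample / (σ²_sample + σ²_error)`:
the fraction of residual-level variation attributable to true
between-sample differences once gene, group and interaction effects are
removed. A stable combination tracks its samples tightly (`σ²_error`
small → ρ near 1).

Numerical choices:

* **Balanced complete data** use the closed-form ANOVA solution
  (`σ̂²_e = MS_error`, `σ̂²_s = max(0, (MS_samples − MS_error)/k)`), which
  equals the lme4 REML estimate with the zero boundary — an equality the
  test suite asserts — and the F-based consistency interval: each bound is
  `(F/F_crit − 1)/(F/F_crit + k − 1)` with `F = MS_samples/MS_error` on
  (n−g, (n−g)(k−1)) df, truncated to [0, 1] (truncation is flagged).
* **Unbalanced or missing data** fall back to a numerical REML fit and a
  seeded parametric-bootstrap percentile interval (default 1000
  resamples). On balanced data the two intervals agree within 0.03 at
  n = 50, which is tested.
* **Degenerate fits** (zero sample variance) return ρ = 0 with a flag
  rather than an error.

**Systematic effects.** Reference genes must not respond to treatment.
The ML likelihood-ratio statistic of the full model against
`y ~ gene + (1 | sample)` (df = (g−1)k) is always reported. For its
p-value the package does not use the asymptotic chi-square reference on
balanced data: at realistic sizes (n ≈ 60) that reference is visibly
anti-conservative (simulated type-I error ≈ 0.07 at the 0.05 level),
because the ML variance estimates are biased with gk fixed-effect
parameters. Instead, balanced designs use the exact orthogonal
decomposition — the group main effect has an exact F-test against the
between-sample stratum, the gene:group interaction an exact F-test
against the residual stratum, and the two independent p-values are
Fisher-combined — which is calibrated at any sample size (the test suite
checks uniformity by Kolmogorov–Smirnov on 1000 null replicates at
n = 60). Unbalanced data fall back to the asymptotic chi-square; the
`lrt_method` field records which reference produced the p-value. A
combination with p ≤ 0.05 is *flagged* as unsuitable, never auto-excluded
— a winning combination can legitimately sit near the threshold and the
analyst should see it.

**Combination search** (`search_combinations`) evaluates all combinations
of size 2, then 3, …, up to `max_k` (default 5; exhaustive per size — at
10 candidate genes sizes 2–5 are 957 fits, which is desk-tractable), ranks
by the *lower* 95% confidence limit of the ICC (ties by narrower width,
then input order), and stops when a larger size fails to raise the best
lower bound: using the lower bound rewards combinations whose stability is
both high and precisely estimated. Reliability labels follow the
conventional ICC bands (poor < 0.5 ≤ moderate < 0.75 ≤ good < 0.9 ≤
excellent), combining the band of the lower limit with the band of the
point estimate ("moderate to good").

**Sample-size planning** (`bonett_sample_size`) inverts the expected CI
width of an ICC measured by k raters:

```
n = ceil( 8 z²_{α/2} (1−ρ)² (1+(k−1)ρ)² / (k (k−1) w²) + 1 )
```

with z = 1.959964 for 95%. ρ is rounded to two decimals before evaluation
(the convention of published ICC sample-size calculators; `digits = NULL`
disables): entering 0.86 yields n = 106 for k = 2 and w = 0.1, while the
unrounded 0.858 would yield 108. `sample_size_table` tabulates the grid
k = 2–5, ρ = 0.70–0.90, w ∈ {0.1, 0.2}.

**Variance of a product** (`variance_of_product`) provides the
second-moment identities used to reason about normalised-quantity
uncertainty, in the dependent form
`Cov(X²,Y²) + (Var X + μ²_x)(Var Y + μ²_y) − (Cov(X,Y) − μ_x μ_y)²` and its
independence reduction `Var X Var Y + Var X μ²_y + Var Y μ²_x`; the two
coincide (and match Monte-Carlo) when X and Y are independent.

## GOI normalisation

`nrq` divides a GOI's RQ by the per-sample geometric mean RQ of the
chosen reference combination and propagates relative standard errors in
first-order (delta-method) quadrature on the log scale:
`rSE(NRQ)² = rSE(goi)² + (1/k²) Σ rSE(ref)²`. Replicate-level rSEs come
from the replicate Cq spread via `ln(E)·SD(Cq)`. Downstream group testing
(ANOVA and friends) is deliberately out of scope; NRQ tables export
cleanly.

## The synthetic-data generator

`simulate_dataset` produces replicate-level Cq data with known ground
truth so every stage is testable without laboratory data. The latent
log2 expression of gene g in sample s of group i is

```
x = μ_g + shift_ig + b_s + ε_gs,   b_s ~ N(0, σ²_b),  ε ~ N(0, σ²_{e,g})
```

mapped to the Cq scale by `Cq = baseline_g − x·log(2)/log(E_g) + plate
offset + well noise`. The per-gene efficiency conversion is deliberate:
with E ≠ 2, pipelines that assume perfect doubling diverge from
efficiency-corrected ones, so the simulator exercises that code path
nontrivially. Plate offsets are additive on Cq (multiplicative on
quantity), matching the factor-correction model.

Defaults emulate a multi-group animal-injury design: 7 treatment groups
of 8 samples (56 total), the standard 10-gene rat candidate panel with
per-gene efficiencies in (1.84, 2.0] (values typical of plate-specific
standard curves), baseline Cq between 10.5 (18S, the highly abundant
ribosomal RNA) and 27.5, a shared sample-effect SD of σ_b = 1.2 log2
units, per-gene residual SDs graded 0.45–2.2 so the classic algorithms
have a true ranking to recover, opposite 0.25-cycle offsets on two
plates, triplicate wells with 0.1-cycle noise, and no missingness unless
requested. `truth_icc` returns the closed-form target
`σ²_b / (σ²_b + mean σ²_{e,g})` for any combination.

What the generator does *not* emulate: amplification-curve artefacts,
efficiency estimation error (efficiencies are inputs by design),
non-normal expression noise, structured (non-random) missingness, and
between-run drift. Passing tests on simulated data therefore demonstrate
correctness of the estimators under the stated model, not robustness to
every real-world pathology.

## Problem sizes used in the test suite

The stochastic guarantees are exercised at the sizes the methods are
specified for: ICC parameter recovery and CI coverage on 500 replicates
of n = 200 samples (truth ρ = 0.75); LRT null calibration on 1000
replicates at n = 60 and power on 150 replicates of the default 56-sample
design with a 1-log2-unit shift; cross-entropy/assignment agreement on 50
random 5-gene ensembles. The full suite runs in about two minutes.

## Known limitations

* Continuous systematic covariates are not implemented (categorical
  treatment groups only); the model surface is an extension point.
* The weighted-footrule weight normalisation is a declared dialect;
  different published tools normalise scores differently, which can swap
  closely ranked genes near the top of a consensus while leaving the
  bottom ranks stable.
* BestKeeper p-values are plain Pearson correlation tests; the original
  tool's spreadsheet heuristics (e.g. its outlier handling) are not
  reproduced beyond the optional 3×MAD filter.
* Efficiencies are inputs: the package does not estimate them from
  fluorescence curves.
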