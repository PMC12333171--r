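---
title: "Methods: secretome categorization, clinical scoring and potency readouts for conditioned MSC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secretome categorization, clinical scoring and potency readouts for conditioned MSC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscpotency)
```

This vignette documents the models, rules and numerical choices behind
`mscpotency`, in the spirit of a methods section: what each procedure
assumes, which tunable parameters matter, and what the synthetic-data
validation does and does not demonstrate.

## 1. NPX data model and differential secretion

Proximity-extension-assay (Olink-style) panels report Normalized Protein
eXpression (NPX), a relative log2-scale abundance unit, for hundreds of
proteins per supernatant sample. The `npx_matrix` container holds a
protein × sample matrix plus a design mapping each sample to one of five
conditions: plain culture medium, PBMC alone, resting MSC (rMSC), the
MSC–PBMC coculture, and conditioned MSC replated for three days
(D3-cMSC). Missingness is represented as `NA` and never consumed
numerically.

Two quality filters precede analysis:

- **LOD removal.** A value strictly below its protein's limit of
  detection becomes missing. The boundary is deliberate: values exactly
  at the LOD are retained, making the rule deterministic. Comparisons use
  an absolute tolerance of 1e-9, here and in every threshold test in the
  package.
- **Missingness exclusion.** Proteins missing in strictly more than 50%
  of all samples (jointly, not per condition) are removed, and the
  removed set is reported.

Both filters are idempotent, which the test suite checks.

`differential_secretion()` runs a classical one-way ANOVA per protein
across the condition groups — the study design has unequal group sizes
(2/3/4/4/4 samples), which the classical F test handles; a Welch variant
is available via `welch = TRUE` but is not the default. A protein is
testable when at least two conditions retain at least two non-missing
samples; untestable proteins are reported but excluded from the
Benjamini–Hochberg family, so the adjustment is performed across tested
proteins only (standard practice; the alternative — adjusting across the
pre-filter family — is not what BH assumes). Fully degenerate proteins
(zero variance everywhere) get p = 1 when all means agree and p = 0
otherwise, by convention.

## 2. The six-way secretome categorization

The categorization takes one `ConditionProfile` per protein — its five
per-condition means — and asks which qualitative pattern it shows. The
source material states the patterns ("higher in the coculture", "lower in
D3-cMSC", "positive values were retained after subtraction") but not the
numeric margins, so the margins are free parameters of
`classifier_config()`. The defaults were derived once from the smallest
margins actually observed among the printed members of each category:

| rule | default | smallest printed margin |
|---|---|---|
| consumed (τ_cons) | 0.4 | SRC, 0.46 |
| conditioning (τ_cond) | 0.3 | MSR1, 0.34 |
| inhibited (τ_inh) | 0.2 | SAA4, 0.24 |
| immunomodulatory (τ_imm) | 0.25 | ADA, 0.29 |
| coculture deficit (δ_coc) | 0.25 | C1QTNF1 tolerated at 0.10 |
| constitutive (τ_const, ε) | 0.4, 0.75 | no printed members |

Three structural choices cannot be avoided and are worth stating
explicitly:

- **Consumed is terminal.** Several consumed growth factors (EGF, the
  PDGF subunits, TCN2, STIP1) numerically satisfy the inhibited rule as
  well — their levels fall further after conditioning — yet are reported
  only as consumed. The classifier therefore gives consumed precedence
  and keeps it exclusive.
- **The middle categories are multi-label.** CCL17 is printed both as a
  conditioning and an inhibited protein; single-label semantics cannot
  represent that. Conversely, CCL24, CCL4, CCL3 and GNLY also satisfy the
  inhibited margins numerically but are printed only as conditioning:
  no threshold set reproduces that distinction, so the package reports
  the rule outcome (they receive both labels) rather than guessing a
  curated exception list. The 14 inhibited calls on the packaged table
  are exactly the 10 printed ones plus these 4.
- **The strict `PBMC > Medium` clause** in the conditioning rule encodes
  "more abundant in PBMC supernatants"; it is what keeps ADM — strongly
  coculture-elevated but PBMC-depressed — out of the conditioning set.

Constitutive proteins ("equally present in all MSC-containing
conditions") have no printed members, so the constitutive rule is
validated only against synthetic data, and it is evaluated last, only
when no other label fired — its pattern is otherwise a weaker version of
the immunomodulatory one.

The packaged fixture stores the printed means (two decimals, comma
decimals normalized) exactly as printed. The printed subtraction columns
are retained for QC only: 83 of them differ by 0.01 from subtraction of
the rounded means, implying the source subtracted unrounded values. The
loader flags these; it never "corrects" the means.

`calibrate_thresholds()` exists for re-deriving thresholds on annotated
profiles: an exhaustive grid search maximizing exact label-set agreement,
with ties broken toward larger (more conservative) thresholds.

## 3. The composite clinical score

The humanized NSG-MG model is followed weekly with four instruments,
each mapped to an ordinal sub-score: weight loss versus the sham mean
(0–3), grip-strength loss versus habituation (0–4), inverted-grid hold
time Tr (0–3) and a behavior grade (0, 0.5, 1, 1.5, 2, 3 — the printed
scale skips 2.5 and the package rejects it). The global clinical score is

GCS = weight score + strength score + (behavior score + grid score)/2,

bounded by 0 and 10; death fixes every sub-score at its maximum, hence
GCS = 10. Printed interval labels such as "5–9.99%" are implemented as
half-open intervals (`[5, 10)`), and "Tr = 45 to 59 s" as `[45, 60)` with
exactly 60 s scoring 0 — the only readings without gaps. How dead
animals enter later weeks is not specified in the source; the default
carries the terminal maximum forward, with `death = "drop"` available.

Normalization to each animal's score at the injection week (week 2)
defaults to a ratio — the natural reading of "normalized to" — with a
difference mode available because a zero baseline makes ratios undefined
(the package raises an error suggesting it). `compare_groups()` drops
excluded weeks (the study discarded weeks 3 and 7 after a grip-machine
failure and a shortened first cohort), fits a two-way arm × week linear
model, and reports Tukey-adjusted pairwise arm contrasts within each
week via `emmeans`, plus mean ± SEM summaries.

## 4. Barcode design and debarcoding

Samples are multiplexed by staining each with a unique combination of
k = 3 metal-isotope-tagged antibodies against one surface antigen (CD90),
so m channels accommodate C(m, 3) samples; the study ran 15 samples per
tube. The main text does not state m; the package default is m = 6, the
smallest m with C(m, 3) ≥ 15, and m is a free parameter throughout.
`design_scheme()` assigns the first n k-subsets in lexicographic channel
order, making the code book deterministic.

Debarcoding generalizes the study's Boolean gating into two explicit
methods. The *threshold* method is the faithful analog: channels above a
per-channel cutoff are positive, and an event is assigned only when its
positive set equals a code exactly. The *rank* method mirrors standard
mass-cytometry debarcoding practice: the top-k scheme channels form the
candidate code and the intensity gap between the k-th and (k+1)-th
ranked channels (the separation) must reach `min_separation`; doublets —
two cells in one event, showing more than k bright channels — fail the
gap. Ranking ties break by channel order, and an exact tie across the
k/(k+1) boundary leaves the code ambiguous, so the event is unassigned.
Intensities are consumed on a transformed (arcsinh-like) scale;
transformation of raw counts is the simulator's concern.

One honest caveat, verified by simulation: raising the doublet load
lowers the accuracy of *assigned* events no matter the separation gate,
because a doublet of two same-code cells is indistinguishable from a
perfect singlet. What the gate does guarantee — and what the tests
assert — is that yield falls monotonically with `min_separation`,
singlet-restricted accuracy is preserved, and misassignment stays below
the doublet rate.

## 5. CFSE proliferation readouts

CFSE halves with each division, producing log-spaced generation peaks.
All computation happens in log10 space, one division = log10(2) ≈ 0.301
decades. The source gated proliferation in analysis software without
stating the rule, so the gate here is constructed, not transcribed: the
undivided gate is the density mode of the *non-activated* control minus
`k_sigma` (default 2.5) times the scaled MAD. A control that looks
multimodal (secondary density peaks more than half a division away) is
rejected with an error, as are controls under 100 events. Events exactly
at the gate count as undivided (strict inequality, deterministic).

`count_generations()` smooths the distribution with a kernel density
(bandwidth spacing/8, so adjacent generations at σ ≤ 0.08 stay resolved),
walks down from the undivided peak and accepts each next peak only if its
gap from the previous accepted one lies within spacing × (1 ± 0.2);
off-ladder peaks are rejected with a warning. The inhibition index is
100 × (1 − treated/activated) on the percent-proliferating scale, and the
saxagliptin probe arm is represented as a plain condition tag — no
pharmacokinetics.

## 6. Synthetic data: what it emulates, and what it does not

Every generator is seeded, routes all randomness through that seed, and
returns ground truth sufficient to score its downstream estimator.

**NPX panels** (`simulate_npx_panel`): 609 proteins with the study's
category sizes (7/65/22/10/40, remainder null), uniform baselines on
[1, 8], category-specific condition offsets mirroring the reference
table's margin structure, Gaussian per-sample noise σ = 0.15 (the source
reports replicate counts, not variances; 0.15 log2 units is a plausible
within-condition spread for conditioned-medium panels), and the study's
sample sizes 2/3/4/4/4. At σ = 0 the classifier recovers every planted
category exactly; at the defaults its macro-averaged recall exceeds
0.95. With `margin_scale = 0` the panel is a pure null used to check
ANOVA calibration and BH control.

**Cohorts** (`simulate_cohort`): a latent severity follows the placebo
curve (0.05 → 0.65 over weeks 0–6, 0.25 at the week-2 injection) and is
multiplied by the arm effect (1.0/0.9/0.5) from the week after
injection — applying the multiplier before injection would be cancelled
by baseline normalization. Severity maps to the four instruments
linearly with saturation at the rubric extremes, and the map constants
place each rubric's bin edges at half-step offsets of the severity
scale, so each sub-score is proportional to severity in expectation and
GCS ≈ 11 × severity over the working range. That linearity is what makes
the arm-level normalized-GCS ratio a consistent estimator of the planted
multiplier; `estimate_treatment_effect()` normalizes at arm level
because per-animal baseline ratios are heavy-tailed, and drops
post-death weeks so censoring cannot bias the ratio. Deaths occur with
weekly probability `death_hazard × expected severity` (default 0.05,
acting on the noise-free severity so mortality does not select on
measurement noise), and one humanization failure is expected per
27-mouse cohort (rate 1/27), reproducing the n = 8 placebo group after
filtering.

**Barcoded events** (`simulate_barcoded_events`): code channels
N(6, 0.8), background N(1, 0.8) on the transformed scale, 5% doublets as
channel-wise maxima of two random singlets.

**CFSE** (`simulate_cfse`): a generation ladder with undivided mean 4.0,
peak σ = 0.05, divided events spread uniformly over the generations;
matched non-activated, activated (60% divided) and treated arms whose
default divided fractions (rMSC 0.42, γMSC 0.40, D3-cMSC 0.25) encode
the study's potency ordering — the conditioned supernatant inhibits
most.

What passing these validations shows is that the estimators recover the
structures the generators plant: rule margins on Gaussian means, a
multiplicative severity effect under rubric quantization, k-subset codes
under Gaussian channel noise, log-spaced mixture peaks. Real data differ
in ways the generators deliberately do not model — correlated proteins
and plate effects in NPX panels, non-Gaussian spillover and
signal-intensity drift in mass cytometry, asymmetric and overlapping
CFSE peaks, mice whose severity does not follow a smooth curve — so the
synthetic results bound implementation correctness, not field
performance.

## 7. Problem sizes and determinism

The shipped validation uses desk-scale sizes chosen to exercise every
code path with comfortable statistical resolution: 500-protein null
panels for calibration checks, 10,000-event debarcoding runs against an
independent brute-force oracle, 10,000-event CFSE samples (binomial
error ≈ 0.5 percentage points), and 50-animal-per-arm cohorts for effect
recovery averaged over five replicates (single replicates scatter with
sd ≈ 0.04 around the planted 0.5). All of it is reproducible from fixed
seeds; identical seeds give bit-identical datasets.
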