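---
title: "Methods: diurnal multi-omics rhythmicity and photoacclimation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diurnal multi-omics rhythmicity and photoacclimation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielomics)
```

## The experimental design this package models

`dielomics` analyses multi-omics time courses from synchronized
photosynthetic cell populations acclimated to diurnal light regimes. The
reference design is three light conditions — low (LL, ~50), moderate (ML,
~200, the control) and high (HL, ~1,000 µmol photons m⁻² s⁻¹) — sampled at
five timepoints per diurnal cycle with three independent replicates: 45
samples, 15 cellular states.

Timepoints are labelled relative to the dark-to-light transition under a
12 h light : 12 h dark cycle: `+2`, `+6`, `+10` are hours into the light
phase; `-2` and `-10` are hours *before the next* lights-on, i.e.
Zeitgeber times 22 and 14. All chronology in the package — adjacency for
the 4-h lag rule, phase arithmetic, plotting order — uses ZT hours
(2, 6, 10, 14, 22 within one cycle), never the lexical order of the
labels, because `-10` (early night, ZT14) precedes `-2` (late night,
ZT22).

```{r}
d <- build_design()
head(d)
```

## Rhythm detection: the fixed-period cosinor

Each feature's series $y(t)$ on the analysis scale (log2 abundance) is
regressed on a single cosine of fixed 24-h period,

$$y(t) = M + \beta_c \cos(2\pi t/24) + \beta_s \sin(2\pi t/24) +
\varepsilon,$$

giving the mesor $M$, the amplitude $A=\sqrt{\beta_c^2+\beta_s^2}$ (half
the fitted peak-to-trough range, in log2 units) and the acrophase
$\varphi$, the ZT hour of the fitted maximum. Significance is the F-test
of $\beta_c=\beta_s=0$ with 2 numerator degrees of freedom;
Benjamini–Hochberg q-values are computed within one (layer, condition)
family, and a feature is called rhythmic at $q<0.05$. We fit each feature
separately rather than principal-component scores, because per-feature
acrophases are the quantity every downstream comparison consumes; whether
q-values should instead be pooled globally is configurable
(`fit_all` is called once per condition, so families are per condition by
construction).

Numerical choices worth knowing:

* **Degenerate series.** A constant series gets $A=0$, $p=1$ (defined —
  flat is an answer); fewer than 4 finite observations or fewer than 3
  distinct times makes the 3-parameter design rank-deficient and the
  feature is excluded, with its id reported in the `"excluded"` attribute.
* **Replicates** enter as independent observations at their ZT. Averaging
  before fitting is available (`average_replicates = TRUE`) but narrows
  the residual degrees of freedom from 12 to 2.
* **Double-plotting** (duplicating each observation 24 h later) is
  reproduced for fidelity with common practice but is *off* by default:
  duplication leaves the least-squares point estimates exactly unchanged
  (proved numerically in the test suite) while doubling $n$ and hence
  deflating p-values. Enabling it logs a warning.
* The period is fixed at 24 h; there is no period scan and no
  Lomb–Scargle/JTK alternative, deliberately.

Phase comparisons use the minimal signed difference on the 24-h circle,
mapped to $(-12, 12]$ with the antipodal case fixed at $+12$.
`phase_concordance` restricts to features rhythmic in both conditions and
reports the median difference, the fraction within ±2 h, and a
Fisher–Lee circular correlation. `mrna_protein_lag` maps the protein
acrophase minus the mRNA acrophase to $[0, 24)$ — a protein peaking 20 h
after its transcript is reported as 20, not −4, because translation
follows transcription.

## Differential abundance

**Transcripts** use a deliberately simplified negative-binomial Wald test.
Counts are normalized with median-of-ratios size factors (falling back to
library-size ratios, with a warning, when no gene is nonzero everywhere).
Gene-wise dispersion is estimated by method of moments from the two
within-group variances and moderated by taking the maximum of the
gene-wise estimate and the across-gene median (floored at $10^{-8}$);
without that floor, 3-replicate variance estimates occasionally collapse
and the Wald statistic explodes under the null. There is no dispersion
shrinkage towards a mean-variance trend, no outlier refitting and no
independent filtering: the contract this test honours is the *call*
contract — `up` iff $\log_2 FC > 1$ and BH-adjusted $p < 0.01$, `down`
symmetrically — not numerical equivalence with any particular NB
implementation. The log2 fold change uses an explicit pseudocount
(default 0.5 on normalized means) because fold changes on near-zero means
are otherwise unbounded.

**Proteins** use the outlier-style Z-score procedure appropriate to
compressed-dynamic-range reporter-ion data: per protein, the log2 fold
change of replicate-averaged abundances (test over control, one
distribution per timepoint) is standardised against all proteins'
fold changes, and `|Z| > 2` is called — *gated* by the limit of
quantitation: a protein whose mean abundance in either arm is at or below
the LOQ is `not_evaluable`. The LOQ gate vetoes the final call only; all
finite fold changes remain in the Z distribution (configurable via
`trim_below_loq`), because the gate is a reporting filter, not a
distribution trim. The LOQ itself is a user parameter; the default — the
1st percentile of finite control means — is a pragmatic floor for data
whose true quantitation limit is not recorded, and should be overridden
when the instrument's LOQ is known. Under a Gaussian fold-change null
this procedure calls ~4.6% of proteins by construction (the 2-SD tail
mass); the test suite checks the empirical rate lands in [0.03, 0.06].

## Core light-response classification

A change is **core** to the HL population when it is HL-specific relative
to the ML control: `core_up` = significantly up in HL while unchanged or
down in LL; `core_down` mirror-image. Same-direction changes in both test
populations are attributed to productivity/synchrony differences and are
`not_core`. `not_evaluable` inputs count as `unchanged` unless
`strict = TRUE` drops them — the choice is exposed because undetected-
in-one-arm handling is genuinely open. The gene-level core list is the
union over timepoints and layers, deduplicated by gene with provenance
(`layer:timepoint:direction` tokens), so a gene core at the mRNA level at
one timepoint and at the protein level at another is counted once.

A gene's response is **constitutive** when it is significant in the same
direction at all five timepoints; the denominator is genes significant
anywhere. Responses are counted per gene, not per gene × timepoint event,
with direction consistency required (`direction_free = TRUE` relaxes it).

**mRNA–protein concordance** pairs differential events either
simultaneously or with a protein call at the next sampled timepoint
exactly 4 h later. On the ZT grid the 4-h steps are 22→2, 2→6, 6→10 and
10→14; the 14→22 night gap is 8 h and never matches — no interpolation is
attempted off the sampled grid.

## Clustering, enrichment, and correlation QC

Per-state mean profiles are Z-scored per feature per layer (constant rows
excluded), the mRNA and protein blocks concatenated for genes detected in
both layers, and k-means run with `centers = 16`, `iter.max = 1000` on
the study scale. Because base k-means is initialization-sensitive and the
upstream convention does not pin an initialization, we seed with
k-means++ under a *required* seed and canonicalize cluster labels by the
peak position of each centre, so run-to-run outputs are comparable;
boundary-level agreement with any other tool's clusters is expected only
up to initialization.

Enrichment is the upper-tail hypergeometric test per flat term set
(`P(X ≥ overlap)` via `phyper`), BH-adjusted across terms, significant at
adjusted p < 0.05; the universe defaults to all detected genes and term
sets are intersected with it. No GO-DAG propagation is performed — term
sets are taken as supplied.

PCA removes the `floor(0.10 · n)` lowest-variance features before
decomposition, scaling off by default (inputs are already on comparable
log/z scales). Pairwise Pearson correlations support complete and
pairwise-complete missing-value semantics, with pairs sharing fewer than
3 finite observations reported as `NA`; replicate QC summarizes the
median within-state replicate correlation.

## Photophysiology indices

Closed forms, each validated against hand values and invariance
properties: de-epoxidation state $(0.5A+Z)/(V+A+Z)$ (scale-invariant,
in $[0,1]$, undefined on a zero pool); stacking repeat distance
height/layers, defined only for stacked membranes (≥ 2 layers);
$F_v/F_m = (F_m - F_0)/F_m$; $\mathrm{NPQ} = (F_m - F_m')/F_m'$ with
$F_m' > F_m$ rejected rather than clipped. The 77 K PSI/PSII ratio
normalizes the spectrum to its PSII-region maximum and takes windowed
maxima (680–690 and 705–720 nm) rather than fixed wavelengths, because
instrument calibration shifts peaks; the windows are arguments. After
normalization the PSII maximum is 1, so the ratio equals the normalized
PSI-window peak. The heavier post-hoc battery (Tukey, Games–Howell,
Dunn) is out of scope; `summarize_physio` produces per-state means/SDs
plus an optional plain one-way ANOVA so qualitative orderings can be
asserted.

## The synthetic-data generator

The generator is first-class, tested code: it produces datasets with the
statistical structure the analysis assumes, carrying a ground-truth table
so every stage is testable without any external download. Its defaults
*are* the study conditions:

| parameter | default | why |
|---|---|---|
| design | 3 × 5 × 3 = 45 samples | the reference design |
| `frac_rhythmic` | 0.91 | the rhythmic nuclear-transcript fraction the design emulates |
| `amplitude_log2` | 2 | 16-fold peak-to-trough, typical of strongly rhythmic transcripts |
| phases | uniform on [0, 24) | unbiased recovery tests; a `"bimodal"` dawn/dusk option exists |
| `mesor_log2_mean/sd` | 8 / 1.5 | realistic count depth and spread |
| `nb_dispersion` | 0.05 | one shared dispersion; a stated simplification over gene-wise trends |
| protein lag | uniform [2, 8] h | the translation/turnover delay window |
| `protein_amp_scale_range` | [0.3, 0.7] | compressed reporter-ion dynamic range |
| `protein_noise_sd_log2`, LOQ, dropout | 0.4, 16, 0.05 | detection floor (left-censoring) plus random dropout |
| `effect_size_log2`, `frac_responsive`, `frac_shared`, `frac_constitutive` | 2, 0.10, 0.3, 0.2 | planted photoacclimation responses, HL-specific and shared, transient and constitutive |

Condition effects are additive on log2 (matching how fold changes are
defined); counts are negative-binomial and the FPKM-like layer is a fixed
library-size rescaling. Under the defaults the transcript replicate
correlation exceeds 0.95 (the generator contract; real data of this kind
reaches ≥ 0.98) and the protein correlation ~0.91–0.95. Physiology
tables encode the qualitative orderings the indices must reproduce:
highest HL de-epoxidation early/midday with a +10 drop, fewer and looser
thylakoid stacks in HL at every timepoint, a midday HL Fv/Fm depression
with late-day recovery, HL-dominant NPQ capacity, and daytime state
transitions in the 77 K ratio (LL pinned in State 1). With
`physio_noise_sd = 0` the tables equal their configured means exactly.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: gene-wise dispersion trends, TMT plex batch
structure (the dominant detection covariate in multiplexed proteomics;
omitted here), bimodal phase clustering (off by default), secondary
ultradian components, unequal library sizes, and annotation error. Every
generator output is byte-identical under the same configuration and seed.

## Validation scenarios and problem sizes

The acceptance checks (mirrored in `scripts/acceptance.R`) run at the
study's design scale and finish in well under a minute in total:

* **Type-I error**: 2,000 null genes through the count generator; raw
  p < 0.05 rate within [0.03, 0.07].
* **Phase recovery**: 500 genes simulated with Gaussian log2 noise at an
  amplitude/noise ratio of exactly 3 (the stated condition, which NB
  counts would only approximate); circular MAE ≤ 1 h, and the linear fit
  agrees with an exhaustive 0.1-h acrophase grid search within 0.2 h on
  every gene.
* **Lag recovery**: 350 rhythmic genes, lag pinned at 4 h; end-to-end
  median recovered lag in [3, 5] h.
* **Core-union recovery** is defined as a high-signal scenario: 2,000
  genes with 120 HL-specific and 60 shared planted responses at log2
  effect 2, mesor 10 ± 1, dispersion 0.02. With the generator's default
  mesor spread (8 ± 1.5) the rhythmic troughs of low-mesor genes carry
  too few counts for the two-gate call in one arm, which mimics
  HL-specificity and contaminates the list — a real phenomenon of
  two-population designs worth knowing about, and the reason the
  recovery guarantee is stated for the high-signal regime only.
* **Exactness checks**: protein Z calls against a brute-force oracle on
  1,000 random instances; the core truth table by exhaustive enumeration;
  hypergeometric p against explicit tail sums on all universes ≤ 50;
  k-means recovery of three planted profile groups at ARI 1.0 with
  bit-identical reruns; the physiology closed forms.

## Known limitations

The NB test's normal Wald p-values are approximate at n = 3 per group;
the moderated dispersion keeps the null calibrated but very heavy-tailed
technical artifacts would not be caught without outlier refitting. The
Z-score protein caller conflates biological and technical variance by
design (it is an outlier test, not an inference). The 4-h lag rule is
grid-bound: a true 4-h lag across the 8-h night gap is invisible. The
cosinor assumes a single sinusoidal component; sharp non-sinusoidal waves
lose amplitude and can shift phase. Five timepoints per cycle cannot
distinguish a 24-h rhythm from higher harmonics aliasing onto it.
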