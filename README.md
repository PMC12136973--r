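# dielomics

Analysis pipeline for **diurnal multi-omics time courses of
light-acclimated, synchronized algal cultures** — for researchers asking
how a photosynthetic cell's daily gene-expression program responds to
limiting and excess light. The reference design is three diurnal light
regimes (LL ~50, ML ~200, HL ~1,000 µmol photons m⁻² s⁻¹) × five
timepoints across a 12:12 light–dark cycle × three replicates: 45
samples, 15 cellular states, measured at the transcript (FPKM-like),
protein (TMT reporter-intensity) and physiology levels.

## What it computes

**Rhythm detection.** A fixed-period cosinor per feature,
`y(t) = M + βc·cos(2πt/24) + βs·sin(2πt/24)`, with amplitude
`A = √(βc² + βs²)`, acrophase `φ` = ZT hour of the fitted maximum, an
F-test of `βc = βs = 0`, and BH q-values per (layer, condition); rhythmic
at q < 0.05. Circular phase statistics compare conditions (phase
concordance, Fisher–Lee circular correlation) and layers (mRNA→protein
acrophase lag on [0, 24)).

**Differential abundance.** Transcripts: a simplified negative-binomial
Wald test (median-of-ratios normalization, moment-based moderated
dispersion) honoring the call contract |log₂FC| > 1 and BH p < 0.01.
Proteins: per-timepoint fold-change Z-scores with |Z| > 2 calls gated by a
limit of quantitation.

**Light-response classification.** Core HL-specific responses (changed in
HL, unchanged or opposite in LL), constitutive-response fractions across
all five timepoints, and mRNA–protein concordance allowing a 4-h lag on
the sampled ZT grid.

**Clustering & enrichment.** Merged mRNA+protein z-score profiles
clustered by seeded k-means (k = 16 default, canonical labels),
hypergeometric term enrichment with BH correction, PCA with a
bottom-10 %-variance filter, and replicate/co-expression Pearson
correlation with explicit missing-value semantics.

**Photophysiology.** De-epoxidation state `(0.5·Anthera + Zea)/(Vio +
Anthera + Zea)`, thylakoid stacking repeat distance (height/layers,
stacked membranes only), `Fv/Fm = (Fm − F0)/Fm`, `NPQ = (Fm − Fm′)/Fm′`,
and the 77 K PSI/PSII fluorescence ratio from windowed 684/711 nm peaks.

**Synthetic data with ground truth.** A first-class generator emulates the
full design — rhythmic fractions, protein lags with compressed dynamic
range, planted HL-specific/shared and transient/constitutive responses,
protein detection floors and dropout, and physiology tables with the
expected condition/time orderings — so every stage is testable offline.

## Worked example

```r
library(dielomics)
design <- build_design()                       # 45 samples, 15 states
cfg    <- sim_config(n_genes = 500, seed = 42)
truth  <- generate_truth(cfg)
mrna   <- simulate_mrna(truth, design, cfg)
prot   <- simulate_protein(truth, design, cfg)

fits_ml <- fit_all(log2_transform(mrna$fpkm), condition = "ML", design = design)
sum(fits_ml$rhythmic)
#> [1] 459        # of 500 genes; 455 were planted rhythmic (91%)

fits_hl <- fit_all(log2_transform(mrna$fpkm), condition = "HL", design = design)
phase_concordance(fits_hl, fits_ml)$summary
#>     n median_delta median_abs_delta concordant_fraction circular_r defined
#> 1 455    0.0209208        0.2859282            0.989011  0.9819577    TRUE
```

Phases agree between light regimes (median shift 0.02 h, 99 % within
±2 h): the rhythmic program is resilient to the light regime, exactly as
planted. Proteins lag their transcripts:

```r
fits_p <- fit_all(log2_transform(prot), condition = "ML", design = design)
mrna_protein_lag(fits_ml, fits_p)$summary
#>     n median_lag fraction_2_8
#> 1 440   5.278677    0.8909091
```

The median recovered lag (5.3 h) sits mid-way through the planted 2–8 h
window, and 89 % of lags fall inside it. Differential calls at dawn
against the ML control:

```r
de <- call_mrna_de(nb_wald_test(mrna$counts, test_condition = "HL",
                                timepoint = "+2"))
table(de$call)
#>            up          down     unchanged not_evaluable
#>            11             8           481             0
```

Photophysiology: the HL population's xanthophyll de-epoxidation state is
high early/midday and collapses at night, as configured in the
generator:

```r
ph  <- simulate_physio_tables(design, cfg)
pig <- pigment_indices(ph$pigments)
subset(summarize_physio(pig, "des"), condition == "HL")
#>    condition timepoint_label variable  mean      sd n
#> 1         HL             -10      des 0.134 0.00683 3
#> 4         HL              -2      des 0.086 0.00360 3
#> 7         HL             +10      des 0.211 0.01959 3
#> 10        HL              +2      des 0.520 0.01515 3
#> 13        HL              +6      des 0.556 0.01230 3
```

## Documentation

The methods vignette
(`vignettes/diel-multiomics-methods.Rmd`) describes the models, the
tunable parameters and their defaults, what the generator does and does
not emulate, and the package's numerical choices and limitations.
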