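# coxflow

Soil carboxydovore bacteria — microbes that oxidize trace and atmospheric
carbon monoxide for supplemental energy — are the main biological sink of
atmospheric CO. Their functional marker is *coxL*, the gene for the large
subunit of the aerobic Mo-Cu CO dehydrogenase (CODH), whose seven-residue
active-site signature separates the functional **type I** enzymes
(`AYXCSFR`) from the hypothetical **type II** group (`AYRGAGR`) and a rare
atypical variant (`PYRGAGR`).

`coxflow` implements, as a tested reusable R pipeline, the analytical chain
that links *coxL* community structure to high-affinity CO uptake in soil:

1. **Sequence typing** — six-frame in silico translation and signature
   classification of *coxL* clone libraries
   (`translate_frames()`, `classify_motif()`, `classify_library()`).
2. **Similarity-threshold calibration** — pairwise similarity scores
   *S* = 1 − *D* for paired 16S rRNA / *coxL* genome panels, OLS of
   *S*<sub>coxL</sub> on *S*<sub>16S</sub>, and the species-level *coxL*
   OTU threshold read off the regression at a 16S cutoff, with its 95%
   prediction interval
   (`pairwise_similarity()`, `fit_calibration()`, `derive_threshold()`).
3. **Community analysis** — complete-linkage OTU clustering at a 0.90
   similarity cutoff, rarefaction to a common library size, Shannon
   *H′* = −Σ *p*<sub>i</sub> ln *p*<sub>i</sub> and Simpson
   *D* = Σ *p*<sub>i</sub>², and unweighted UniFrac distances between
   libraries with UPGMA clustering and jackknife node support
   (`cluster_otus()`, `subsample_otu_table()`, `otu_diversity()`,
   `unifrac_distance()`, `upgma_jackknife()`).
4. **Uptake kinetics** — apparent first-order rate constants *k* from the
   logarithmic decrease of flask-headspace CO mixing ratio (≥5 points,
   25 ppbv detection floor), converted to potential uptake rates
   *k·x*<sub>ref</sub>·*n*<sub>air</sub>/*m*<sub>soil</sub>
   (pmol g⁻¹(dw) h⁻¹) and to cell-specific rates (zmol cfu⁻¹ h⁻¹)
   (`fit_decay()`, `uptake_rate()`, `cell_specific_rate()`).
5. **Gene abundance** — qPCR standard curves with efficiency
   *E* = 10^(−1/slope) − 1, absolute quantification to copies g⁻¹(dw), and
   theoretical carboxydovore population bands
   *N* = CO<sub>soil</sub>/CO<sub>bacteria</sub> bracketing the qPCR
   abundances (`fit_standard_curve()`, `quantify_copies()`,
   `theoretical_band()`, `band_consistency()`).
6. **Ordination** — Hellinger transformation, redundancy analysis written
   out from its algebra, permutation tests, Blanchet-style forward
   selection and VIF screening (`hellinger()`, `rda_fit()`,
   `forward_select_rda()`).
7. **Synthetic data** — generators for every input class with a recorded
   ground truth (`simulate_*()`), so each stage has a parameter-recovery
   test surface without any external downloads.

## Worked example

```r
library(coxflow)

## calibrate a species-level coxL OTU threshold on a 41-taxon panel
sim <- simulate_gene_pairs(41, slope = 0.8, intercept = 0.15,
                           noise_sd = 0.02, seed = 7)
cal <- fit_calibration(sim$pairs)
cal
#> coxL ~ 16S similarity calibration (n = 820 pairs)
#>   s_coxl = 0.1634 + 0.7862 * s_16s   (R2 = 0.952, P = 0)
#>   residual SD 0.0058
derive_threshold(cal, x_species = 0.97)
#> Species-level similarity threshold: 0.926 +/- 0.011 (at 16S = 0.97, 95% PI)

## flask kinetics -> soil-normalized potential uptake rate
flask <- simulate_decay_series(0.5, 1, seq(0, 1.75, 0.25), cv = 0.05,
                               seed = 7, soil_dw_g = 50, headspace_l = 0.48)
fit <- fit_decay(flask$curve)
fit
#> First-order CO uptake, flask flask1: k = 0.4951 1/h (R2 = 0.964, n = 8)
uptake_rate(fit, flask$curve)   # 190.6 pmol g-1(dw) h-1

## bracket a qPCR abundance with the theoretical population band
band <- theoretical_band(co_soil = convert_mol(11, "nmol", "pmol"),
                         act_low = convert_mol(29, "zmol", "pmol"),
                         act_high = convert_mol(2171, "zmol", "pmol"))
band
#> Theoretical carboxydovore population: 5.07e+09 to 3.79e+11 cells g-1(dw)
band_consistency(band, 1e10)
#> [1] "within"
```

The 820 pairs are all unordered combinations of a 41-taxon panel; the
threshold 0.926 ± 0.011 is the regression read at the classical 0.97
16S species boundary; 190.6 pmol g⁻¹(dw) h⁻¹ is the potential uptake rate
of a flask whose CO mixing ratio decays at *k* ≈ 0.5 h⁻¹ over 50 g of dry
soil; and 5.1 × 10⁹ – 3.8 × 10¹¹ cells g⁻¹ is the population needed to
explain a forest-soil uptake of 11 nmol g⁻¹ h⁻¹ given isolate-specific
activities of 29–2171 zmol cfu⁻¹ h⁻¹.

## Vignette

`vignettes/coxflow-methods.Rmd` documents the models and their
assumptions, the synthetic-data generators and what they do and do not
emulate, every tunable parameter with its default and rationale, and the
numerical design choices (tie-breaks, tolerances, degenerate inputs).
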