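---
title: "Models and methods behind coxflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coxflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coxflow` links the community structure of soil CO-oxidizing
(carboxydovore) bacteria, profiled through the *coxL* marker gene, to
high-affinity CO uptake activity. This vignette is the package's own
account of the models it implements, the assumptions behind them, the
tunable parameters that matter, and the design decisions taken where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Active-site signature classification

The large subunit of the aerobic Mo-Cu CO dehydrogenase carries a
seven-residue active-site loop whose sequence separates the functional
type I enzymes (`AYXCSFR`, with one variable residue) from the
hypothetical type II group (`AYRGAGR`) and a rare atypical variant
(`PYRGAGR`). `classify_motif()` scans all six reading frames produced by
`translate_frames()` (standard genetic code; ambiguous codons become `X`;
internal stops are retained as `*`).

Decisions:

* **Wildcard width.** The `X` in the type I signature is read as exactly
  one arbitrary residue (`AY.CSFR`), which keeps all three signatures
  seven residues long.
* **Precedence.** If several signatures match (possible in chimeric
  inputs), exact motifs outrank the wildcarded one:
  `AYRGAGR` > `PYRGAGR` > `AY.CSFR`, with a warning.
* **Stop-codon guard.** A match with a stop codon within
  `stop_window = 20` residues is rejected as an out-of-frame artifact.
  The radius is a configurable default, not a biological constant; it
  approximates the screening a clone library would get during manual
  curation of translated inserts.

Classification is invariant to reverse-complementing the input (the six
frames are merely relabelled), which the tests assert for every planted
library, including frame-shifted and reverse-complemented clones.

## 2. Similarity-threshold calibration

Functional-gene OTU cutoffs are arbitrary unless anchored to taxonomy.
The calibration module anchors the *coxL* cutoff to the 16S rRNA species
boundary: for a panel of genomes carrying both genes, all
$\binom{n}{2}$ pairwise similarity scores $S = 1 - D$ are computed per
gene ($D$ = proportion of differing sites, gap/`N` columns removed
pairwise), and *coxL* similarity is regressed on 16S similarity by OLS:

$$S_{coxL} = \beta_0 + \beta_1 S_{16S} + \varepsilon.$$

`derive_threshold()` reads the regression at a 16S species-level cutoff
`x_species` and attaches the standard OLS prediction-interval half-width

$$t_{n-2,\,0.975}\; s \sqrt{1 + \tfrac1n +
  \tfrac{(x^\ast - \bar x)^2}{S_{xx}}},$$

the "±" of the derived threshold.

Decisions:

* **`x_species = 0.97`** by default — the classical 16S species
  boundary. Published panel-specific thresholds depend on the exact
  genome panel and the cutoff chosen, so the package treats the derived
  threshold as a function of both, not as a constant to reproduce.
* **Regression direction** is *coxL* on 16S, because the object of
  inference is a *coxL* threshold at a known 16S cutoff.
* **"±" = 95% prediction half-width**, not the standard error of the
  fitted mean: the threshold is applied to new sequence pairs, so the
  interval must cover a new observation.
* **Pairwise deletion** of gap/ambiguous columns makes the distance
  robust to ragged alignment ends.
* A near-zero slope with a high intercept (seen for type II-like panels)
  pushes the threshold toward 1 with a wide interval — the correct
  reading is that the gene offers no sub-species resolution, and
  `derive_threshold()` flags clamping at the `[0, 1]` boundary.

## 3. OTU clustering, rarefaction, diversity, UniFrac

* `cluster_otus()` uses complete-linkage (furthest-neighbour)
  agglomeration on $1 - S$, cut at $1 - \text{cutoff}$, so every pair
  inside an OTU meets the cutoff. Complete linkage was chosen for
  determinism and because it gives the most conservative OTU membership;
  average linkage is available via `linkage = "average"`. Agglomeration
  ties are resolved by `stats::hclust`'s lowest-index rule; the test
  suite checks equality with a brute-force $O(n^3)$ oracle on panels up
  to 50 sequences, where continuous similarities make ties a
  measure-zero event.
* `subsample_otu_table()` normalizes libraries to the smallest
  sequencing effort by uniform sampling without replacement, with the
  seed recorded on the result. Rarefying deeper libraries biases Shannon
  diversity downward in expectation — that is the point of normalizing —
  so the tests assert determinism and exact library sizes rather than
  any false invariance.
* `otu_diversity()` reports richness, Shannon
  $H' = -\sum p_i \ln p_i$ (natural log) and the Simpson sum
  $D = \sum p_i^2$ together with $1 - D$ and $1/D$, because all three
  Simpson conventions circulate in the soil-ecology literature and each
  is derivable from the same sum. Indices are emitted per sample and,
  when a grouping is supplied, pooled per group: published index tables
  are sometimes computed on pooled libraries, and emitting both makes
  the convention explicit rather than guessed.
* `unifrac_distance()` implements unweighted UniFrac directly from its
  definition — branch length unique to either sample over branch length
  covered by their union — by per-branch enumeration on the rooted input
  tree. The test suite cross-checks against an independent
  implementation (`picante::unifrac`). The unweighted form matches an
  analysis of which lineages are present, not their abundances.
* `upgma_jackknife()` clusters samples by UPGMA on the UniFrac matrix
  and attaches node support as the fraction of jackknife replicates
  (default `keep_frac = 0.75` of all sequences) whose re-clustered tree
  contains the same sample clade. Replicates that empty a sample are
  skipped and counted rather than patched.

## 4. Flask headspace kinetics

Closed-flask CO uptake follows first-order kinetics at trace mixing
ratios, so `fit_decay()` estimates $k$ as minus the OLS slope of
$\ln(\text{CO})$ on time, using only points above the detection floor
(default 25 ppbv, the practical limit of reduced-gas analyzers) and
requiring at least `min_points = 5` usable observations.

`uptake_rate()` converts $k$ to a potential uptake rate
$k \, x_{ref} \, n_{air} / m_{soil}$ in pmol g$^{-1}$(dw) h$^{-1}$, with
$n_{air} = PV/RT$.

Decisions:

* **Reference mixing ratio** defaults to the first uncensored
  observation (flask assays start near 1 ppmv); `"atmospheric"`
  (0.1 ppmv) and `"mean"` are provided because the conversion convention
  is not universal, and the choice is recorded on the result.
* **Headspace volume**: explicit if known; otherwise the nominal bottle
  volume (0.5 L) minus the soil bulk volume at a configurable bulk
  density (default 1.2 g cm$^{-3}$).
* **Temperature/pressure** default to 298.15 K and 101.325 kPa.
* Gross CO production and consumption cannot be separated from a single
  net decay curve when the compensation concentration sits below the
  detection floor; the package deliberately reports *potential* uptake
  rates and nothing more.

`cell_specific_rate()` divides the molar flask rate by the cfu count,
reported in zmol cfu$^{-1}$ h$^{-1}$ (1 zmol = $10^{-21}$ mol), assuming
one viable cell per cfu.

## 5. qPCR quantification and population bands

Standard curves are OLS fits of Cq on $\log_{10}(\text{copies})$;
efficiency uses $E = 10^{-1/\text{slope}} - 1$, so perfect doubling gives
$E = 1$ at slope $-1/\log_{10} 2 \approx -3.32$. Quantification inverts
the curve and scales copies per reaction to copies per gram dry soil
through explicit volume factors
(`dilution * elution_ul / (template_ul * soil_dw_g)`); every factor is an
argument, because per-gram scaling conventions are the least portable
part of any qPCR protocol. Cq values outside the standard range are
flagged as extrapolations.

`theoretical_band()` computes the carboxydovore density needed to explain
a measured soil uptake rate, $N = CO_{soil}/CO_{bacteria}$, evaluated at
the lowest and highest cell-specific rates available from reference
isolates: the *least* active isolate bounds the population from *above*.
All arithmetic runs in mol through an exact unit registry
(`convert_mol()`), since the inputs arrive in nmol, pmol and zmol.
`band_consistency()` classifies an abundance against the closed interval
$[N_{lower}, N_{upper}]$ under the one-copy-per-cell assumption; the
classification is monotone in abundance by construction.

The assay registry `coxl_assays()` ships three degenerate-primer assays
with priming coordinates embedded in the primer names;
`amplicon_length()` returns the coordinate difference and flags
disagreement with the recorded nominal size instead of silently
reconciling (one shipped assay's nominal size differs from its
coordinate difference; both numbers are carried).

## 6. Ordination

`hellinger()` applies $y'_{ij} = \sqrt{y_{ij}/y_{i\cdot}}$, making
Euclidean distances between stations ecologically meaningful and damping
rare-OTU weight. `rda_fit()` implements redundancy analysis from its
algebra: column-center $Y$, standardize $X$ to z-scores, project by
multivariate OLS, eigen-decompose the fitted covariance (constrained
axes) and the residual covariance (unconstrained axes). The constrained
proportion is constrained inertia over total inertia; per-axis fractions
of both total and constrained inertia are reported because "the first two
axes explained x%" is ambiguous between the two denominators.

Decisions and numerical choices:

* **Scaling**: correlation (type 2) triplot scaling by default.
* **Permutation scheme**: free permutation of station rows;
  $p = (1 + \#\{F^\pi \ge F\})/(1 + n_{perm})$. No restricted scheme is
  imposed: with a 3-land-use × 3-station design, block permutations
  would leave too few distinct rearrangements to resolve small p-values.
* **Degenerate responses**: a constant $Y$ gives pseudo-$F$ 0/0, mapped
  to 0, so a fully tied permutation distribution yields $p = 1$ rather
  than `NaN`.
* **Duplicate OTU profiles** (exact column duplicates) are collapsed
  before the analysis with a mapping report — collinear profiles carry
  no independent information and break none-the-wiser interpretations of
  species scores.
* **Forward selection** (`forward_select_rda()`) follows the
  double-stopping rule: a candidate enters only if its partial
  permutation test passes `alpha` *and* the adjusted $R^2$ of the
  augmented model does not exceed that of the full candidate model. The
  ceiling comparison carries a tolerance `ceiling_slack = 0.01`: when
  the remaining candidates are uninformative, both adjusted $R^2$ values
  are unbiased estimates of the same population quantity, and an exact
  comparison degenerates to a coin flip on sampling noise that would
  drop genuinely explanatory variables about half the time. The slack
  keeps the ceiling as an overfitting guard without that pathology.
* **VIF screening** uses the diagonal of the inverted correlation
  matrix, warning above 10.

A practical caveat the tests respect: with 9 stations and 5–7 candidate
variables, the full model keeps only 1–3 residual degrees of freedom and
its adjusted $R^2$ is dominated by the junk-degrees penalty, so the
ceiling prevents any second variable from entering regardless of effect
size. Selection-recovery simulations therefore run at 24–30 stations,
while ordination, permutation and null-calibration checks keep the
9-station survey design.

## 7. Synthetic-data generators

Every generator returns a `sim_truth` record of its planted parameters
and runs on a private RNG stream derived from `(seed, scenario_id)`, so
results are bit-reproducible and adding scenarios never perturbs existing
fixtures. The caller's RNG state is untouched.

* `simulate_gene_pairs()` plants a linear relation between pairwise
  *coxL* and 16S similarities. Each taxon receives a per-gene
  substitution load on a star phylogeny; loads for *coxL* are solved by
  least squares on the additive $\log(1 - \tfrac43 p)$ scale so the
  planted line holds in expectation for raw similarity scores. Because
  i.i.d. per-pair noise cannot be embedded exactly in a metric distance
  matrix realized by sequences, the `noise_sd` target is projected onto
  the per-taxon loads: the realized residual spread is of the requested
  order but not identical to it, which the recovery tests account for by
  checking slope recovery and interval coverage, not residual SD. Sites
  mutate independently with no indels, so alignment-free identity holds.
* `simulate_clone_library()` plants exactly one signature per clone
  (largest-remainder apportionment makes class counts exact), embedded
  in stop-free random coding background screened against accidental
  signature matches, with optional 0/1/2-base frame offsets and random
  reverse-complement orientation.
* `simulate_decay_series()` uses multiplicative Gaussian noise
  (`cv = 0.05` by default) on the exponential decay — gas-analyzer
  reproducibility is relative, typically below 5% — and flags values
  under the detection floor as censored. The multiplicative form is an
  assumption; instrument noise structure is rarely published.
* `simulate_qpcr_run()` draws Cq from the log-linear standard model with
  standards spanning $10^1$–$10^9$ copies.
* `simulate_community_env()` plants two true gradients (water content,
  CO uptake) with OTU-specific loadings plus five nuisance soil
  variables carrying the collinearity structure of temperate soil
  surveys (K, P, pH track water; C, N track CO uptake). At zero noise
  the abundance matrix is an exact linear function of the two gradients,
  so a constrained ordination on them explains all variance — the
  analytic anchor for the RDA tests. The default 9 stations mirror a
  3 × 3 land-use design.

What the generators do *not* emulate — and therefore what passing tests
do not show about real data: PCR/cloning bias and chimeras, sequencing
error, indels and alignment uncertainty, realistic phylogenies (trees
for UniFrac tests are random or hand-built), qPCR plate effects and
inhibition, spatial autocorrelation between stations, and non-linear or
unimodal species responses (for which RDA itself would be the wrong
model).

## 8. Problem sizes and tolerances

The test suite runs panels of 41/61 taxa (820/1830 pairs), 100-replicate
recovery simulations for kinetics ($k = 0.5$ h$^{-1}$, 5% noise, 8
points) and calibration, 200-seed null calibration of the permutation
test at 199 permutations, clone libraries up to 279 sequences, and oracle
comparisons up to 50 sequences (clustering), 20 leaves (UniFrac) and
survey-scale matrices (RDA, $10^{-8}$ on eigenvalues). Noiseless paths
are held to $10^{-10}$; stochastic recovery checks use the generous
bounds that their own sampling distributions dictate (e.g. median
relative error, interval coverage). These sizes were chosen to exercise
every code path at the scale of a realistic soil survey while keeping the
default test run fast.
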