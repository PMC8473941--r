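---
title: "Mass-balance attribution of archaeal ether lipids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-balance attribution of archaeal ether lipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etherbudget)
library(dplyr)
```

## The scientific problem

Archaeal glycerol dialkyl glycerol tetraethers (GDGTs) accumulate in marine
sediments and underpin the TEX~86~ sea-surface-temperature proxy, yet the
archaea known to produce them in culture — Marine Group I (MGI)
Thaumarchaeota — live mostly below the euphotic zone. In stratified
oligotrophic water columns the surface archaeal community is essentially
pure MGII/MGIII Thermoplasmatota, with Thaumarchaeota undetectable, and
still small amounts of intact polar (IP) ether lipids — the form carrying
sugar or phosphate head groups, indicative of living cells — are measurable
there. Deciding whether Thermoplasmatota plausibly produce those lipids, or
whether trace Thaumarchaeota were simply missed, is a quantitative question:
it turns on per-cell lipid quotas, absolute cell densities, and sequencing
detection limits. This package implements that chain of inference as
composable, tested functions.

## The measurement model

### Lipid quantification

LC-MS selected-ion-monitoring peaks are quantified against a spiked C~46~
tetraether internal standard by single-point calibration:

$$c = \frac{A_\mathrm{analyte}}{A_\mathrm{IS}} \cdot RF \cdot
      \frac{m_\mathrm{IS}}{V} \quad [\mathrm{ng/L}]$$

The response factor $RF$ expresses how much weaker an analyte responds than
the standard: 1.5 for crenarchaeol, applied to all GDGTs, and 4.0 for the
diether archeol (`quant_config()`). Three gates apply, all inclusive at
their boundary:

* **signal-to-noise**: peaks with $A/\mathrm{noise} < 5$ are reported as
  zero and flagged `failed_sn`. The flag is distinct from the LOQ flag
  because a near-threshold peak can still be a real compound, and the user
  should be able to see that judgment call.
* **limit of quantification**: 0.00060 ng/L. Concentrations below it keep
  their computed value but are flagged `below_loq` rather than zeroed,
  preserving information for sensitivity analyses.
* **absence**: zero-area peaks are flagged `absent` and counted as zero.

Each extract is measured twice: untreated (core lipids only) and after acid
hydrolysis, which cleaves polar head groups so the hydrolyzed fraction
measures core + intact polar lipids together. The IP pool is obtained by
subtraction per compound, `ip = total - core`. Because the two fractions
pass through different preparations, matrix effects differ between them and
the subtraction can come out negative for individual compounds; negative
values are *retained* per compound (they are informative about measurement
noise) and clamped to zero only when summing to the per-sample IP total, so
`ip_total` is never negative. When several adducts of one compound were
monitored, the maximum-area adduct is used — summing adducts would
double-count ion current and is not standard for SIM quantification.

Head-group-resolved pools (MH/DH/PH/HPH classes) have no authentic
standards, so `ipl_class_distribution()` reports only within-class
peak-area fractions, never ng/L.

The C~46~ response is taken per record rather than averaged across a run:
internal standards are spiked per extract, and per-record normalisation is
what makes the standard internal.

### Absolute abundances

Amplicon read fractions are relative; droplet digital PCR with the same
universal SSU rRNA primers provides the absolute anchor. For each sample,
`absolute_abundance()` distributes the ddPCR total over archaeal groups in
proportion to reads, conserving the total exactly, and converts copies to
cells with a per-cell rRNA gene copy number of 1 — the value in cultivated
marine Thaumarchaeota genomes and the typical state of oligotrophic marine
prokaryotes. The copy number is a parameter (`budget_params()`), so users
working on taxa with multi-copy operons can change it.

The sequencing detection limit is defined as the relative abundance
corresponding to a single read, $100/R$ percent at read depth $R$
(`detection_limit()`). It is deliberately theoretical — a best case; real
detection is worse — which makes the downstream argument conservative in
the right direction: if an inferred population exceeds even the one-read
limit and was not seen, its absence is meaningful.

### The mass balance

With measured IP totals $L$ and cell densities $N_g$:

* `per_cell_quota(L, N)` = $L/N$: the quota a group would need to account
  for the lipids alone. Estimated per sample and summarised as range plus
  arithmetic mean over samples (not a pooled regression — per-sample ratios
  are what the data support, and the mean matches how such values are
  reported in the field).
* `expected_pool(N, Q)` and `attribute_pools()` propagate quotas to
  expected pools per group and normalised source attributions deeper in
  the water column. Groups under 1 % relative abundance are excluded from
  the accounting by default (`min_group_fraction`): their expected pools
  are below every other term's uncertainty.
* `infer_cells(L, Q)` inverts the model, and `detectability()` compares the
  implied relative abundance against the detection limit (inclusive
  boundary, consistent with the SN gate).
* `membrane_fraction(Q)` scales a quota against the ~1.4 × 10⁻⁶ ng of polar
  lipid in a 500-nm cell's membrane, the sanity check that distinguishes
  "plausible membrane component" from "trace contamination or export".

A sample in which *no* compound in the hydrolyzed fraction reached an `ok`
flag behaves as an in-situ blank: it is retained and flagged
(`quantifiable = FALSE`) but excluded from quota summaries. Samples where
measured lipids are zero but cells are present keep their quota of zero —
excluding them would bias quotas upward.

## Multivariate statistics

The community-versus-lipid comparison uses three from-scratch
implementations (vegan serves as an independent cross-check in the test
suite, never as the implementation):

* **Bray-Curtis**, $\sum_i |x_i - y_i| / \sum_i (x_i + y_i)$, computed on
  row-normalised relative abundances so sequencing depth and absolute
  concentration drop out. Bray-Curtis is *not* scale-invariant — this is a
  property test, not an oversight.
* **NMDS** minimising Kruskal stress-1,
  $\sqrt{\sum (d - \hat d)^2 / \sum d^2}$, where $\hat d$ is the
  pool-adjacent-violators isotonic regression of configuration distances on
  input dissimilarities with the primary (weak) tie treatment. The
  optimiser alternates the monotone regression with a Guttman-transform
  update and accepts only stress-decreasing steps, so the stress trajectory
  is non-increasing by construction; if a step would increase stress the
  previous configuration is kept and iteration stops. The first start is
  the classical-scaling configuration, the rest random; 20 restarts by
  default, deterministic under a fixed seed. An all-equal dissimilarity
  matrix is flagged `converged = FALSE` with a warning. Stress below 0.1 is
  conventionally a good embedding.
* **Mantel test**: Pearson correlation of lower triangles with jointly
  permuted labels of the second matrix, one-tailed for positive
  association, $p = (1 + \#\{r_\pi \ge r\})/(1 + n_\mathrm{perm})$. The
  default 999 permutations give a minimum attainable p of 0.001, the
  convention in community ecology. Lipid-side input is the per-sample
  relative composition of hydrolyzed-fraction totals; samples excluded as
  blanks are dropped from both matrices (a zero composition has no
  defined relative abundance).

## The synthetic generator

`generate_dataset(synthetic_config())` emulates the statistical structure
of a stratified oligotrophic depth profile, with every default fixed to the
study conditions it models, not tuned to any test:

| parameter | default | basis |
|---|---|---|
| total copies above DCM | U(2.11 × 10⁶, 6.02 × 10⁶)/L | observed surface range |
| total copies within/below | U(6.0 × 10⁶, 1.22 × 10⁷)/L | observed deep range |
| MGI quota | 1.27 × 10⁻⁶ ng/cell | culture-derived value |
| MGII/III quota | 1.21 × 10⁻⁹ ng/cell | surface mass-balance estimate |
| read depth | U(1,695, 40,915) | observed per-sample range |
| core:IP ratio | 4 above, 0.1 below DCM | observed total-vs-IP pools |
| peak-area noise | lognormal, sdlog 0.10 | typical LC-MS replicate CV |
| matrix effect | extra sdlog 0.15, non-hydrolyzed only | drives negative IP estimates |
| Dirichlet jitter | concentration 200 | mild between-sample composition drift |

MGI composition above the DCM is exactly zero — a structural, not a
sampled, zero. Counts are multinomial at the drawn read depth, so the count
channel carries irreducible sampling noise even when lipid noise is turned
off; the noise-free round-trip identity is therefore asserted on the lipid
channel (recovered IP totals equal truth to floating precision; quotas
against the truth cell densities return the configured value exactly),
while count-channel recovery is checked statistically. The quota-recovery
check uses 600 surface samples: per-sample quota ratios have a standard
deviation near 0.4 (the total-minus-core subtraction amplifies fraction
noise ~5-fold above the DCM, and per-compound clamping adds positive skew,
a genuine property of the subtraction method), so a median over 600 samples
carries ~2 % sampling error against the 10 % recovery band. At these
defaults the estimator's median bias is about +5 %.

What the generator does *not* emulate: chromatographic peak shape and
co-elution, adduct-specific response, chimeras and taxonomic
misassignment, depth autocorrelation beyond the two-cluster split, and
lipid export/advection between depths. Passing tests therefore validate
the inference chain's arithmetic and its statistical calibration under the
stated noise model — not the field accuracy of any real instrument.

## Numerical and design choices

* Boundaries are inclusive everywhere (SN ≥ 5, detectability ≥ limit) so
  tests are deterministic.
* IP subtraction is exact (`ip = total - core` to 1e-12 relative); order of
  peak records never matters.
* TEX~86~ with an all-zero denominator returns `NA` with a warning, never
  0 — a zero would be a valid-looking temperature signal.
* Rarefaction subsamples without replacement, seeded; at full depth it
  equals observed richness exactly.
* All randomness flows through explicit seed arguments (`withr::with_seed`),
  so no call mutates the session RNG state.
* The pipeline result embeds a config and input hash; identical inputs give
  identical output bundles, byte for byte.

Problem sizes in the test suite (6-10 samples for ordinations, 600 samples
for quota recovery, 1,000 replicates for Mantel calibration) were chosen so
each statistical check has adequate power while the whole suite stays
interactive.

## Known limitations

* Single-point internal-standard calibration assumes response linearity
  across the measured range; dilution-series calibration is out of scope.
* Quota estimates inherit the copy-number assumption linearly: if
  Thermoplasmatota carried two rRNA operons per genome, quotas double.
* The Thermoplasmatota quota is estimated where they are the *only*
  candidate source; if an unmeasured group contributed lipids there, quotas
  are overestimates (conservative for the attribution argument).
* NMDS with monotone-descent acceptance can stop at a local minimum;
  restarts mitigate but do not eliminate this, as with any NMDS.

## A complete run

```{r pipeline, eval = FALSE}
ds  <- generate_dataset(synthetic_config(seed = 1))
res <- run_pipeline(ds$peaks, ds$counts, ds$taxonomy, ds$ddpcr, ds$metadata)
glance(res$budget)
autoplot(res$nmds_community,
         colour_by = setNames(ds$metadata$cluster, ds$metadata$sample_id))
autoplot(res$budget)
```
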