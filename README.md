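# etherbudget

Who made the archaeal lipids in the surface ocean? Glycerol dialkyl glycerol
tetraethers (GDGTs) — the membrane lipids behind the TEX<sub>86</sub>
palaeothermometer — are classically attributed to Marine Group I (MGI)
Thaumarchaeota. Yet intact polar (IP) ether lipids, the signature of living
cells, are measurable in oligotrophic surface waters where Thaumarchaeota are
completely absent and MGII/MGIII Thermoplasmatota are the only archaea
present. `etherbudget` implements the quantitative inference chain that turns
this observation into a source-attribution argument, for anyone combining
lipid biomarker measurements with absolute microbial abundance data in ocean
depth profiles.

## The model

Three measured quantities per water sample — the IP ether lipid pool
*L* (ng/L, from LC-MS with internal-standard quantification and
hydrolyzed-minus-non-hydrolyzed subtraction), the absolute abundance *N_g*
of each archaeal group (SSU rRNA copies/L, from ddPCR totals distributed by
amplicon read fractions), and the per-sample read depth *R* — are linked by
a per-cell lipid quota *Q* (ng/cell):

- **quota estimation** in surface samples where group *g* is the only
  candidate source: *Q_g = L / N_g*
- **expected pool** for any group: *E_g = N_g · Q_g*, and attribution
  fractions *E_g / Σ E_g* deeper in the water column
- **abundance inference** for a hypothesised producer: *N* = *L / Q*,
  compared against the sequencing detection limit 100/*R* % (one read) to
  ask whether that population could have been missed by sequencing
- **membrane fraction**: *Q* as a percentage of the ~1.4 × 10⁻⁶ ng of polar
  lipid a 500-nm archaeal cell membrane would contain.

Around this core the package provides the supporting statistics the analysis
needs: Shannon diversity, Monte-Carlo rarefaction, Bray-Curtis
dissimilarities, two-dimensional non-metric multidimensional scaling (NMDS)
with Kruskal stress-1 (pool-adjacent-violators isotonic regression, Guttman
updates, multiple restarts), and the one-tailed permutation Mantel test —
the latter three implemented from scratch and cross-checked against vegan in
the test suite. A synthetic depth-profile generator with known ground truth
(two depth clusters split at the deep chlorophyll maximum, structurally
absent Thaumarchaeota above it, matrix-effect noise that produces the
occasional negative IP estimate) makes the whole chain testable end to end.

All user-facing functions are data-frame first and return tibbles; fitted
objects (`nmds_fit`, `mantel_test`, `lipid_budget`) support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(etherbudget)

ds  <- generate_dataset(synthetic_config(seed = 1))
res <- run_pipeline(ds$peaks, ds$counts, ds$taxonomy, ds$ddpcr, ds$metadata)
res
#> etherbudget pipeline result
#>   18 samples, 18 lipid-quantifiable
#>   NMDS stress: community 0.000, lipids 0.000
#>   Mantel: r = 0.963, p = 0.001
#> Lipid mass-balance budget
#>   18 samples (10 surface, 8 within/below DCM)
#>   Thermoplasmatota quota: 7.24e-10-2.18e-09 ng/cell (mean 1.48e-09)
#>   Max Thermoplasmatota attribution within/below DCM: 0.189%
```

Reading these numbers: community and lipid composition cluster the same way
(Mantel r = 0.963 at the minimum p for 999 permutations), the per-cell quota
that surface Thermoplasmatota would need to explain the measured IP lipids
is of order 10⁻⁹ ng/cell — three orders of magnitude below the ~1.27 × 10⁻⁶
ng/cell measured for cultivated Thaumarchaeota — and at realistic deep-water
abundances Thermoplasmatota could account for under 0.2 % of the IP lipid
pool there. The per-sample detectability verdict asks the converse question:

```r
dplyr::filter(tidy(res$budget), surface)[1:3, c(1, 4, 7, 10, 11, 12)]
#>   sample_id ip_total_ng_L quota_thermo inferred_thaum_percent detection_limit_percent detectable
#> 1   S1_005m       0.00225     7.24e-10                 0.0564                 0.00372       TRUE
#> 2   S1_025m       0.00477     1.85e-09                 0.1428                 0.00436       TRUE
#> 3   S1_045m       0.00691     1.21e-09                 0.0941                 0.00651       TRUE
```

If hidden Thaumarchaeota had produced the surface lipids at their cultured
quota, their implied abundance (0.06–0.17 % of archaeal rRNA here) would sit
well above the one-read sequencing detection limit — they would have been
seen. Their absence is therefore informative, not a sequencing artefact.

`vignettes/lipid-mass-balance.Rmd` walks through the model, its
assumptions, every tunable parameter, and what the synthetic generator does
and does not emulate.

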