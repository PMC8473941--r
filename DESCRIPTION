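Package: etherbudget
Title: Mass-Balance Attribution of Archaeal Ether Lipids in Ocean Depth Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative inference chain linking archaeal membrane ether
    lipids (GDGTs and archeol) to the planktonic archaeal groups that could
    have produced them. Converts LC-MS selected-ion-monitoring peak tables
    into core and intact-polar lipid concentrations via internal-standard
    quantification with compound response factors, signal-to-noise and
    limit-of-quantification rules, and hydrolyzed-minus-non-hydrolyzed
    subtraction; anchors amplicon relative abundances to absolute SSU rRNA
    copy concentrations with droplet digital PCR totals; derives per-cell
    lipid quotas, expected lipid pools per taxon, source-attribution
    fractions, inferred abundances of hypothesised producers, and sequencing
    detection-limit verdicts; and provides from-scratch Bray-Curtis
    distances, non-metric multidimensional scaling with Kruskal stress-1,
    and the permutation Mantel test, plus a synthetic depth-profile data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
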