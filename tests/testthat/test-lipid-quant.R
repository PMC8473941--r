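# Internal-standard quantification, IP subtraction and lipid indices.

test_that("signal_to_noise divides area by noise and rejects bad noise", {
  expect_equal(signal_to_noise(10, 2), 5)
  expect_equal(signal_to_noise(0, 1), 0)
  # the default threshold boundary is inclusive
  expect_gte(signal_to_noise(7.5, 1.5), quant_config()$sn_threshold)
  expect_error(signal_to_noise(10, 0), "invalid noise")
  expect_error(signal_to_noise(10, -1), "invalid noise")
  expect_error(signal_to_noise(-1, 1), "non-negative")
})

test_that("quantify_core applies the internal-standard formula and RFs", {
  # conc = (A/A_is) * RF * m_is / V, hand arithmetic
  cren <- quantify_core(2.0, 0.1, 1.0, 5, 20, "crenarchaeol")
  expect_equal(cren$conc_ng_L, 0.75)
  expect_equal(cren$flag, "ok")
  arch <- quantify_core(1.0, 0.1, 1.0, 4, 20, "archeol")
  expect_equal(arch$conc_ng_L, 0.8)
  # all GDGTs share the crenarchaeol response factor
  for (cmp in gdgt_compounds) {
    expect_equal(
      quantify_core(2.0, 0.1, 1.0, 5, 20, cmp)$conc_ng_L, 0.75,
      info = cmp
    )
  }
})

test_that("quantify_core flags absent, failed-SN and below-LOQ peaks", {
  expect_equal(
    quantify_core(0, 1, 1, 5, 20, "GDGT-0"),
    tibble::tibble(conc_ng_L = 0, flag = "absent")
  )
  # SN below threshold: reported as zero, flagged distinctly from LOQ
  failed <- quantify_core(4.9, 1, 1, 5, 20, "GDGT-0")
  expect_equal(failed$flag, "failed_sn")
  expect_equal(failed$conc_ng_L, 0)
  # below LOQ: value retained, not zeroed
  cfg <- quant_config()
  small_area <- cfg$loq_ng_per_L / 2 * 20 / (1.5 * 5)
  loq <- quantify_core(small_area, small_area / 100, 1, 5, 20, "GDGT-1")
  expect_equal(loq$flag, "below_loq")
  expect_equal(loq$conc_ng_L, cfg$loq_ng_per_L / 2)
  # an exact-threshold SN passes (inclusive boundary)
  at <- quantify_core(5, 1, 1, 5, 20, "GDGT-0")
  expect_false(at$flag == "failed_sn")
})

test_that("quantify_core rejects unknown compounds and the C46 standard", {
  expect_error(quantify_core(1, 1, 1, 5, 20, "GDGT-9"), "unknown compound")
  expect_error(quantify_core(1, 1, 1, 5, 20, "C46-standard"), "C46")
  expect_error(quantify_core(1, 1, 0, 5, 20, "GDGT-0"), "positive")
})

test_that("quantify_core is linear in area and inversely proportional to volume", {
  a <- runif(20, 1, 100)
  base <- quantify_core(a, 1e-9, 1, 5, 20, rep("GDGT-2", 20))$conc_ng_L
  doubled <- quantify_core(2 * a, 1e-9, 1, 5, 20, rep("GDGT-2", 20))$conc_ng_L
  halfvol <- quantify_core(a, 1e-9, 1, 5, 10, rep("GDGT-2", 20))$conc_ng_L
  expect_equal(doubled, 2 * base)
  expect_equal(halfvol, 2 * base)
})

test_that("IP concentration is total minus core, negatives retained per compound", {
  peaks <- dplyr::bind_rows(
    peaks_for_conc("S1", "hydrolyzed", c(crenarchaeol = 0.015)),
    peaks_for_conc("S1", "non_hydrolyzed", c(crenarchaeol = 0.005))
  )
  prof <- quantify_lipids(peaks)
  cren <- prof[prof$compound == "crenarchaeol", ]
  expect_equal(cren$ip_ng_L, 0.010)
  expect_equal(ip_totals(prof)$ip_total_ng_L, 0.010)
})

test_that("negative IP values are kept per compound but clamped in the total", {
  peaks <- dplyr::bind_rows(
    peaks_for_conc("S1", "hydrolyzed", c(crenarchaeol = 0.003)),
    peaks_for_conc("S1", "non_hydrolyzed", c(crenarchaeol = 0.005))
  )
  prof <- quantify_lipids(peaks)
  expect_equal(prof$ip_ng_L[prof$compound == "crenarchaeol"], -0.002)
  expect_equal(ip_totals(prof)$ip_total_ng_L, 0)
})

test_that("identical fractions give zero IP everywhere", {
  conc <- setNames(runif(7, 0.01, 1), ether_compounds)
  peaks <- dplyr::bind_rows(
    peaks_for_conc("S1", "hydrolyzed", as.list(conc)),
    peaks_for_conc("S1", "non_hydrolyzed", as.list(conc))
  )
  prof <- quantify_lipids(peaks)
  expect_equal(prof$ip_ng_L, rep(0, 7))
  expect_equal(ip_totals(prof)$ip_total_ng_L, 0)
})

test_that("profiles satisfy ip = total - core exactly and order invariance", {
  set.seed(42)
  total <- setNames(as.list(runif(7, 0.001, 2)), ether_compounds)
  core <- setNames(as.list(runif(7, 0.001, 2)), ether_compounds)
  peaks <- dplyr::bind_rows(
    peaks_for_conc("S1", "hydrolyzed", total),
    peaks_for_conc("S1", "non_hydrolyzed", core)
  )
  prof <- quantify_lipids(peaks)
  expect_equal(prof$ip_ng_L, prof$total_ng_L - prof$core_ng_L,
    tolerance = 1e-12
  )
  shuffled <- quantify_lipids(peaks[sample(nrow(peaks)), ])
  expect_equal(ip_totals(shuffled), ip_totals(prof))
  expect_gte(ip_totals(prof)$ip_total_ng_L, 0)
})

test_that("missing compounds appear as zero with flag absent", {
  peaks <- dplyr::bind_rows(
    peaks_for_conc("S1", "hydrolyzed", c(`GDGT-0` = 0.5)),
    peaks_for_conc("S1", "non_hydrolyzed", c(`GDGT-0` = 0.2))
  )
  prof <- quantify_lipids(peaks)
  expect_equal(nrow(prof), length(ether_compounds))
  arch <- prof[prof$compound == "archeol", ]
  expect_equal(arch$total_ng_L, 0)
  expect_equal(arch$total_flag, "absent")
})

test_that("duplicate peak keys and C46-as-analyte are rejected", {
  dup <- dplyr::bind_rows(peak_row(), peak_row())
  expect_error(quantify_lipids(dup), "duplicate")
  expect_error(
    quantify_lipids(peak_row(compound = "C46-standard")), "C46"
  )
})

test_that("multiple adducts collapse to the maximum-area adduct", {
  peaks <- dplyr::bind_rows(
    peak_row(adduct = "M+NH4", peak_area = 2.0, noise_level = 1e-9),
    peak_row(adduct = "M+Na", peak_area = 1.0, noise_level = 1e-9)
  )
  prof <- quantify_lipids(peaks)
  # area 2.0 with RF 1.5: conc = 2 * 1.5 * 5 / 20 = 0.75
  expect_equal(prof$total_ng_L[prof$compound == "crenarchaeol"], 0.75)
})

test_that("a profile survives a CSV round trip unchanged", {
  ds <- generate_dataset(synthetic_config(
    depths = c(10, 150), n_profiles = 1, seed = 7
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(ds$peaks, path)
  reread <- read_peak_table(path)
  expect_equal(quantify_lipids(reread), quantify_lipids(ds$peaks))
})

test_that("samples with no quantifiable compound are marked control-like", {
  # every hydrolyzed peak fails SN
  peaks <- peaks_for_conc("S1", "hydrolyzed", c(`GDGT-0` = 0.5)) |>
    dplyr::mutate(noise_level = peak_area)
  totals <- ip_totals(quantify_lipids(peaks))
  expect_false(totals$quantifiable)
})

test_that("headgroup-class distributions are area fractions summing to one", {
  peaks <- dplyr::bind_rows(
    peak_row("S1", "non_hydrolyzed", "crenarchaeol", "HPH", peak_area = 100),
    peak_row("S1", "non_hydrolyzed", "GDGT-1", "HPH", peak_area = 100),
    peak_row("S1", "non_hydrolyzed", "GDGT-2", "DH", peak_area = 30),
    peak_row("S1", "non_hydrolyzed", "crenarchaeol-isomer", "DH", peak_area = 60),
    peak_row("S1", "non_hydrolyzed", "GDGT-0", "DH", peak_area = 10),
    peak_row("S1", "non_hydrolyzed", "GDGT-3", "PH", peak_area = 0)
  )
  dist <- ipl_class_distribution(peaks)
  hph <- dist[dist$headgroup_class == "HPH", ]
  expect_equal(sort(hph$fraction), c(0.5, 0.5))
  dh <- dist[dist$headgroup_class == "DH", ]
  expect_equal(
    setNames(dh$fraction, dh$compound)[
      c("GDGT-2", "crenarchaeol-isomer", "GDGT-0")
    ],
    c(`GDGT-2` = 0.3, `crenarchaeol-isomer` = 0.6, `GDGT-0` = 0.1)
  )
  # zero-area classes omitted; per-class fractions sum to 1
  expect_false("PH" %in% dist$headgroup_class)
  sums <- tapply(dist$fraction, dist$headgroup_class, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-9)
  # single-compound class is trivially 1
  single <- ipl_class_distribution(
    peak_row("S2", "non_hydrolyzed", "crenarchaeol", "HPH", peak_area = 100)
  )
  expect_equal(single$fraction, 1)
})

test_that("tex86 reproduces hand-computed ratios and edge cases", {
  prof <- function(g1, g2, g3, iso) {
    tibble::tibble(
      sample_id = "S1",
      compound = c("GDGT-1", "GDGT-2", "GDGT-3", "crenarchaeol-isomer"),
      core_ng_L = c(g1, g2, g3, iso)
    )
  }
  expect_equal(tex86(prof(1, 1, 1, 1))$tex86, 0.75)
  expect_equal(tex86(prof(2, 1, 1, 1))$tex86, 0.6)
  expect_equal(tex86(prof(1, 0, 0, 0))$tex86, 0)
  expect_warning(out <- tex86(prof(0, 0, 0, 0)), "undefined")
  expect_true(is.na(out$tex86))
})

test_that("tex86 is invariant to rescaling all concentrations", {
  base <- tibble::tibble(
    sample_id = "S1",
    compound = c("GDGT-1", "GDGT-2", "GDGT-3", "crenarchaeol-isomer"),
    core_ng_L = c(0.3, 0.7, 0.2, 1.4)
  )
  for (k in c(0.001, 1, 250)) {
    scaled <- dplyr::mutate(base, core_ng_L = core_ng_L * k)
    expect_equal(tex86(scaled)$tex86, tex86(base)$tex86)
  }
})
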