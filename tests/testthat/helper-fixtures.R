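# Shared fixtures: tiny hand-built peak tables and count tables.

peak_row <- function(sample_id = "S1", fraction = "hydrolyzed",
                     compound = "crenarchaeol", headgroup_class = "core",
                     adduct = "M+NH4", peak_area = 100, noise_level = 1,
                     is_area = 1, is_mass_ng = 5, volume_L = 20) {
  tibble::tibble(
    sample_id = sample_id, fraction = fraction, compound = compound,
    headgroup_class = headgroup_class, adduct = adduct,
    peak_area = peak_area, noise_level = noise_level, is_area = is_area,
    is_mass_ng = is_mass_ng, volume_L = volume_L
  )
}

# A peak table encoding exact concentrations: with is_area = 1, is_mass = 5,
# V = 20 and RF r, area a gives concentration a * r * 5 / 20 = a * r / 4.
# So area = conc * 4 / r recovers conc exactly.
peaks_for_conc <- function(sample_id, fraction, conc, config = quant_config()) {
  purrr::map_dfr(names(conc), function(cmp) {
    rf <- if (cmp == "archeol") config$rf_archeol else config$rf_crenarchaeol
    peak_row(
      sample_id = sample_id, fraction = fraction, compound = cmp,
      peak_area = conc[[cmp]] * 4 / rf,
      noise_level = 1e-9 # SN astronomically high: quantification never gated
    )
  })
}

# Simple wide count table from a named list sample -> counts vector.
count_table <- function(counts_by_sample, aasv_ids = NULL) {
  n <- length(counts_by_sample[[1]])
  aasv_ids <- aasv_ids %||% sprintf("aasv%02d", seq_len(n))
  out <- tibble::tibble(aasv_id = aasv_ids)
  for (s in names(counts_by_sample)) out[[s]] <- counts_by_sample[[s]]
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
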