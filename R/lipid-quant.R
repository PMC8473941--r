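# Internal-standard quantification of archaeal ether lipids from LC-MS SIM
# peak tables: core vs total (acid-hydrolyzed) concentrations, intact polar
# lipids by subtraction, headgroup-class peak-area distributions, and TEX86.

#' Recognised ether lipid compounds and headgroup classes
#'
#' The analyte set covers the isoprenoid tetraethers with zero to three
#' cyclopentane rings (GDGT-0 to GDGT-3), crenarchaeol and its late-eluting
#' regioisomer, and the diether archeol. `C46-standard` is the synthetic
#' tetraether internal standard spiked into every extract; it is a reference
#' compound only and must never appear as an analyte.
#'
#' @format Character vectors.
#' @name compounds
NULL

#' @rdname compounds
#' @export
gdgt_compounds <- c(
  "GDGT-0", "GDGT-1", "GDGT-2", "GDGT-3",
  "crenarchaeol", "crenarchaeol-isomer"
)

#' @rdname compounds
#' @export
ether_compounds <- c(gdgt_compounds, "archeol")

#' @rdname compounds
#' @export
headgroup_classes <- c("core", "MH", "DH", "PH", "HPH")

peak_table_columns <- c(
  "sample_id", "fraction", "compound", "headgroup_class", "adduct",
  "peak_area", "noise_level", "is_area", "is_mass_ng", "volume_L"
)

#' Quantification settings for the internal-standard method
#'
#' Single-point quantification relative to the C46 internal standard, with
#' compound response factors expressing how much weaker an analyte responds
#' than C46: 1.5 for crenarchaeol (applied to all GDGTs) and 4.0 for archeol.
#' Peaks must reach a signal-to-noise ratio of at least `sn_threshold` to be
#' quantified; concentrations below `loq_ng_per_L` are reported but flagged.
#'
#' @param rf_crenarchaeol Response factor applied to all GDGT core lipids.
#' @param rf_archeol Response factor applied to archeol.
#' @param sn_threshold Minimum signal-to-noise ratio (inclusive).
#' @param loq_ng_per_L Limit of quantification in ng/L.
#' @return A validated list of class `quant_config`.
#' @export
#' @examples
#' quant_config()
quant_config <- function(rf_crenarchaeol = 1.5, rf_archeol = 4.0,
                         sn_threshold = 5, loq_ng_per_L = 0.00060) {
  cfg <- list(
    rf_crenarchaeol = rf_crenarchaeol, rf_archeol = rf_archeol,
    sn_threshold = sn_threshold, loq_ng_per_L = loq_ng_per_L
  )
  bad <- names(cfg)[!vapply(cfg, function(x) {
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  }, logical(1))]
  if (length(bad) > 0) {
    abort(paste0(
      "quant_config fields must be single positive numbers; invalid: ",
      paste(bad, collapse = ", ")
    ))
  }
  structure(cfg, class = "quant_config")
}

response_factor <- function(compound, config) {
  unknown <- setdiff(unique(compound), ether_compounds)
  if (length(unknown) > 0) {
    abort(paste0("unknown compound: ", paste(unknown, collapse = ", ")))
  }
  ifelse(compound == "archeol", config$rf_archeol, config$rf_crenarchaeol)
}

#' Signal-to-noise ratio of a SIM peak
#'
#' @param peak_area Non-negative peak area (arbitrary units).
#' @param noise_level Positive noise level in the same units.
#' @return `peak_area / noise_level`, vectorised.
#' @export
#' @examples
#' signal_to_noise(10, 2)
signal_to_noise <- function(peak_area, noise_level) {
  if (any(!is.finite(noise_level)) || any(noise_level <= 0)) {
    abort("invalid noise: noise_level must be strictly positive")
  }
  if (any(peak_area < 0)) {
    abort("peak_area must be non-negative")
  }
  peak_area / noise_level
}

#' Quantify a core-lipid peak against the C46 internal standard
#'
#' Concentration is `(peak_area / is_area) * RF(compound) * is_mass_ng /
#' volume_L` in ng/L. Peaks with signal-to-noise below the threshold are
#' reported as zero with flag `failed_sn`; zero-area peaks as `absent`;
#' quantified concentrations below the limit of quantification keep their
#' computed value with flag `below_loq`.
#'
#' @param peak_area,noise_level,is_area,is_mass_ng,volume_L Peak measurement
#'   fields, recycled to a common length.
#' @param compound Compound name(s) from [ether_compounds].
#' @param config A [quant_config()].
#' @return A tibble with columns `conc_ng_L` and `flag`.
#' @export
#' @examples
#' quantify_core(2, 0.1, 1, 5, 20, "crenarchaeol")
quantify_core <- function(peak_area, noise_level, is_area, is_mass_ng,
                          volume_L, compound, config = quant_config()) {
  stopifnot(inherits(config, "quant_config"))
  if (any(compound == "C46-standard")) {
    abort("the C46 internal standard cannot be quantified as an analyte")
  }
  if (any(is_area <= 0) || any(is_mass_ng <= 0) || any(volume_L <= 0)) {
    abort("is_area, is_mass_ng and volume_L must be strictly positive")
  }
  rf <- response_factor(compound, config)
  sn <- signal_to_noise(peak_area, noise_level)
  conc <- (peak_area / is_area) * rf * is_mass_ng / volume_L
  flag <- dplyr::case_when(
    peak_area == 0 ~ "absent",
    sn < config$sn_threshold ~ "failed_sn",
    conc < config$loq_ng_per_L ~ "below_loq",
    TRUE ~ "ok"
  )
  conc[flag %in% c("absent", "failed_sn")] <- 0
  tibble::tibble(conc_ng_L = conc, flag = flag)
}

validate_peak_table <- function(peaks) {
  missing_cols <- setdiff(peak_table_columns, names(peaks))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "peak table is missing columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(peaks$compound == "C46-standard")) {
    abort("the C46 internal standard cannot be quantified as an analyte")
  }
  unknown <- setdiff(unique(peaks$compound), ether_compounds)
  if (length(unknown) > 0) {
    abort(paste0("unknown compound: ", paste(unknown, collapse = ", ")))
  }
  bad_frac <- setdiff(unique(peaks$fraction), c("hydrolyzed", "non_hydrolyzed"))
  if (length(bad_frac) > 0) {
    abort(paste0("unknown fraction: ", paste(bad_frac, collapse = ", ")))
  }
  bad_class <- setdiff(unique(peaks$headgroup_class), headgroup_classes)
  if (length(bad_class) > 0) {
    abort(paste0("unknown headgroup class: ", paste(bad_class, collapse = ", ")))
  }
  if (any(peaks$fraction == "hydrolyzed" & peaks$headgroup_class != "core")) {
    abort("hydrolyzed-fraction peaks must be core lipids")
  }
  if (any(peaks$compound == "archeol" &
            !peaks$headgroup_class %in% c("core", "MH"))) {
    abort("intact polar archeol is limited to the MH headgroup class")
  }
  dup <- peaks |>
    dplyr::count(
      .data$sample_id, .data$fraction, .data$compound,
      .data$headgroup_class, .data$adduct
    ) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "duplicate peak records for ",
      paste(dup$sample_id[1], dup$fraction[1], dup$compound[1],
            dup$headgroup_class[1], dup$adduct[1]),
      " (and possibly others)"
    ))
  }
  invisible(peaks)
}

# One adduct per (sample, fraction, compound, class): keep the maximum area.
collapse_adducts <- function(peaks) {
  peaks |>
    dplyr::group_by(
      .data$sample_id, .data$fraction, .data$compound, .data$headgroup_class
    ) |>
    dplyr::slice_max(.data$peak_area, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Build per-sample lipid profiles from a SIM peak table
#'
#' Quantifies core lipids in both the non-hydrolyzed fraction (`core_ng_L`)
#' and the acid-hydrolyzed fraction (`total_ng_L`), and derives the intact
#' polar lipid concentration per compound by subtraction, `ip_ng_L =
#' total_ng_L - core_ng_L`. Negative per-compound differences are retained
#' here (they arise from fraction-specific matrix effects) and are clamped to
#' zero only when summed by [ip_totals()]. Compounds absent from the table
#' appear with concentration zero and flag `absent`. When several adducts of
#' one compound were monitored, the maximum-area adduct is used.
#'
#' @param peaks A peak table with columns `sample_id`, `fraction`
#'   (`"hydrolyzed"`/`"non_hydrolyzed"`), `compound`, `headgroup_class`,
#'   `adduct`, `peak_area`, `noise_level`, `is_area`, `is_mass_ng`,
#'   `volume_L`. See [read_peak_table()].
#' @param config A [quant_config()].
#' @return A tibble with one row per sample and compound: `core_ng_L`,
#'   `core_flag`, `total_ng_L`, `total_flag` (from the hydrolyzed fraction,
#'   which drives the intact-polar budget), and `ip_ng_L`.
#' @export
quantify_lipids <- function(peaks, config = quant_config()) {
  stopifnot(inherits(config, "quant_config"))
  peaks <- tibble::as_tibble(peaks)
  validate_peak_table(peaks)

  core_rows <- peaks |>
    dplyr::filter(.data$headgroup_class == "core") |>
    collapse_adducts()
  quantified <- dplyr::bind_cols(
    core_rows,
    quantify_core(
      core_rows$peak_area, core_rows$noise_level, core_rows$is_area,
      core_rows$is_mass_ng, core_rows$volume_L, core_rows$compound, config
    )
  ) |>
    dplyr::select(
      "sample_id", "fraction", "compound", "conc_ng_L", "flag"
    )

  grid <- tidyr::expand_grid(
    sample_id = unique(peaks$sample_id),
    fraction = c("hydrolyzed", "non_hydrolyzed"),
    compound = ether_compounds
  )
  grid |>
    dplyr::left_join(quantified,
      by = c("sample_id", "fraction", "compound")
    ) |>
    dplyr::mutate(
      conc_ng_L = dplyr::coalesce(.data$conc_ng_L, 0),
      flag = dplyr::coalesce(.data$flag, "absent")
    ) |>
    tidyr::pivot_wider(
      names_from = "fraction",
      values_from = c("conc_ng_L", "flag")
    ) |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      compound = factor(.data$compound, levels = ether_compounds),
      core_ng_L = .data$conc_ng_L_non_hydrolyzed,
      core_flag = .data$flag_non_hydrolyzed,
      total_ng_L = .data$conc_ng_L_hydrolyzed,
      total_flag = .data$flag_hydrolyzed,
      ip_ng_L = .data$total_ng_L - .data$core_ng_L
    ) |>
    dplyr::arrange(.data$sample_id, .data$compound) |>
    dplyr::mutate(compound = as.character(.data$compound))
}

#' Per-sample intact polar lipid totals with the negative-clamp rule
#'
#' Sums per-compound intact polar concentrations after clamping negative
#' values to zero, so `ip_total_ng_L` is never negative. A sample where no
#' compound in the hydrolyzed fraction reached an `ok` flag (everything
#' failed signal-to-noise, fell below the limit of quantification, or was
#' absent) is marked `quantifiable = FALSE`; such a sample behaves as an
#' in-situ blank and is excluded from quota summaries downstream.
#'
#' @param profiles Output of [quantify_lipids()].
#' @return A tibble with `sample_id`, `ip_total_ng_L`, `total_ng_L` (summed
#'   hydrolyzed-fraction concentration) and `quantifiable`.
#' @export
ip_totals <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      ip_total_ng_L = sum(pmax(.data$ip_ng_L, 0)),
      total_ng_L = sum(.data$total_ng_L),
      quantifiable = any(.data$total_flag == "ok"),
      .groups = "drop"
    )
}

#' Peak-area distribution of intact polar lipids by headgroup class
#'
#' Authentic standards for the glycosidic and phosphatidic headgroup forms
#' (MH, DH, PH, HPH) are not available, so those pools cannot be quantified
#' absolutely; instead the within-class composition is reported as peak-area
#' fractions. Classes with zero total area in a sample are omitted.
#'
#' @param peaks A peak table as for [quantify_lipids()].
#' @return A tibble `sample_id`, `headgroup_class`, `compound`, `fraction`
#'   where fractions sum to one within each sample and class.
#' @export
ipl_class_distribution <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  validate_peak_table(peaks)
  ipl <- peaks |>
    dplyr::filter(
      .data$fraction == "non_hydrolyzed", .data$headgroup_class != "core"
    ) |>
    collapse_adducts()
  if (nrow(ipl) == 0) {
    return(tibble::tibble(
      sample_id = character(), headgroup_class = character(),
      compound = character(), fraction = numeric()
    ))
  }
  ipl |>
    dplyr::group_by(.data$sample_id, .data$headgroup_class) |>
    dplyr::filter(sum(.data$peak_area) > 0) |>
    dplyr::mutate(fraction = .data$peak_area / sum(.data$peak_area)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "headgroup_class", "compound", "fraction") |>
    dplyr::arrange(.data$sample_id, .data$headgroup_class, .data$compound)
}

#' TEX86 ring index
#'
#' Ratio of the tetraethers with two and three cyclopentane rings plus the
#' crenarchaeol regioisomer to the same set plus GDGT-1:
#' `(GDGT-2 + GDGT-3 + cren-isomer) / (GDGT-1 + GDGT-2 + GDGT-3 +
#' cren-isomer)`. Scale-invariant in the concentrations. When all four
#' compounds are zero the index is undefined and returned as `NA` with a
#' warning rather than zero.
#'
#' @param profiles Output of [quantify_lipids()] (or any tibble with
#'   `sample_id`, `compound` and the concentration column).
#' @param value Name of the concentration column to use; core lipids by
#'   default, matching the sediment proxy definition.
#' @return A tibble `sample_id`, `tex86`.
#' @export
tex86 <- function(profiles, value = "core_ng_L") {
  needed <- c("GDGT-1", "GDGT-2", "GDGT-3", "crenarchaeol-isomer")
  wide <- profiles |>
    dplyr::filter(.data$compound %in% needed) |>
    dplyr::select("sample_id", "compound", dplyr::all_of(value)) |>
    tidyr::pivot_wider(
      names_from = "compound", values_from = dplyr::all_of(value),
      values_fill = 0
    )
  missing_cols <- setdiff(needed, names(wide))
  for (m in missing_cols) wide[[m]] <- 0
  if (any(unlist(wide[needed]) < 0)) {
    abort("tex86 requires non-negative concentrations")
  }
  num <- wide[["GDGT-2"]] + wide[["GDGT-3"]] + wide[["crenarchaeol-isomer"]]
  den <- num + wide[["GDGT-1"]]
  out <- tibble::tibble(
    sample_id = wide$sample_id,
    tex86 = ifelse(den > 0, num / den, NA_real_)
  )
  if (anyNA(out$tex86)) {
    warn("tex86 undefined for samples with no ring-bearing GDGTs; returned NA")
  }
  out
}

#' Read and write the package's tabular formats
#'
#' Thin readr wrappers for the CSV/TSV dialects used throughout: the LC-MS
#' peak table (CSV, one row per monitored peak), the AASV count table (TSV,
#' AASVs as rows in column `aasv_id`, samples as columns), the two-column
#' taxonomy table (TSV: `aasv_id`, `group`), and the ddPCR totals (CSV:
#' `sample_id`, `total_copies_per_L`).
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return The parsed tibble (readers) or `x` invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_peak_table <- function(path) {
  peaks <- tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE))
  validate_peak_table(peaks)
  peaks
}

#' @rdname table_io
#' @export
write_peak_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}
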