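# Mass-balance attribution of intact polar ether lipids to archaeal groups:
# per-cell quotas, expected pools, attribution fractions, inferred producer
# abundances, membrane fractions and sequencing-detectability verdicts.

#' Parameters of the lipid mass-balance model
#'
#' @param quota_thaumarchaeota Published per-cell ether lipid content of
#'   cultivated marine Thaumarchaeota, ng/cell.
#' @param quota_theoretical_membrane Estimated total polar lipid content of
#'   an archaeon with a 500 nm cell diameter, ng/cell; denominator of
#'   [membrane_fraction()].
#' @param quota_thermoplasmatota Optional fixed per-cell quota for
#'   Thermoplasmatota (ng/cell). `NULL` (default) means estimate it from the
#'   surface samples where Thermoplasmatota are the only archaea present.
#' @param copy_number SSU rRNA gene copies per cell used to convert copies to
#'   cells throughout (default 1).
#' @param min_group_fraction Archaeal groups below this relative abundance
#'   are excluded from expected-pool accounting (default 0.01, i.e. groups
#'   under 1 percent are not considered plausible bulk lipid sources).
#' @param thaum_group,thermo_groups Group labels identifying Thaumarchaeota
#'   and Thermoplasmatota in the abundance table.
#' @return A validated list of class `budget_params`.
#' @export
budget_params <- function(quota_thaumarchaeota = 1.27e-6,
                          quota_theoretical_membrane = 1.4e-6,
                          quota_thermoplasmatota = NULL,
                          copy_number = 1,
                          min_group_fraction = 0.01,
                          thaum_group = "MGI",
                          thermo_groups = c("MGII", "MGIII")) {
  num <- list(
    quota_thaumarchaeota = quota_thaumarchaeota,
    quota_theoretical_membrane = quota_theoretical_membrane,
    copy_number = copy_number
  )
  bad <- names(num)[!vapply(num, function(x) {
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  }, logical(1))]
  if (length(bad) > 0) {
    abort(paste0(
      "budget_params fields must be single positive numbers; invalid: ",
      paste(bad, collapse = ", ")
    ))
  }
  if (!is.null(quota_thermoplasmatota) && quota_thermoplasmatota <= 0) {
    abort("quota_thermoplasmatota must be positive when supplied")
  }
  if (min_group_fraction < 0 || min_group_fraction >= 1) {
    abort("min_group_fraction must be in [0, 1)")
  }
  structure(
    list(
      quota_thaumarchaeota = quota_thaumarchaeota,
      quota_theoretical_membrane = quota_theoretical_membrane,
      quota_thermoplasmatota = quota_thermoplasmatota,
      copy_number = copy_number,
      min_group_fraction = min_group_fraction,
      thaum_group = thaum_group,
      thermo_groups = thermo_groups
    ),
    class = "budget_params"
  )
}

#' Per-cell lipid quota
#'
#' Ratio of a measured intact polar lipid pool to the cell density of its
#' hypothesised producer.
#'
#' @param ip_total_ng_L Non-negative lipid pool, ng/L.
#' @param cells_per_L Strictly positive cell density, cells/L.
#' @return Quota in ng/cell, vectorised.
#' @export
per_cell_quota <- function(ip_total_ng_L, cells_per_L) {
  if (any(cells_per_L <= 0)) abort("undefined quota: cells_per_L must be > 0")
  if (any(ip_total_ng_L < 0)) abort("ip_total_ng_L must be non-negative")
  ip_total_ng_L / cells_per_L
}

#' Expected lipid pool from a cell density and a per-cell quota
#'
#' @param cells_per_L Non-negative cell density.
#' @param quota_ng_per_cell Non-negative per-cell lipid content.
#' @return Pool in ng/L, vectorised.
#' @export
#' @examples
#' expected_pool(6.42e6, 1.27e-6)
expected_pool <- function(cells_per_L, quota_ng_per_cell) {
  if (any(cells_per_L < 0) || any(quota_ng_per_cell < 0)) {
    abort("cells_per_L and quota_ng_per_cell must be non-negative")
  }
  cells_per_L * quota_ng_per_cell
}

#' Cell density implied by a measured lipid pool
#'
#' Inverse of [expected_pool()]: the abundance a hypothesised producer would
#' need to account for a measured lipid pool at a given per-cell quota.
#'
#' @param ip_total_ng_L Non-negative lipid pool, ng/L.
#' @param quota_ng_per_cell Strictly positive per-cell lipid content.
#' @return Cells/L, vectorised.
#' @export
#' @examples
#' infer_cells(0.0010, 1.27e-6)
infer_cells <- function(ip_total_ng_L, quota_ng_per_cell) {
  if (any(quota_ng_per_cell <= 0)) abort("quota_ng_per_cell must be > 0")
  if (any(ip_total_ng_L < 0)) abort("ip_total_ng_L must be non-negative")
  ip_total_ng_L / quota_ng_per_cell
}

#' Measured quota as a percentage of the theoretical membrane content
#'
#' @param quota_ng_per_cell Non-negative per-cell quota.
#' @param params A [budget_params()] supplying the theoretical whole-membrane
#'   lipid content per cell.
#' @return Percentage, vectorised.
#' @export
membrane_fraction <- function(quota_ng_per_cell, params = budget_params()) {
  if (any(quota_ng_per_cell < 0)) abort("quota must be non-negative")
  100 * quota_ng_per_cell / params$quota_theoretical_membrane
}

#' Attribution fractions across candidate lipid sources
#'
#' Normalises a named vector of expected pools to fractions summing to one.
#' When every pool is zero the attribution is undefined and `NA` fractions
#' are returned with a warning.
#'
#' @param pools Named non-negative numeric vector of expected pools (ng/L).
#' @return Named fractions in `[0, 1]`.
#' @export
#' @examples
#' attribute_pools(c(`MGII/III` = 1.03e-2, MGI = 8.15))
attribute_pools <- function(pools) {
  if (any(pools < 0)) abort("expected pools must be non-negative")
  total <- sum(pools)
  if (total == 0) {
    warn("attribution undefined: all expected pools are zero")
    return(setNames(rep(NA_real_, length(pools)), names(pools)))
  }
  pools / total
}

#' Ratio of measured to expected lipid pool
#'
#' @param measured_ng_L Measured intact polar lipid total, ng/L.
#' @param expected_ng_L Expected total from the cell-quota model, ng/L.
#' @return `measured / expected`; `NA` with a warning where the expected
#'   total is zero.
#' @export
measured_vs_expected <- function(measured_ng_L, expected_ng_L) {
  if (any(measured_ng_L < 0) || any(expected_ng_L < 0)) {
    abort("pools must be non-negative")
  }
  out <- ifelse(expected_ng_L > 0, measured_ng_L / expected_ng_L, NA_real_)
  if (anyNA(out)) {
    warn("measured_vs_expected undefined where the expected pool is zero")
  }
  out
}

#' Would an inferred population have been sequenced?
#'
#' Converts an inferred cell density to a relative abundance against the
#' ddPCR total and compares it with the sequencing detection limit at the
#' sample's read depth. The comparison is inclusive: a population sitting
#' exactly at the one-read limit counts as detectable.
#'
#' @param inferred_cells_per_L Hypothesised producer density, cells/L.
#' @param total_copies_per_L Positive ddPCR total, copies/L.
#' @param read_depth Positive integer read count.
#' @param copy_number SSU rRNA copies per cell (default 1).
#' @return Tibble `relative_abundance_percent`, `detection_limit_percent`,
#'   `detectable`.
#' @export
detectability <- function(inferred_cells_per_L, total_copies_per_L,
                          read_depth, copy_number = 1) {
  if (any(total_copies_per_L <= 0)) abort("total_copies_per_L must be > 0")
  if (any(inferred_cells_per_L < 0)) abort("inferred cells must be >= 0")
  rel <- 100 * inferred_cells_per_L * copy_number / total_copies_per_L
  lim <- detection_limit(read_depth)
  tibble::tibble(
    relative_abundance_percent = rel,
    detection_limit_percent = lim,
    detectable = rel >= lim
  )
}

#' Full lipid mass-balance budget for a set of samples
#'
#' Joins per-sample intact polar lipid totals with absolute archaeal
#' abundances and runs the attribution model:
#'
#' * Samples where the Thaumarchaeota group is absent ("surface" samples)
#'   yield a per-cell Thermoplasmatota quota (`ip_total / thermo cells`), its
#'   fraction of the theoretical membrane content, the Thaumarchaeota density
#'   that the measured lipids would imply at the published quota, and a
#'   verdict on whether that population would have been sequenced.
#' * Samples containing Thaumarchaeota get expected pools per group (groups
#'   under `min_group_fraction` relative abundance excluded), attribution
#'   fractions, and the measured-over-expected ratio.
#'
#' Samples flagged non-quantifiable by [ip_totals()] (no compound reached an
#' `ok` flag) are retained in the output but excluded from quota summaries,
#' mirroring the treatment of an in-situ blank.
#'
#' @param profiles Output of [quantify_lipids()], or a precomputed
#'   [ip_totals()] tibble.
#' @param abundance Output of [absolute_abundance()].
#' @param params A [budget_params()].
#' @return An object of class `lipid_budget`: a list with `samples` (one row
#'   per sample), `pools` (one row per sample and candidate source group),
#'   the Thermoplasmatota quota summary (`quota_mean`, `quota_range`), and
#'   `params`. `tidy()` returns the per-sample table, `glance()` a one-row
#'   summary.
#' @export
lipid_budget <- function(profiles, abundance, params = budget_params()) {
  stopifnot(inherits(params, "budget_params"))
  ip <- if ("ip_total_ng_L" %in% names(profiles)) {
    profiles
  } else {
    ip_totals(profiles)
  }
  if (!"quantifiable" %in% names(ip)) ip$quantifiable <- TRUE

  ab <- abundance |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rel_abundance = .data$copies_per_L /
      .data$total_copies_per_L) |>
    dplyr::ungroup()

  per_sample <- ab |>
    dplyr::group_by(
      .data$sample_id, .data$read_depth, .data$total_copies_per_L,
      .data$detection_limit_percent
    ) |>
    dplyr::summarise(
      thermo_cells = sum(.data$cells_per_L[
        .data$group %in% params$thermo_groups
      ]),
      thaum_cells = sum(.data$cells_per_L[.data$group == params$thaum_group]),
      .groups = "drop"
    ) |>
    dplyr::inner_join(ip, by = "sample_id") |>
    dplyr::mutate(surface = .data$thaum_cells == 0)

  missing <- setdiff(ip$sample_id, per_sample$sample_id)
  if (length(missing) > 0) {
    abort(paste0(
      "samples without abundance data: ", paste(missing, collapse = ", ")
    ))
  }

  # Thermoplasmatota quota: estimated in samples where they are the only
  # candidate source, summarised as range + arithmetic mean over
  # quantifiable samples.
  per_sample <- per_sample |>
    dplyr::mutate(
      quota_thermo = dplyr::if_else(
        .data$surface & .data$thermo_cells > 0,
        .data$ip_total_ng_L / .data$thermo_cells,
        NA_real_
      ),
      membrane_percent = membrane_fraction(
        dplyr::coalesce(.data$quota_thermo, 0), params
      ),
      membrane_percent = dplyr::if_else(
        is.na(.data$quota_thermo), NA_real_, .data$membrane_percent
      )
    )

  usable <- per_sample$quantifiable & !is.na(per_sample$quota_thermo)
  quota_mean <- if (any(usable)) mean(per_sample$quota_thermo[usable]) else NA_real_
  quota_range <- if (any(usable)) range(per_sample$quota_thermo[usable]) else c(NA_real_, NA_real_)
  quota_thermo_used <- params$quota_thermoplasmatota %||% quota_mean

  # Surface samples: infer the Thaumarchaeota density the lipids would imply
  # and ask whether sequencing could have missed it.
  inferred <- ifelse(
    per_sample$surface,
    infer_cells(per_sample$ip_total_ng_L, params$quota_thaumarchaeota),
    NA_real_
  )
  rel <- 100 * inferred * params$copy_number / per_sample$total_copies_per_L
  per_sample <- per_sample |>
    dplyr::mutate(
      inferred_thaum_cells = inferred,
      inferred_thaum_percent = rel,
      detectable = .data$inferred_thaum_percent >=
        .data$detection_limit_percent
    )

  # Deep samples: expected pools per candidate group and attribution.
  group_quota <- function(group) {
    dplyr::case_when(
      group == params$thaum_group ~ params$quota_thaumarchaeota,
      group %in% params$thermo_groups ~ quota_thermo_used,
      TRUE ~ NA_real_
    )
  }
  pools <- ab |>
    dplyr::filter(
      .data$sample_id %in% per_sample$sample_id[!per_sample$surface],
      .data$rel_abundance >= params$min_group_fraction,
      !is.na(group_quota(.data$group))
    ) |>
    dplyr::mutate(
      quota_ng_per_cell = group_quota(.data$group),
      expected_pool_ng_L = expected_pool(
        .data$cells_per_L, .data$quota_ng_per_cell
      )
    ) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      attribution_fraction = if (sum(.data$expected_pool_ng_L) > 0) {
        .data$expected_pool_ng_L / sum(.data$expected_pool_ng_L)
      } else {
        NA_real_
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "sample_id", "group", "cells_per_L", "quota_ng_per_cell",
      "expected_pool_ng_L", "attribution_fraction"
    )

  expected_totals <- pools |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      expected_total_ng_L = sum(.data$expected_pool_ng_L), .groups = "drop"
    )
  per_sample <- per_sample |>
    dplyr::left_join(expected_totals, by = "sample_id") |>
    dplyr::mutate(
      measured_over_expected = dplyr::if_else(
        !.data$surface & .data$expected_total_ng_L > 0,
        .data$ip_total_ng_L / .data$expected_total_ng_L,
        NA_real_
      )
    ) |>
    dplyr::select(
      "sample_id", "surface", "quantifiable", "ip_total_ng_L",
      "thermo_cells", "thaum_cells", "quota_thermo", "membrane_percent",
      "inferred_thaum_cells", "inferred_thaum_percent",
      "detection_limit_percent", "detectable",
      "expected_total_ng_L", "measured_over_expected",
      "read_depth", "total_copies_per_L"
    )

  structure(
    list(
      samples = per_sample,
      pools = pools,
      quota_mean = quota_mean,
      quota_range = quota_range,
      quota_thermo_used = quota_thermo_used,
      params = params
    ),
    class = "lipid_budget"
  )
}

#' @export
print.lipid_budget <- function(x, ...) {
  cat("Lipid mass-balance budget\n")
  cat(sprintf(
    "  %d samples (%d surface, %d within/below DCM)\n",
    nrow(x$samples), sum(x$samples$surface), sum(!x$samples$surface)
  ))
  if (!is.na(x$quota_mean)) {
    cat(sprintf(
      "  Thermoplasmatota quota: %.3g-%.3g ng/cell (mean %.3g)\n",
      x$quota_range[1], x$quota_range[2], x$quota_mean
    ))
  }
  thermo <- x$pools$attribution_fraction[
    x$pools$group %in% x$params$thermo_groups
  ]
  if (length(thermo) > 0 && !all(is.na(thermo))) {
    by_sample <- x$pools |>
      dplyr::filter(.data$group %in% x$params$thermo_groups) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(f = sum(.data$attribution_fraction), .groups = "drop")
    cat(sprintf(
      "  Max Thermoplasmatota attribution within/below DCM: %.3g%%\n",
      100 * max(by_sample$f, na.rm = TRUE)
    ))
  }
  invisible(x)
}

#' @rdname lipid_budget
#' @param x A `lipid_budget` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lipid_budget <- function(x, ...) {
  x$samples
}

#' @rdname lipid_budget
#' @exportS3Method generics::glance
glance.lipid_budget <- function(x, ...) {
  thermo_frac <- x$pools |>
    dplyr::filter(.data$group %in% x$params$thermo_groups) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(f = sum(.data$attribution_fraction), .groups = "drop")
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_surface = sum(x$samples$surface),
    quota_thermo_mean = x$quota_mean,
    quota_thermo_min = x$quota_range[1],
    quota_thermo_max = x$quota_range[2],
    max_thermo_attribution = if (nrow(thermo_frac) > 0) {
      max(thermo_frac$f, na.rm = TRUE)
    } else {
      NA_real_
    },
    mean_measured_over_expected = mean(
      x$samples$measured_over_expected,
      na.rm = TRUE
    )
  )
}

#' @rdname lipid_budget
#' @param object A `lipid_budget` object.
#' @exportS3Method ggplot2::autoplot
autoplot.lipid_budget <- function(object, ...) {
  dat <- object$pools
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$sample_id, y = .data$expected_pool_ng_L, fill = .data$group
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_point(
      data = object$samples[!object$samples$surface, ],
      ggplot2::aes(x = .data$sample_id, y = .data$ip_total_ng_L),
      inherit.aes = FALSE, shape = 21, fill = "white"
    ) +
    ggplot2::labs(
      x = NULL, y = "IP ether lipids (ng/L)",
      title = "Expected source pools vs measured IP lipid totals",
      fill = "Group"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
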