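# Absolute archaeal abundances: amplicon relative abundances anchored to
# ddPCR SSU rRNA totals, sequencing detection limits, and alpha diversity.

archaeal_groups <- c(
  "MGI", "MGII", "MGIII", "Halobacterota", "Nanoarchaeota",
  "Woesearchaeota", "other-archaea"
)

counts_long <- function(counts) {
  if (!"aasv_id" %in% names(counts)) {
    abort("count table must have an `aasv_id` column; samples as columns")
  }
  counts |>
    tidyr::pivot_longer(-"aasv_id",
      names_to = "sample_id", values_to = "count"
    ) |>
    dplyr::mutate(count = as.integer(.data$count))
}

#' Absolute taxon abundances from amplicon counts and ddPCR totals
#'
#' Distributes each sample's total SSU rRNA gene concentration (copies/L,
#' from droplet digital PCR with the same universal primers) across archaeal
#' groups in proportion to their amplicon read counts:
#' `copies(group) = total * count(group) / count(all)`. Copies are converted
#' to cells with a per-cell rRNA operon copy number, one by default as
#' appropriate for oligotrophic marine archaea. Group totals conserve the
#' ddPCR total exactly.
#'
#' @param counts Wide count table: column `aasv_id` plus one non-negative
#'   integer column per sample.
#' @param taxonomy Two-column tibble `aasv_id`, `group` covering every AASV.
#' @param ddpcr Tibble `sample_id`, `total_copies_per_L` covering every
#'   sample in `counts`.
#' @param copy_number SSU rRNA gene copies per cell; either a single number
#'   or a named vector by group.
#' @return A tibble with one row per sample and group: `copies_per_L`,
#'   `cells_per_L`, plus per-sample `read_depth` and
#'   `detection_limit_percent`.
#' @export
absolute_abundance <- function(counts, taxonomy, ddpcr, copy_number = 1) {
  long <- counts_long(tibble::as_tibble(counts))
  if (any(long$count < 0)) abort("counts must be non-negative")
  missing_tax <- setdiff(unique(long$aasv_id), taxonomy$aasv_id)
  if (length(missing_tax) > 0) {
    abort(paste0(
      "AASVs without a taxonomy group: ", paste(missing_tax, collapse = ", ")
    ))
  }
  missing_dd <- setdiff(unique(long$sample_id), ddpcr$sample_id)
  if (length(missing_dd) > 0) {
    abort(paste0(
      "samples without a ddPCR total: ", paste(missing_dd, collapse = ", ")
    ))
  }

  by_group <- long |>
    dplyr::left_join(taxonomy, by = "aasv_id") |>
    dplyr::group_by(.data$sample_id, .data$group) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(read_depth = sum(.data$count)) |>
    dplyr::ungroup()
  if (any(by_group$read_depth == 0)) {
    abort("no reads: a sample has zero total counts")
  }

  cn <- copy_number
  if (is.null(names(cn))) {
    if (length(cn) != 1L) abort("unnamed copy_number must be a single value")
    cn_for <- function(group) rep(cn, length(group))
  } else {
    cn_for <- function(group) {
      out <- unname(cn[group])
      out[is.na(out)] <- 1
      out
    }
  }

  out <- by_group |>
    dplyr::left_join(ddpcr, by = "sample_id") |>
    dplyr::mutate(
      copies_per_L = .data$total_copies_per_L * .data$count / .data$read_depth,
      cells_per_L = copies_to_cells(.data$copies_per_L, cn_for(.data$group)),
      detection_limit_percent = detection_limit(.data$read_depth)
    ) |>
    dplyr::select(
      "sample_id", "group", "count", "copies_per_L", "cells_per_L",
      "read_depth", "total_copies_per_L", "detection_limit_percent"
    ) |>
    dplyr::arrange(.data$sample_id, .data$group)
  out
}

#' Convert SSU rRNA gene copies to cells
#'
#' @param copies_per_L Non-negative copy concentration.
#' @param copy_number Strictly positive per-cell gene copy number (default 1,
#'   the value for cultivated marine Thaumarchaeota and the typical state of
#'   oligotrophic marine picoplankton).
#' @return `copies_per_L / copy_number`, vectorised.
#' @export
copies_to_cells <- function(copies_per_L, copy_number = 1) {
  if (any(!is.finite(copy_number)) || any(copy_number <= 0)) {
    abort("copy_number must be strictly positive")
  }
  if (any(copies_per_L < 0)) abort("copies_per_L must be non-negative")
  copies_per_L / copy_number
}

#' Theoretical sequencing detection limit
#'
#' The relative abundance corresponding to a single read in a sample
#' sequenced to `read_depth` reads: `100 / read_depth`, in percent. A taxon
#' whose true relative abundance falls below this cannot be expected to
#' appear in the amplicon library.
#'
#' @param read_depth Positive integer read count(s).
#' @return Detection limit in percent, vectorised.
#' @export
#' @examples
#' detection_limit(1695)
detection_limit <- function(read_depth) {
  if (any(read_depth < 1)) abort("read_depth must be at least 1")
  100 / read_depth
}

#' Shannon diversity index (natural log)
#'
#' @param counts Non-negative count vector with a positive total.
#' @return `-sum(p * log(p))` over non-zero proportions.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) abort("shannon undefined for an all-zero count vector")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Observed richness
#'
#' @param counts Non-negative count vector.
#' @return Number of taxa with at least one read.
#' @export
richness <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  sum(counts > 0)
}

#' Per-sample alpha diversity summaries
#'
#' @param counts Wide count table as for [absolute_abundance()].
#' @return Tibble `sample_id`, `read_depth`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(counts) {
  counts_long(tibble::as_tibble(counts)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      read_depth = sum(.data$count),
      richness = richness(.data$count),
      shannon = shannon(.data$count),
      .groups = "drop"
    )
}

rarefy_once <- function(pool, depth, n_taxa) {
  drawn <- pool[sample.int(length(pool), depth)]
  sum(tabulate(drawn, nbins = n_taxa) > 0)
}

#' Monte-Carlo rarefaction of a count vector
#'
#' Mean number of distinct taxa recovered in random subsamples drawn without
#' replacement at each requested depth. At full depth the curve equals the
#' observed richness exactly.
#'
#' @param counts Non-negative count vector.
#' @param depths Integer subsampling depths, each at most `sum(counts)`.
#' @param reps Number of random subsamples per depth.
#' @param seed Integer seed making the curve reproducible.
#' @return Tibble `depth`, `mean_richness`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 100, seed = 1) {
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (any(depths > total)) {
    abort("rarefaction depth exceeds the total read count")
  }
  if (any(depths < 1) || reps < 1) abort("depths and reps must be >= 1")
  pool <- rep.int(seq_along(counts), counts)
  withr::with_seed(seed, {
    tibble::tibble(
      depth = as.integer(depths),
      mean_richness = vapply(depths, function(d) {
        mean(vapply(
          seq_len(reps),
          function(i) rarefy_once(pool, d, length(counts)),
          numeric(1)
        ))
      }, numeric(1))
    )
  })
}

#' @rdname table_io
#' @export
read_count_table <- function(path) {
  tibble::as_tibble(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname table_io
#' @export
write_count_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname table_io
#' @export
read_taxonomy <- function(path) {
  tax <- tibble::as_tibble(readr::read_tsv(path, show_col_types = FALSE))
  if (!all(c("aasv_id", "group") %in% names(tax))) {
    abort("taxonomy table needs columns `aasv_id` and `group`")
  }
  tax
}

#' @rdname table_io
#' @export
write_taxonomy <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname table_io
#' @export
read_ddpcr <- function(path) {
  dd <- tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE))
  if (!all(c("sample_id", "total_copies_per_L") %in% names(dd))) {
    abort("ddPCR table needs columns `sample_id` and `total_copies_per_L`")
  }
  if (any(dd$total_copies_per_L < 0)) {
    abort("ddPCR totals must be non-negative")
  }
  dd
}

#' @rdname table_io
#' @export
write_ddpcr <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}
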