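# Synthetic depth-profile datasets with known ground truth, emulating the
# statistical structure of stratified oligotrophic stations: two depth
# clusters split at the deep chlorophyll maximum, Thaumarchaeota absent
# above it, 100-1000x lower lipid concentrations above it, archeol a minor
# component, multiplicative peak-area noise, and fraction-specific matrix
# effects that occasionally drive per-compound IP estimates negative.

default_lipid_signature <- function() {
  sig <- rbind(
    MGI = c(0.30, 0.08, 0.08, 0.04, 0.40, 0.05, 0.05),
    MGII = c(0.45, 0.10, 0.08, 0.05, 0.20, 0.05, 0.07),
    MGIII = c(0.45, 0.10, 0.08, 0.05, 0.20, 0.05, 0.07),
    Halobacterota = c(0.20, 0, 0, 0, 0, 0, 0.80),
    Nanoarchaeota = c(1, 0, 0, 0, 0, 0, 0)
  )
  colnames(sig) <- ether_compounds
  sig
}

#' Configuration of the synthetic depth-profile generator
#'
#' Defaults encode the study conditions the generator emulates: total
#' archaeal SSU rRNA gene concentrations of 2.11e6-6.02e6 copies/L above the
#' deep chlorophyll maximum (DCM) and 6.0e6-1.22e7 within/below it; per-cell
#' ether lipid quotas of 1.27e-6 ng/cell for Thaumarchaeota (MGI) and
#' 1.21e-9 ng/cell for Thermoplasmatota (MGII/MGIII); per-sample read depths
#' of 1,695-40,915; MGI completely absent above the DCM; and core-lipid
#' pools four times the intact polar pool above the DCM but only a tenth of
#' it within/below (where living biomass dominates the signal).
#'
#' @param depths Sampling depths in metres, sorted ascending.
#' @param dcm_depth DCM depth (m); shallower samples form the "above"
#'   cluster.
#' @param n_profiles Number of stations/depth profiles.
#' @param composition Named list `above`/`below` of mean group compositions
#'   (each summing to one).
#' @param true_quota Named per-cell quotas (ng/cell) per group.
#' @param lipid_signature Group-by-compound matrix of lipid pool
#'   proportions; rows sum to one.
#' @param total_copies_range Named list `above`/`below` of uniform ranges
#'   for the ddPCR total (copies/L).
#' @param read_depth_range Uniform range of per-sample read depths.
#' @param core_to_ip Named vector `above`/`below`: ratio of the core lipid
#'   pool to the intact polar pool in each cluster.
#' @param noise_sigma Lognormal sdlog applied to every peak area.
#' @param matrix_effect_sigma Additional lognormal sdlog applied to the
#'   non-hydrolyzed fraction only; the source of negative IP estimates.
#' @param dirichlet_alpha Concentration of the per-sample Dirichlet jitter
#'   around the cluster composition (larger = less jitter).
#' @param n_aasv_per_group Number of AASVs simulated per group.
#' @param ipl_class_weights Relative weights of the MH/DH/PH/HPH headgroup
#'   classes used for the class-distribution peaks.
#' @param is_area,is_mass_ng,volume_L Internal-standard peak area, spiked
#'   standard mass (ng) and filtered volume (L) shared by all samples.
#' @param seed Integer seed; identical configs generate byte-identical
#'   datasets.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    depths = c(5, 25, 45, 75, 100, 125, 150, 175, 200),
    dcm_depth = 120,
    n_profiles = 2,
    composition = list(
      above = c(
        MGI = 0, MGII = 0.72, MGIII = 0.27,
        Halobacterota = 0.005, Nanoarchaeota = 0.005
      ),
      below = c(
        MGI = 0.40, MGII = 0.38, MGIII = 0.21,
        Halobacterota = 0.008, Nanoarchaeota = 0.002
      )
    ),
    true_quota = c(
      MGI = 1.27e-6, MGII = 1.21e-9, MGIII = 1.21e-9,
      Halobacterota = 1.21e-9, Nanoarchaeota = 0
    ),
    lipid_signature = default_lipid_signature(),
    total_copies_range = list(
      above = c(2.11e6, 6.02e6), below = c(6.0e6, 1.22e7)
    ),
    read_depth_range = c(1695, 40915),
    core_to_ip = c(above = 4, below = 0.1),
    noise_sigma = 0.10,
    matrix_effect_sigma = 0.15,
    dirichlet_alpha = 200,
    n_aasv_per_group = c(
      MGI = 30, MGII = 60, MGIII = 40, Halobacterota = 8, Nanoarchaeota = 5
    ),
    ipl_class_weights = c(MH = 0.35, DH = 0.25, PH = 0.15, HPH = 0.25),
    is_area = 1e6, is_mass_ng = 5, volume_L = 20,
    seed = 1) {
  cfg <- list(
    depths = depths, dcm_depth = dcm_depth, n_profiles = n_profiles,
    composition = composition, true_quota = true_quota,
    lipid_signature = lipid_signature,
    total_copies_range = total_copies_range,
    read_depth_range = read_depth_range, core_to_ip = core_to_ip,
    noise_sigma = noise_sigma, matrix_effect_sigma = matrix_effect_sigma,
    dirichlet_alpha = dirichlet_alpha,
    n_aasv_per_group = n_aasv_per_group,
    ipl_class_weights = ipl_class_weights,
    is_area = is_area, is_mass_ng = is_mass_ng, volume_L = volume_L,
    seed = seed
  )
  if (is.unsorted(depths, strictly = TRUE)) {
    abort("invalid synthetic_config: depths must be strictly increasing")
  }
  groups <- names(true_quota)
  for (cl in c("above", "below")) {
    comp <- composition[[cl]]
    if (is.null(comp) || !setequal(names(comp), groups)) {
      abort(paste0(
        "invalid synthetic_config: composition$", cl,
        " must name the same groups as true_quota"
      ))
    }
    if (abs(sum(comp) - 1) > 1e-8 || any(comp < 0)) {
      abort(paste0(
        "invalid synthetic_config: composition$", cl,
        " must be non-negative and sum to 1"
      ))
    }
  }
  if (any(true_quota < 0)) {
    abort("invalid synthetic_config: true_quota values must be >= 0")
  }
  if (!all(groups %in% rownames(lipid_signature))) {
    abort("invalid synthetic_config: lipid_signature must cover every group")
  }
  if (!identical(colnames(lipid_signature), ether_compounds)) {
    abort(paste0(
      "invalid synthetic_config: lipid_signature columns must be the ",
      "ether compounds in canonical order"
    ))
  }
  if (any(abs(rowSums(lipid_signature) - 1) > 1e-8) ||
        any(lipid_signature < 0)) {
    abort(paste0(
      "invalid synthetic_config: lipid_signature rows must be ",
      "non-negative and sum to 1"
    ))
  }
  if (noise_sigma < 0 || matrix_effect_sigma < 0) {
    abort("invalid synthetic_config: noise sigmas must be >= 0")
  }
  if (!setequal(names(n_aasv_per_group), groups) ||
        any(n_aasv_per_group < 1)) {
    abort(paste0(
      "invalid synthetic_config: n_aasv_per_group must give >= 1 AASV ",
      "for every group"
    ))
  }
  if (any(unlist(total_copies_range) <= 0) ||
        any(vapply(total_copies_range, diff, numeric(1)) < 0)) {
    abort("invalid synthetic_config: total_copies_range must be positive ranges")
  }
  if (read_depth_range[1] < 1 || diff(read_depth_range) < 0) {
    abort("invalid synthetic_config: read_depth_range must be a range >= 1")
  }
  structure(cfg, class = "synthetic_config")
}

# Area a concentration would produce at unit lognormal noise: inverse of the
# internal-standard quantification formula.
concentration_to_area <- function(conc, rf, cfg) {
  conc * cfg$volume_L / (rf * cfg$is_mass_ng) * cfg$is_area
}

synthetic_taxonomy <- function(cfg) {
  purrr::map_dfr(names(cfg$n_aasv_per_group), function(g) {
    k <- cfg$n_aasv_per_group[[g]]
    tibble::tibble(
      aasv_id = sprintf("AASV_%s_%03d", g, seq_len(k)),
      group = g
    )
  })
}

# Fixed geometric within-group AASV proportions (rank-abundance realism).
within_group_props <- function(k) {
  p <- 0.7^(seq_len(k) - 1)
  p / sum(p)
}

#' Generate a synthetic depth-profile dataset
#'
#' Produces every input the analysis pipeline consumes -- LC-MS peak table,
#' AASV count table, taxonomy, ddPCR totals, sample metadata -- together
#' with the ground truth used to validate recovery. For each sample: the
#' ddPCR total and group composition are drawn for its depth cluster; true
#' intact polar lipid pools are `cells x quota x signature`; the core pool
#' is `core_to_ip` times the IP pool; peak areas invert the quantification
#' formula and are perturbed by multiplicative lognormal noise, with an
#' extra matrix-effect term on the non-hydrolyzed fraction; counts are
#' multinomial at a uniform read depth. Everything derives from
#' `config$seed`, so identical configs give byte-identical outputs.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_dataset`: a list with `peaks`,
#'   `counts`, `taxonomy`, `ddpcr`, `metadata` and `truth` (per-sample true
#'   cells, per-group and per-compound lipid pools, quotas, cluster labels).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  groups <- names(cfg$true_quota)
  taxonomy <- synthetic_taxonomy(cfg)
  aasv_base <- taxonomy |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(within_prop = within_group_props(dplyr::n())) |>
    dplyr::ungroup()

  samples <- tidyr::expand_grid(
    station = sprintf("S%d", seq_len(cfg$n_profiles)),
    depth = cfg$depths
  ) |>
    dplyr::mutate(
      sample_id = sprintf("%s_%03dm", .data$station, .data$depth),
      cluster = ifelse(.data$depth < cfg$dcm_depth, "above", "below")
    )

  sn_noise <- setNames(
    concentration_to_area(
      0.00060, response_factor(ether_compounds, quant_config()), cfg
    ) / 5,
    ether_compounds
  )

  withr::with_seed(cfg$seed, {
    per_sample <- purrr::map(seq_len(nrow(samples)), function(i) {
      smp <- samples[i, ]
      cl <- smp$cluster
      total_copies <- runif(
        1, cfg$total_copies_range[[cl]][1], cfg$total_copies_range[[cl]][2]
      )
      base <- cfg$composition[[cl]][groups]
      comp <- numeric(length(base))
      pos <- base > 0
      comp[pos] <- rgamma(sum(pos), shape = cfg$dirichlet_alpha * base[pos])
      comp <- setNames(comp / sum(comp), groups)
      cells <- total_copies * comp

      pool_by_group <- cells * cfg$true_quota[groups]
      ip <- drop(pool_by_group %*% cfg$lipid_signature[groups, ])
      core <- cfg$core_to_ip[[cl]] * ip
      total <- core + ip

      rf <- response_factor(ether_compounds, quant_config())
      sd_core <- sqrt(cfg$noise_sigma^2 + cfg$matrix_effect_sigma^2)
      hyd_area <- concentration_to_area(total, rf, cfg) *
        exp(rnorm(length(total), 0, cfg$noise_sigma))
      core_area <- concentration_to_area(core, rf, cfg) *
        exp(rnorm(length(core), 0, sd_core))

      peak_row <- function(fraction, class, compound, area) {
        tibble::tibble(
          sample_id = smp$sample_id, fraction = fraction,
          compound = compound, headgroup_class = class,
          adduct = "M+NH4", peak_area = area,
          noise_level = sn_noise[compound],
          is_area = cfg$is_area, is_mass_ng = cfg$is_mass_ng,
          volume_L = cfg$volume_L
        )
      }
      peaks <- dplyr::bind_rows(
        peak_row("hydrolyzed", "core", ether_compounds, unname(hyd_area)),
        peak_row("non_hydrolyzed", "core", ether_compounds, unname(core_area))
      )
      ipl <- purrr::map_dfr(names(cfg$ipl_class_weights), function(class) {
        cmp <- if (class == "MH") ether_compounds else gdgt_compounds
        conc <- ip[cmp] * cfg$ipl_class_weights[[class]]
        area <- concentration_to_area(conc, rf[match(cmp, ether_compounds)], cfg) *
          exp(rnorm(length(cmp), 0, cfg$noise_sigma))
        peak_row("non_hydrolyzed", class, cmp, unname(area))
      })
      peaks <- dplyr::bind_rows(peaks, ipl)

      read_depth <- round(runif(1, cfg$read_depth_range[1], cfg$read_depth_range[2]))
      probs <- comp[aasv_base$group] * aasv_base$within_prop
      counts <- drop(rmultinom(1, read_depth, probs))

      list(
        peaks = peaks,
        counts = tibble::tibble(
          aasv_id = aasv_base$aasv_id, sample_id = smp$sample_id,
          count = counts
        ),
        ddpcr = tibble::tibble(
          sample_id = smp$sample_id, total_copies_per_L = total_copies
        ),
        cells = tibble::tibble(
          sample_id = smp$sample_id, group = groups,
          cells_per_L = unname(cells), cluster = cl
        ),
        pools = tibble::tibble(
          sample_id = smp$sample_id, group = groups,
          true_pool_ng_L = unname(pool_by_group)
        ),
        compound_pools = tibble::tibble(
          sample_id = smp$sample_id, compound = ether_compounds,
          ip_ng_L = unname(ip), core_ng_L = unname(core),
          total_ng_L = unname(total)
        )
      )
    })

    peaks <- purrr::map_dfr(per_sample, "peaks")
    counts_wide <- purrr::map_dfr(per_sample, "counts") |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "count") |>
      dplyr::arrange(match(.data$aasv_id, taxonomy$aasv_id))
    ddpcr <- purrr::map_dfr(per_sample, "ddpcr")
    truth_cells <- purrr::map_dfr(per_sample, "cells")
    truth_pools <- purrr::map_dfr(per_sample, "pools")
    truth_compound <- purrr::map_dfr(per_sample, "compound_pools")

    metadata <- samples |>
      dplyr::mutate(
        dcm_depth = cfg$dcm_depth,
        chl_a_ug_L = 0.05 + 0.45 * exp(-((.data$depth - cfg$dcm_depth) / 30)^2)
      ) |>
      dplyr::select(
        "sample_id", "station", "depth", "dcm_depth", "cluster", "chl_a_ug_L"
      )

    structure(
      list(
        peaks = peaks,
        counts = counts_wide,
        taxonomy = taxonomy,
        ddpcr = ddpcr,
        metadata = metadata,
        truth = list(
          cells = truth_cells,
          pools = truth_pools,
          compound_pools = truth_compound,
          quotas = cfg$true_quota,
          clusters = samples |> dplyr::select("sample_id", "cluster")
        ),
        config = cfg
      ),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic depth-profile dataset: %d samples (%d above DCM), %d AASVs\n",
    nrow(x$metadata), sum(x$metadata$cluster == "above"), nrow(x$taxonomy)
  ))
  invisible(x)
}

#' Write a synthetic dataset to disk in the pipeline's input dialects
#'
#' Emits `peaks.csv`, `counts.tsv`, `taxonomy.tsv`, `ddpcr.csv`,
#' `metadata.csv` and `truth.json` into `dir`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return The vector of file paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    peaks = file.path(dir, "peaks.csv"),
    counts = file.path(dir, "counts.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    ddpcr = file.path(dir, "ddpcr.csv"),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_peak_table(dataset$peaks, paths["peaks"])
  write_count_table(dataset$counts, paths["counts"])
  write_taxonomy(dataset$taxonomy, paths["taxonomy"])
  write_ddpcr(dataset$ddpcr, paths["ddpcr"])
  readr::write_csv(dataset$metadata, paths["metadata"])
  jsonlite::write_json(
    dataset$truth, paths["truth"],
    dataframe = "columns", digits = NA, auto_unbox = TRUE
  )
  invisible(paths)
}
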