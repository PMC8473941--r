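# Mass-balance model: quotas, expected pools, attribution, detectability.

test_that("per_cell_quota is the lipid pool per producer cell", {
  expect_equal(per_cell_quota(0.0121, 1.0e7), 1.21e-9)
  expect_equal(per_cell_quota(0, 5e6), 0)
  expect_equal(per_cell_quota(1.27e-6 * 1e6, 1e6), 1.27e-6)
  expect_error(per_cell_quota(1, 0), "undefined quota")
})

test_that("expected_pool reproduces the printed pool maxima", {
  # max Thermoplasmatota abundance x mean quota -> printed MGII/III maximum
  expect_equal(signif(expected_pool(8.55e6, 1.21e-9), 3), 1.03e-2)
  # max Thaumarchaeota abundance x published quota -> printed maximum
  expect_equal(signif(expected_pool(6.42e6, 1.27e-6), 3), 8.15)
  expect_equal(expected_pool(0, 1e-6), 0)
  expect_error(expected_pool(-1, 1), "non-negative")
})

test_that("infer_cells reproduces the printed minimum inferred abundance", {
  # minimum surface IP-ether pool / published Thaumarchaeota quota
  expect_equal(signif(infer_cells(0.0010, 1.27e-6), 3), 7.87e2)
  expect_equal(infer_cells(0, 1.27e-6), 0)
  expect_equal(infer_cells(2.54e-6, 1.27e-6), 2)
  expect_error(infer_cells(1, 0), "> 0")
})

test_that("quota and pool operations are exact inverses", {
  set.seed(5)
  cells <- runif(50, 1e3, 1e8)
  quota <- 10^runif(50, -10, -5)
  pool <- runif(50, 1e-4, 20)
  expect_equal(
    expected_pool(cells, per_cell_quota(pool, cells)), pool,
    tolerance = 1e-12
  )
  expect_equal(
    infer_cells(expected_pool(cells, quota), quota), cells,
    tolerance = 1e-12
  )
})

test_that("membrane_fraction scales against the theoretical membrane quota", {
  expect_equal(membrane_fraction(1.4e-6), 100)
  expect_equal(membrane_fraction(0), 0)
  # printed minimum Thermoplasmatota quota -> ~0.018% of a full membrane
  expect_equal(round(membrane_fraction(2.5e-10), 3), 0.018)
})

test_that("attribution fractions normalise pools and flag degenerate input", {
  # printed pool maxima: Thermoplasmatota share sits below the 1% bound
  f <- attribute_pools(c(thermo = 1.03e-2, thaum = 8.15))
  expect_equal(unname(f["thermo"]), 1.03e-2 / (1.03e-2 + 8.15))
  expect_lt(f[["thermo"]], 0.01)
  expect_equal(unname(attribute_pools(c(A = 1, B = 1))), c(0.5, 0.5))
  expect_equal(unname(attribute_pools(c(A = 1, B = 0))), c(1, 0))
  expect_error(attribute_pools(c(A = -1, B = 1)), "non-negative")
  expect_warning(f0 <- attribute_pools(c(A = 0, B = 0)), "undefined")
  expect_true(all(is.na(f0)))
})

test_that("attribution sums to one and is scale-invariant", {
  set.seed(8)
  for (rep in 1:5) {
    pools <- setNames(runif(4, 0, 5), letters[1:4])
    f <- attribute_pools(pools)
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_equal(attribute_pools(pools * 37.5), f)
  }
})

test_that("measured_vs_expected is the plain ratio with zero signalled", {
  expect_equal(measured_vs_expected(10, 5), 2)
  expect_equal(round(measured_vs_expected(16.92, 8.16), 2), 2.07)
  expect_equal(measured_vs_expected(3.3, 3.3), 1)
  expect_warning(r <- measured_vs_expected(1, 0), "undefined")
  expect_true(is.na(r))
})

test_that("detectability compares inferred abundance with the one-read limit", {
  v <- detectability(4.03e3, 4e6, 1695)
  expect_equal(v$relative_abundance_percent, 100 * 4.03e3 / 4e6)
  expect_equal(v$detection_limit_percent, 100 / 1695)
  expect_true(v$detectable)
  expect_false(detectability(0, 4e6, 1695)$detectable)
  # boundary is inclusive: exactly one read's worth is detectable
  depth <- 2000
  total <- 5e6
  at_limit <- total * (100 / depth) / 100
  expect_true(detectability(at_limit, total, depth)$detectable)
  expect_false(detectability(at_limit * 0.999, total, depth)$detectable)
})

budget_fixture <- function() {
  # two surface samples (no MGI) and two deep samples; exact arithmetic
  abundance <- tibble::tibble(
    sample_id = rep(c("surf1", "surf2", "deep1", "deep2"), each = 3),
    group = rep(c("MGI", "MGII", "MGIII"), 4),
    copies_per_L = c(
      0, 3e6, 1e6,
      0, 2e6, 2e6,
      4e6, 3e6, 1e6,
      6e6, 2e6, 2e6
    ),
    cells_per_L = c(
      0, 3e6, 1e6,
      0, 2e6, 2e6,
      4e6, 3e6, 1e6,
      6e6, 2e6, 2e6
    )
  ) |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(
      total_copies_per_L = sum(copies_per_L),
      read_depth = 10000L,
      detection_limit_percent = 100 / 10000
    ) |>
    dplyr::ungroup()
  ip <- tibble::tibble(
    sample_id = c("surf1", "surf2", "deep1", "deep2"),
    ip_total_ng_L = c(4e6 * 2e-9, 4e6 * 1e-9, 8, 10),
    quantifiable = TRUE
  )
  list(abundance = abundance, ip = ip)
}

test_that("lipid_budget estimates surface quotas and summarises them", {
  fx <- budget_fixture()
  b <- lipid_budget(fx$ip, fx$abundance)
  s <- tidy(b)
  expect_equal(sum(s$surface), 2)
  # per-sample quota = ip_total / thermoplasmatota cells
  expect_equal(
    s$quota_thermo[s$sample_id == "surf1"], 2e-9
  )
  expect_equal(b$quota_mean, 1.5e-9)
  expect_equal(b$quota_range, c(1e-9, 2e-9))
  # membrane fraction uses the theoretical whole-membrane content
  expect_equal(
    s$membrane_percent[s$sample_id == "surf1"], 100 * 2e-9 / 1.4e-6
  )
})

test_that("lipid_budget infers surface Thaumarchaeota and their detectability", {
  fx <- budget_fixture()
  b <- lipid_budget(fx$ip, fx$abundance)
  s <- tidy(b)
  surf1 <- s[s$sample_id == "surf1", ]
  expect_equal(surf1$inferred_thaum_cells, 8e-3 / 1.27e-6)
  expect_equal(
    surf1$inferred_thaum_percent,
    100 * (8e-3 / 1.27e-6) / 4e6
  )
  # ~0.157% against a 0.01% one-read limit: would have been sequenced
  expect_true(surf1$detectable)
})

test_that("lipid_budget expected pools, attribution and ratio on deep samples", {
  fx <- budget_fixture()
  b <- lipid_budget(fx$ip, fx$abundance)
  pools <- b$pools
  deep1 <- pools[pools$sample_id == "deep1", ]
  # MGI at the published quota, thermo groups at the estimated mean
  expect_equal(
    deep1$expected_pool_ng_L[deep1$group == "MGI"], 4e6 * 1.27e-6
  )
  expect_equal(
    deep1$expected_pool_ng_L[deep1$group == "MGII"], 3e6 * 1.5e-9
  )
  expect_equal(sum(deep1$attribution_fraction), 1, tolerance = 1e-9)
  s <- tidy(b)
  d1 <- s[s$sample_id == "deep1", ]
  expect_equal(
    d1$measured_over_expected,
    8 / (4e6 * 1.27e-6 + 4e6 * 1.5e-9)
  )
  expect_true(is.na(d1$quota_thermo))
})

test_that("groups below the relative-abundance floor are excluded from pools", {
  fx <- budget_fixture()
  extra <- tibble::tibble(
    sample_id = "deep1", group = "Halobacterota",
    copies_per_L = 4e4, cells_per_L = 4e4,
    total_copies_per_L = 8e6 + 4e4, read_depth = 10000L,
    detection_limit_percent = 0.01
  )
  ab <- dplyr::bind_rows(fx$abundance, extra) |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(total_copies_per_L = sum(copies_per_L)) |>
    dplyr::ungroup()
  params <- budget_params(thermo_groups = c("MGII", "MGIII", "Halobacterota"))
  b <- lipid_budget(fx$ip, ab, params)
  # 4e4 / 8.04e6 ~ 0.5% < 1% floor: no Halobacterota pool
  expect_false("Halobacterota" %in% b$pools$group)
  b2 <- lipid_budget(
    fx$ip, ab,
    budget_params(
      thermo_groups = c("MGII", "MGIII", "Halobacterota"),
      min_group_fraction = 0
    )
  )
  expect_true("Halobacterota" %in% b2$pools$group)
})

test_that("non-quantifiable samples are excluded from quota summaries", {
  fx <- budget_fixture()
  fx$ip$quantifiable[fx$ip$sample_id == "surf1"] <- FALSE
  b <- lipid_budget(fx$ip, fx$abundance)
  expect_equal(b$quota_mean, 1e-9) # only surf2 contributes
  # the sample itself is still reported
  expect_true("surf1" %in% tidy(b)$sample_id)
})

test_that("glance summarises the budget in one row", {
  fx <- budget_fixture()
  g <- glance(lipid_budget(fx$ip, fx$abundance))
  expect_equal(nrow(g), 1)
  expect_equal(g$n_surface, 2)
  expect_equal(g$quota_thermo_mean, 1.5e-9)
  expect_lt(g$max_thermo_attribution, 0.01)
})
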