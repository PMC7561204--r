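test_that("contingency tables are one-unit-versus-rest with conserved margins", {
  prof <- tibble::tibble(
    event_id = "EV1", unit_kind = "group",
    unit = rep(c("nervous", "other"), each = 3),
    side = rep(c("main", "alternative", "intersect"), 2),
    ped = c(5L, 0L, 2L, 5L, 10L, 8L)
  )
  tab <- make_table(prof, "EV1", "nervous", "main_vs_alt")
  expect_equal(unname(tab), matrix(c(5L, 5L, 0L, 10L), 2, byrow = TRUE))
  # margins equal the side totals
  expect_equal(unname(rowSums(tab)), c(10L, 10L))

  tab2 <- make_table(prof, "EV1", "other", "alt_vs_intersect")
  expect_equal(unname(tab2), matrix(c(10L, 0L, 8L, 2L), 2, byrow = TRUE))

  # an empty unit still yields a valid table with a zero column
  prof0 <- dplyr::mutate(prof, ped = ifelse(unit == "nervous", 0L, ped))
  tab0 <- make_table(prof0, "EV1", "nervous", "main_vs_alt")
  expect_equal(unname(tab0[, 1]), c(0L, 0L))

  expect_error(make_table(prof, "EV1", "muscle", "main_vs_alt"),
               class = "splicepeds_schema_error")
  expect_error(make_table(prof, "EV1", "nervous", "up_vs_down"),
               class = "splicepeds_invalid_input")
})

test_that("two-sided Fisher p-values match enumeration and reference implementation", {
  expect_equal(fisher_two_sided(matrix(c(2, 2, 2, 2), 2)), 1)
  expect_equal(fisher_two_sided(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
  # the published nervous-vs-digestive concordance table is very significant
  expect_lt(fisher_two_sided(matrix(c(32, 7, 46, 78), 2)), 1e-5)

  set.seed(17)
  for (i in 1:200) {
    tot <- sample(4:60, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c_ <- cuts[3] - cuts[2]
    d <- tot - cuts[3]
    tab <- matrix(c(a, c_, b, d), 2)
    p <- fisher_two_sided(tab)
    expect_equal(p, oracle_fisher(a, b, c_, d), tolerance = 1e-12)
    # independent reference implementation agrees
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-6)
    # row swap leaves the two-sided p unchanged
    expect_equal(p, fisher_two_sided(tab[2:1, ]), tolerance = 1e-12)
  }
})

test_that("exactly proportional tables never show association", {
  set.seed(3)
  for (i in 1:20) {
    base <- c(sample(1:6, 1), sample(1:6, 1))
    k1 <- sample(1:5, 1); k2 <- sample(1:5, 1)
    tab <- rbind(base * k1, base * k2)
    expect_equal(fisher_two_sided(tab), 1)
  }
})

test_that("specificity calls find constructed enrichment with the oracle's p-value", {
  sch <- tiny_schema()
  # alternative side seen only in nervous experiments, main side uniform
  d <- dplyr::bind_rows(
    spread_det("P_A1", "EV1", "alternative", c("cortex", "retina"), 3),
    spread_det("P_A2", "EV1", "alternative", c("cortex", "retina"), 3),
    spread_det("P_M", "EV1", "main", sch$tissue, 2),
    spread_det("P_I", "EV1", "intersect", sch$tissue, 2)
  )
  prof <- build_ped_profile(d, sch)
  calls <- call_specificity(prof, unit_level = "group")
  hit <- dplyr::filter(calls, unit == "nervous", comparison == "main_vs_alt")
  # oracle: main 4 of 8 PEDs in nervous, alternative 12 of 12
  expect_equal(hit$p_value, oracle_fisher(4, 4, 12, 0), tolerance = 1e-12)
  expect_true(hit$significant)
  expect_equal(hit$enriched_side, "alternative")
  expect_equal(hit$direction, "enriched")

  # identical side distributions: no significant call at any unit
  d2 <- dplyr::bind_rows(
    spread_det("Q_A", "EV2", "alternative", sch$tissue, 2, gene = "G2"),
    spread_det("Q_M", "EV2", "main", sch$tissue, 2, gene = "G2")
  )
  calls2 <- call_specificity(build_ped_profile(d2, sch))
  expect_false(any(calls2$significant))

  expect_error(call_specificity(prof, alpha = 0),
               class = "splicepeds_invalid_parameter")
})

test_that("both sides of one event can be enriched in different groups", {
  # FYN-like pattern: alternative in nervous, main concentrated elsewhere
  sch <- tiny_schema()
  d <- dplyr::bind_rows(
    spread_det("P_A", "EV1", "alternative", c("cortex", "retina"), 3),
    spread_det("P_M", "EV1", "main", c("colon", "pancreas"), 3),
    spread_det("P_I", "EV1", "intersect", sch$tissue, 3)
  )
  calls <- call_specificity(build_ped_profile(d, sch), unit_level = "group") |>
    dplyr::filter(comparison == "main_vs_alt", significant)
  expect_setequal(calls$unit, c("nervous", "digestive"))
  expect_setequal(calls$enriched_side, c("alternative", "main"))
})

test_that("null simulations keep the significant fraction below alpha", {
  sch <- uniform_schema(6, 2, 3)
  sim <- simulate_cohort(simulation_config(
    n_events = 120, schema = sch,
    transcript_groups = unique(sch$group),
    fraction_specific = 0, psi_background = 0.4, psi_target = 0.4,
    p_detect = 0.6, seed = 99
  ))
  prof <- normalize_sides(build_ped_profile(sim$detections, sch))
  prof <- dplyr::filter(prof, event_id %in% filter_events(prof))
  calls <- call_specificity(prof, unit_level = "group",
                            comparisons = "main_vs_alt")
  expect_lte(mean(calls$p_value < 0.05), 0.08)
})

test_that("Benjamini-Hochberg correction is at least as strict as none", {
  sch <- tiny_schema()
  d <- dplyr::bind_rows(
    spread_det("P_A", "EV1", "alternative", c("cortex", "retina"), 3),
    spread_det("P_M", "EV1", "main", sch$tissue, 2),
    spread_det("Q_A", "EV2", "alternative", "colon", 2, gene = "G2"),
    spread_det("Q_M", "EV2", "main", sch$tissue, 1, gene = "G2")
  )
  prof <- build_ped_profile(d, sch)
  raw <- call_specificity(prof, correction = "none")
  adj <- call_specificity(prof, correction = "bh")
  expect_true(all(adj$significant <= raw$significant))
})
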