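mk_call <- function(event, unit, side = "alternative", sig = TRUE,
                    dir = "enriched", kind = "group") {
  tibble::tibble(event_id = event, unit_kind = kind, unit = unit,
                 comparison = "main_vs_alt", p_value = ifelse(sig, 0.001, 0.5),
                 significant = sig, enriched_side = ifelse(sig, side, "none"),
                 direction = ifelse(sig, dir, NA_character_))
}

test_that("PGE cases admit only enriched, group-level, shared-group calls", {
  calls <- dplyr::bind_rows(
    mk_call("EV1", "nervous"),                       # case
    mk_call("EV1", "muscle"),                        # second case, same event
    mk_call("EV2", "blood", side = "main"),          # blood: excluded
    mk_call("EV3", "digestive", dir = "depleted"),   # depleted: excluded
    mk_call("EV4", "frontal_cortex", kind = "tissue"),  # tissue level only
    mk_call("EV5", "nervous", sig = FALSE)           # not significant
  )
  pge <- build_pge_cases(calls)
  expect_equal(nrow(pge), 2)
  expect_setequal(pge$group, c("nervous", "muscle"))
  expect_equal(unique(pge$event_id), "EV1")

  # FYN-like: alternative enriched in nervous counts once; main side in blood
  # does not add a second case
  fyn <- dplyr::bind_rows(mk_call("FYN", "nervous", side = "alternative"),
                          mk_call("FYN", "blood", side = "main"))
  expect_equal(nrow(build_pge_cases(fyn)), 1)
})

test_that("percent support uses the side's own total as denominator", {
  counts <- tibble::tibble(unit = c("nervous", "other", "nervous", "other"),
                           side = c("alternative", "alternative",
                                    "main", "main"),
                           ped = c(5L, 0L, 3L, 9L))
  expect_equal(pct_support(counts, "alternative", "nervous"), 100)
  expect_equal(pct_support(counts, "main", "nervous"), 25)
  counts0 <- dplyr::mutate(counts, ped = 0L)
  expect_error(pct_support(counts0, "main", "nervous"),
               class = "splicepeds_undefined_support")
})

test_that("concordance summaries count per group and overall", {
  tcalls <- dplyr::bind_rows(
    tibble::tibble(event_id = paste0("N", 1:4), group = "nervous",
                   z_main = -2, z_alt = 2, enriched_side = "alternative"),
    tibble::tibble(event_id = paste0("D", 1:4), group = "digestive",
                   z_main = 2, z_alt = -2, enriched_side = "main"),
    tibble::tibble(event_id = "X1", group = "nervous", z_main = 0, z_alt = 0,
                   enriched_side = "none")
  )
  pge <- tibble::tibble(event_id = c("N1", "N2", "N3", "D1", "Z9"),
                        group = c(rep("nervous", 3), "digestive", "nervous"),
                        enriched_side = "alternative")
  cs <- concordance_summary(pge, tcalls)
  expect_equal(cs$by_group$n_transcript,
               c(digestive = 4L, nervous = 4L)[cs$by_group$group],
               ignore_attr = TRUE)
  expect_equal(cs$by_group$n_concordant[cs$by_group$group == "nervous"], 3L)
  expect_equal(cs$by_group$n_concordant[cs$by_group$group == "digestive"], 1L)
  expect_equal(cs$overall$n_pge, 5L)
  expect_equal(cs$overall$fraction, 4 / 5)
  # concordance is invariant to input ordering
  cs2 <- concordance_summary(pge[sample(nrow(pge)), ],
                             tcalls[sample(nrow(tcalls)), ])
  expect_equal(cs$overall, cs2$overall)

  # matching sides too drops the main-side digestive case
  cs3 <- concordance_summary(pge, tcalls, match_side = TRUE)
  expect_equal(cs3$overall$n_concordant, 3L)

  # identical proportions between groups give p = 1 on proportional tables
  tc_same <- dplyr::bind_rows(
    tibble::tibble(event_id = paste0("A", 1:4), group = "nervous",
                   z_main = -2, z_alt = 2, enriched_side = "alternative"),
    tibble::tibble(event_id = paste0("B", 1:8), group = "muscle",
                   z_main = -2, z_alt = 2, enriched_side = "alternative")
  )
  pge_same <- tibble::tibble(event_id = c("A1", "A2", "B1", "B2", "B3", "B4"),
                             group = c("nervous", "nervous",
                                       rep("muscle", 4)),
                             enriched_side = "alternative")
  cs4 <- concordance_summary(pge_same, tc_same)
  expect_equal(cs4$pairwise$p_value, 1)
})

test_that("support points pair PED and read percentages and drop undefined sides", {
  sch <- tiny_schema()
  d <- dplyr::bind_rows(
    spread_det("P_A", "EV1", "alternative", c("cortex", "retina"), 3),
    spread_det("P_M", "EV1", "main", sch$tissue, 2)
  )
  prof <- build_ped_profile(d, sch)
  reads <- dplyr::bind_rows(
    tibble::tibble(event_id = "EV1", group = c("nervous", "digestive"),
                   side = "alternative", reads = c(90, 10)),
    tibble::tibble(event_id = "EV1", group = c("nervous", "digestive"),
                   side = "main", reads = c(20, 80))
  )
  tcalls <- call_transcript_enrichment(transcript_z(reads))
  pts <- support_points(prof, reads, tcalls)
  expect_true(all(pts$pct_ped >= 0 & pts$pct_ped <= 100))
  enr <- pts[pts$role == "enriched" & pts$group == "nervous", ]
  expect_equal(enr$side, "alternative")
  expect_equal(enr$pct_ped, 100)  # all alternative PEDs are nervous
  expect_equal(enr$pct_reads, 90)

  # a side with zero PED total is excluded, not scored as 0
  d2 <- spread_det("Q_M", "EV2", "main", sch$tissue, 2, gene = "G2")
  prof2 <- build_ped_profile(d2, sch)
  reads2 <- dplyr::mutate(reads, event_id = "EV2")
  pts2 <- support_points(prof2, reads2,
                         call_transcript_enrichment(transcript_z(reads2)))
  expect_false(any(pts2$side == "alternative"))
})

test_that("support correlations behave on exact and noisy strata", {
  pts <- tibble::tibble(group = "nervous", pct_ped = c(10, 40, 90, 100),
                        pct_reads = c(10, 40, 90, 100))
  expect_equal(support_correlation(pts)$r, 1)
  anti <- dplyr::mutate(pts, pct_reads = 100 - pct_ped)
  expect_equal(support_correlation(anti)$r, -1)
  const <- dplyr::mutate(pts, pct_ped = 50)
  expect_error(support_correlation(const),
               class = "splicepeds_undefined_correlation")
  # strata smaller than the minimum are dropped
  small <- pts[1:2, ]
  expect_equal(nrow(support_correlation(small)), 0)

  # heavy noise on one axis lowers |r| relative to the clean stratum
  withr::with_seed(31, {
    x <- runif(60, 0, 100)
    clean <- tibble::tibble(group = "clean", pct_ped = x,
                            pct_reads = pmin(100, pmax(0, x + rnorm(60, 0, 2))))
    noisy <- tibble::tibble(group = "noisy", pct_ped = x,
                            pct_reads = pmin(100, pmax(0, x + rnorm(60, 0, 45))))
    rr <- support_correlation(dplyr::bind_rows(clean, noisy))
    expect_gt(rr$r[rr$stratum == "clean"], rr$r[rr$stratum == "noisy"])
  })
})
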