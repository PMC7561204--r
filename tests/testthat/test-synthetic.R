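small_cfg <- function(seed, ...) {
  sch <- uniform_schema(4, 2, 3)
  simulation_config(n_events = 30, schema = sch,
                    transcript_groups = c(unique(sch$group), "skin"),
                    seed = seed, ...)
}

test_that("simulation is deterministic in the seed and validates its config", {
  s1 <- simulate_cohort(small_cfg(101))
  s2 <- simulate_cohort(small_cfg(101))
  expect_equal(s1$detections, s2$detections)
  expect_equal(s1$reads, s2$reads)
  expect_equal(s1$truth, s2$truth)
  s3 <- simulate_cohort(small_cfg(102))
  expect_false(identical(s1$detections, s3$detections))

  expect_error(simulation_config(n_events = 5),
               class = "splicepeds_config_error")          # seed mandatory
  expect_error(small_cfg(1, p_detect = 1.4),
               class = "splicepeds_config_error")
  expect_error(small_cfg(1, psi_background = 0.5, psi_target = 0.5),
               class = "splicepeds_config_error")
})

test_that("simulated tables pass every module's ingest validation", {
  sim <- simulate_cohort(small_cfg(7))
  expect_silent(validate_detection_table(sim$detections, sim$schema))
  expect_silent(validate_event_table(sim$events))
  expect_s3_class(build_ped_profile(sim$detections, sim$schema), "tbl_df")
  expect_s3_class(transcript_z(sim$reads, groups = sim$transcript_groups),
                  "tbl_df")
  expect_s3_class(disorder_calls(sim$scores), "tbl_df")
  if (nrow(sim$homology)) expect_s3_class(estimate_age(sim$homology), "tbl_df")
  # events have exactly one mechanism and one effect from the vocabularies
  expect_true(all(sim$events$mechanism %in% splice_mechanisms()))
  expect_true(all(sim$events$effect %in% effect_classes()))
})

test_that("expected PED counts track detection probability and experiments", {
  # with usage equal everywhere, E[PEDs] = n_experiments * p_detect * usage
  sch <- uniform_schema(4, 2, 3)  # 24 experiments
  cfg <- simulation_config(n_events = 150, schema = sch,
                           transcript_groups = unique(sch$group),
                           fraction_specific = 0, psi_background = 0.25,
                           psi_target = 0.25, p_detect = 0.6, seed = 55)
  sim <- simulate_cohort(cfg)
  tot <- ped_totals(build_ped_profile(sim$detections, sch))
  mean_alt <- mean(tot$total[tot$side == "alternative"])
  mean_main <- mean(tot$total[tot$side == "main"])
  expect_equal(mean_alt, 24 * 0.6 * 0.25, tolerance = 0.12)
  expect_equal(mean_main, 24 * 0.6 * 0.75, tolerance = 0.06)
})

test_that("read totals scale linearly with the expression parameter", {
  base <- simulate_cohort(small_cfg(77, fraction_specific = 0,
                                    psi_target = 0.3, psi_background = 0.2,
                                    read_mean = 50, read_dispersion = 1e9))
  high <- simulate_cohort(small_cfg(77, fraction_specific = 0,
                                    psi_target = 0.3, psi_background = 0.2,
                                    read_mean = 200, read_dispersion = 1e9))
  ratio <- sum(high$reads$reads) / sum(base$reads$reads)
  expect_equal(ratio, 4, tolerance = 0.05)
})

test_that("recovery reports score calls against the truth", {
  sch <- uniform_schema(6, 2, 3)
  cfg <- simulation_config(n_events = 80, schema = sch,
                           transcript_groups = unique(sch$group),
                           fraction_specific = 0.5, psi_background = 0.05,
                           psi_target = 0.95, p_detect = 0.95,
                           read_dispersion = 1e9, seed = 13)
  sim <- simulate_cohort(cfg)
  prof <- normalize_sides(build_ped_profile(sim$detections, sch))
  prof <- dplyr::filter(prof, event_id %in% filter_events(prof))
  calls <- call_specificity(prof, unit_level = "group")
  tcalls <- call_transcript_enrichment(
    transcript_z(sim$reads, groups = sim$transcript_groups))
  rep <- recovery_report(sim$truth, protein_calls = calls,
                         transcript_calls = tcalls,
                         age_estimates = estimate_age(sim$homology),
                         disorder = disorder_calls(sim$scores))
  # near-perfect information: everything close to the limit
  expect_gt(rep$sensitivity[rep$stage == "protein_group"], 0.9)
  expect_gt(rep$sensitivity[rep$stage == "transcript_group"], 0.95)
  expect_equal(rep$accuracy[rep$stage == "age_bin"], 1)
  expect_gte(rep$accuracy[rep$stage == "disorder"], 0.95)

  # shuffled truth labels drop recovery to chance
  shuffled <- sim$truth
  withr::with_seed(2, {
    shuffled$target_group <- sample(shuffled$target_group)
  })
  rep2 <- recovery_report(shuffled, protein_calls = calls)
  expect_lt(rep2$sensitivity[rep2$stage == "protein_group"],
            rep$sensitivity[rep$stage == "protein_group"])

  # calls for unknown events are a join error
  rogue <- dplyr::mutate(calls, event_id = paste0("zz_", event_id))
  expect_error(recovery_report(sim$truth, protein_calls = rogue),
               class = "splicepeds_join_error")
})
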