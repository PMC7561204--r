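#' Configure a synthetic splicing cohort
#'
#' Defines the stated world the simulator draws from: a replicate proteomics
#' cohort (default: the 30-tissue / 79-experiment / 10-group reference
#' layout), a 12-group transcriptomics cohort, and per-event ground truth for
#' tissue specificity, evolutionary age and disorder. Isoform usage is
#' parameterised by the alternative side's inclusion probability: psi_background
#' everywhere, raised to psi_target in the target group of truly specific
#' events (the main side takes the complement). Peptide detection is
#' presence/absence Bernoulli per experiment with probability
#' `p_detect * usage`; junction reads are negative binomial with mean
#' proportional to usage.
#'
#' @param n_events Number of splice events (default 255, the size of the
#'   reference event set).
#' @param schema Proteomics tissue schema (default
#'   [reference_proteomics_schema()]).
#' @param transcript_groups Transcriptomics group labels (default
#'   [reference_transcript_groups()]).
#' @param fraction_specific Fraction of events that are truly tissue-group
#'   specific (default 95/255, the reference tissue-specific fraction).
#' @param target_groups Groups a specific event may be enriched in; default:
#'   the groups shared between the two cohorts.
#' @param psi_background Background inclusion probability of the alternative
#'   side (default 0.2: the alternative isoform is the minor form).
#' @param psi_target Inclusion probability of the alternative side in the
#'   target group of specific events (default 0.8).
#' @param p_detect Probability that an expressed discriminating peptide is
#'   detected in one experiment (default 0.5, a realistic label-free
#'   detection rate for moderately abundant proteins).
#' @param n_intersect_peptides Non-discriminating peptides per gene
#'   (default 2).
#' @param read_mean Mean junction reads per group for a fully used side
#'   (default 100).
#' @param read_dispersion Negative-binomial size parameter (default 5;
#'   values >= 1e8 switch to Poisson, i.e. the vanishing-noise limit).
#' @param fraction_disordered Fraction of events whose region is truly
#'   disordered (default 0.4, matching the enrichment of disorder among
#'   translated alternative exons).
#' @param age_probs Named probabilities over [age_bins()] (default: the
#'   age mix observed in the reference event set -- mostly ancient).
#' @param seed Mandatory integer seed.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_events = 255,
                              schema = reference_proteomics_schema(),
                              transcript_groups = reference_transcript_groups(),
                              fraction_specific = 95 / 255,
                              target_groups = NULL,
                              psi_background = 0.2,
                              psi_target = 0.8,
                              p_detect = 0.5,
                              n_intersect_peptides = 2,
                              read_mean = 100,
                              read_dispersion = 5,
                              fraction_disordered = 0.4,
                              age_probs = c(primate = 0.078, theria = 0.152,
                                            tetrapoda = 0.25, ancient = 0.52),
                              seed) {
  if (missing(seed) || is.null(seed)) {
    rlang::abort("a seed is mandatory for reproducible simulation",
                 class = "splicepeds_config_error")
  }
  schema <- validate_tissue_schema(schema)
  probs <- c(fraction_specific, psi_background, psi_target, p_detect,
             fraction_disordered)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("probabilities must lie in [0, 1]",
                 class = "splicepeds_config_error")
  }
  if (fraction_specific > 0 && psi_target == psi_background) {
    rlang::abort("psi_target must differ from psi_background when specific events are simulated",
                 class = "splicepeds_config_error")
  }
  if (is.null(target_groups)) {
    target_groups <- intersect(unique(schema$group), transcript_groups)
  }
  if (fraction_specific > 0 && !length(target_groups)) {
    rlang::abort("no admissible target groups shared by the two cohorts",
                 class = "splicepeds_config_error")
  }
  if (!all(names(age_probs) %in% age_bins()) ||
      abs(sum(age_probs) - 1) > 0.05) {
    rlang::abort("age_probs must be (near-)normalised over the age bins",
                 class = "splicepeds_config_error")
  }
  structure(list(
    n_events = as.integer(n_events), schema = schema,
    transcript_groups = transcript_groups,
    fraction_specific = fraction_specific, target_groups = target_groups,
    psi_background = psi_background, psi_target = psi_target,
    p_detect = p_detect,
    n_intersect_peptides = as.integer(n_intersect_peptides),
    read_mean = read_mean, read_dispersion = read_dispersion,
    fraction_disordered = fraction_disordered,
    age_probs = age_probs / sum(age_probs),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# sample() without the scalar-x surprise
resample <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

# Overdispersed counts; huge size means the Poisson (no-overdispersion) limit
rcounts <- function(n, mu, size) {
  if (is.infinite(size) || size >= 1e8) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate a full splicing cohort with known ground truth
#'
#' Draws events (mechanism, side lengths, effect via [classify_effect()]),
#' peptide detections per replicate experiment, junction reads per
#' transcriptomics group, per-residue disorder scores, and homology hits,
#' all consistent with a per-event ground truth. The same seed yields
#' identical output.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `truth`, `events`, `detections`, `reads`,
#'   `scores`, `homology`, `schema`, `transcript_groups`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_events
  schema <- config$schema
  event_id <- sprintf("EV%04d", seq_len(n))
  gene_id <- sprintf("G%04d", seq_len(n))

  ## --- events -------------------------------------------------------------
  mech_probs <- c(skipped_exon = 0.365, alt_3_splice_site = 0.145,
                  alt_5_splice_site = 0.10, mutually_exclusive = 0.12,
                  alt_promoter = 0.135, alt_polyA = 0.135)
  mechanism <- resample(names(mech_probs), n, prob = mech_probs)

  side_a <- integer(n); side_b <- integer(n)
  position <- rep("internal", n)
  homologous <- rep(FALSE, n)
  shares <- rep(TRUE, n)

  idx <- mechanism == "skipped_exon"
  side_a[idx] <- 0L
  side_b[idx] <- resample(5:60, sum(idx))
  idx <- mechanism %in% c("alt_3_splice_site", "alt_5_splice_site")
  micro <- idx & stats::runif(n) < 0.5
  side_a[idx] <- 0L
  side_b[micro] <- resample(1:3, sum(micro))
  side_b[idx & !micro] <- resample(4:30, sum(idx & !micro))
  idx <- mechanism == "mutually_exclusive"
  side_a[idx] <- resample(10:60, sum(idx))
  side_b[idx] <- resample(10:60, sum(idx))
  homologous[idx] <- stats::runif(n)[idx] < 0.5
  idx <- mechanism == "alt_promoter"
  side_a[idx] <- resample(8:80, sum(idx))
  side_b[idx] <- resample(8:80, sum(idx))
  position[idx] <- "n_term"
  homologous[idx] <- stats::runif(n)[idx] < 0.2
  shares[idx] <- stats::runif(n)[idx] > 0.04
  idx <- mechanism == "alt_polyA"
  side_a[idx] <- resample(8:80, sum(idx))
  side_b[idx] <- resample(8:80, sum(idx))
  position[idx] <- "c_term"
  homologous[idx] <- stats::runif(n)[idx] < 0.2
  shares[idx] <- stats::runif(n)[idx] > 0.04

  effect <- classify_effect(side_a, side_b, position, shares, homologous)

  specific <- stats::runif(n) < config$fraction_specific
  target_group <- rep(NA_character_, n)
  target_group[specific] <- resample(config$target_groups, sum(specific))
  age_bin <- resample(names(config$age_probs), n, prob = config$age_probs)
  disordered <- stats::runif(n) < config$fraction_disordered

  region_len_1 <- pmax(side_a, side_b)  # indels: the inserted segment
  region_len_2 <- ifelse(effect %in% c("indel", "micro_indel"),
                         NA_integer_, pmin(side_a, side_b))

  truth <- tibble::tibble(
    event_id, gene_id, mechanism, effect,
    specific, target_group, enriched_side = ifelse(specific, "alternative",
                                                   NA_character_),
    age_bin, age_eligible = eligible_exon(3L * region_len_1),
    disordered,
    region_len_1, region_len_2,
    disorder_excluded = region_len_1 <= 4
  )

  events <- tibble::tibble(
    event_id, gene_id, mechanism, effect,
    side_a_len = side_a, side_b_len = side_b,
    homologous_flag = homologous, age_label = NA_character_
  )

  ## --- proteomics detections ----------------------------------------------
  exps <- schema |>
    tidyr::uncount(.data$n_experiments, .remove = FALSE) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::mutate(experiment_id = paste0(.data$tissue, "_e",
                                         dplyr::row_number())) |>
    dplyr::ungroup()

  usage <- tidyr::expand_grid(event_id = event_id,
                              group = unique(schema$group)) |>
    dplyr::left_join(truth[, c("event_id", "specific", "target_group")],
                     by = "event_id") |>
    dplyr::mutate(
      u_alt = ifelse(.data$specific & .data$group == .data$target_group &
                       !is.na(.data$target_group),
                     config$psi_target, config$psi_background),
      u_main = 1 - .data$u_alt
    )

  grid <- tidyr::expand_grid(
    event_id = event_id,
    exps[, c("experiment_id", "tissue", "group")]
  ) |>
    dplyr::left_join(usage[, c("event_id", "group", "u_alt", "u_main")],
                     by = c("event_id", "group"))

  ng <- nrow(grid)
  draw_side <- function(u, tag, side) {
    hit <- stats::rbinom(ng, 1, config$p_detect * u) == 1
    if (!any(hit)) return(NULL)
    tibble::tibble(
      peptide = paste0(grid$event_id[hit], "_", tag),
      event_id = grid$event_id[hit], side = side,
      experiment_id = grid$experiment_id[hit], tissue = grid$tissue[hit]
    )
  }
  det <- list(draw_side(grid$u_main, "M", "main"),
              draw_side(grid$u_alt, "A", "alternative"))
  for (j in seq_len(config$n_intersect_peptides)) {
    det[[length(det) + 1]] <-
      draw_side(rep(1, ng), paste0("I", j), "intersect")
  }
  detections <- dplyr::bind_rows(det)
  if (nrow(detections)) {
    detections$gene_id <- gene_id[match(detections$event_id, event_id)]
    detections <- detections |>
      dplyr::select("peptide", "gene_id", "event_id", "side",
                    "experiment_id", "tissue") |>
      dplyr::arrange(.data$peptide, .data$experiment_id)
  } else {
    detections <- tibble::tibble(peptide = character(), gene_id = character(),
                                 event_id = character(), side = character(),
                                 experiment_id = character(),
                                 tissue = character())
  }

  ## --- junction reads -----------------------------------------------------
  rgrid <- tidyr::expand_grid(event_id = event_id,
                              group = config$transcript_groups) |>
    dplyr::left_join(truth[, c("event_id", "specific", "target_group")],
                     by = "event_id") |>
    dplyr::mutate(u_alt = ifelse(.data$specific &
                                   .data$group == .data$target_group &
                                   !is.na(.data$target_group),
                                 config$psi_target, config$psi_background))
  nr <- nrow(rgrid)
  reads <- dplyr::bind_rows(
    tibble::tibble(event_id = rgrid$event_id, group = rgrid$group,
                   side = "main",
                   reads = rcounts(nr, config$read_mean * (1 - rgrid$u_alt),
                                   config$read_dispersion)),
    tibble::tibble(event_id = rgrid$event_id, group = rgrid$group,
                   side = "alternative",
                   reads = rcounts(nr, config$read_mean * rgrid$u_alt,
                                   config$read_dispersion)),
    tibble::tibble(event_id = rgrid$event_id, group = rgrid$group,
                   side = "intersect",
                   reads = rcounts(nr, config$read_mean,
                                   config$read_dispersion))
  ) |>
    dplyr::arrange(.data$event_id, .data$group, .data$side)

  ## --- disorder scores ----------------------------------------------------
  score_one <- function(len, dis) {
    if (is.na(len) || len == 0) return(NULL)
    if (dis) stats::rbeta(len, 8, 2) else stats::rbeta(len, 2, 8)
  }
  scores <- lapply(seq_len(n), function(i) {
    r1 <- score_one(region_len_1[i], disordered[i])
    r2 <- score_one(region_len_2[i], FALSE)
    rows <- list()
    if (!is.null(r1)) {
      rows$r1 <- tibble::tibble(event_id = event_id[i], region_id = "r1",
                                position = seq_along(r1), score = r1)
    }
    if (!is.null(r2)) {
      rows$r2 <- tibble::tibble(event_id = event_id[i], region_id = "r2",
                                position = seq_along(r2), score = r2)
    }
    dplyr::bind_rows(rows)
  })
  scores <- dplyr::bind_rows(scores)

  ## --- homology hits ------------------------------------------------------
  ladder <- clade_ladder()
  bin_ranks <- list(primate = 1L, theria = 2:4, tetrapoda = 5L,
                    ancient = 6:7)
  hom <- lapply(seq_len(n), function(i) {
    if (!truth$age_eligible[i]) return(NULL)
    r_final <- resample(bin_ranks[[age_bin[i]]], 1)
    r_other <- resample(r_final:7, 1)
    rmode <- if (stats::runif(1) < 0.5) c(r_final, r_other)
    else c(r_other, r_final)
    modes <- c("exon_only", "exon_plus_flanks")
    rows <- lapply(1:2, function(m) {
      rk <- sort(unique(c(rmode[m], resample(seq_len(rmode[m]), 2))))
      hit <- tibble::tibble(exon_id = event_id[i], mode = modes[m],
                            hit_clade = ladder[rk],
                            insertions = resample(0:3, length(rk)))
      if (rmode[m] < 7 && stats::runif(1) < 0.7) {
        # a distant near-miss the insertion filter must reject
        hit <- dplyr::bind_rows(hit, tibble::tibble(
          exon_id = event_id[i], mode = modes[m],
          hit_clade = ladder[rmode[m] + 1L],
          insertions = resample(4:9, 1)
        ))
      }
      hit
    })
    dplyr::bind_rows(rows)
  })
  homology <- dplyr::bind_rows(hom)
  if (nrow(homology)) {
    homology$hit_species <- paste0("sp_", homology$hit_clade)
    homology <- homology[, c("exon_id", "mode", "hit_species", "hit_clade",
                             "insertions")]
  } else {
    homology <- tibble::tibble(exon_id = character(), mode = character(),
                               hit_species = character(),
                               hit_clade = character(),
                               insertions = integer())
  }

  list(truth = truth, events = events, detections = detections,
       reads = reads, scores = scores, homology = homology,
       schema = schema, transcript_groups = config$transcript_groups,
       config = config)
}

#' Score pipeline calls against simulation ground truth
#'
#' Confusion-matrix summaries per analysis stage. For protein and transcript
#' calls, sensitivity is the fraction of truly specific events (among those
#' present in the calls) detected as significant/enriched in their true
#' target group, and specificity the fraction of truly non-specific events
#' with no call in any group. Age and disorder stages report accuracy against
#' the truth labels.
#'
#' @param truth Ground-truth tibble from [simulate_cohort()].
#' @param protein_calls Output of [call_specificity()] (group level), or
#'   `NULL` to skip.
#' @param transcript_calls Output of [call_transcript_enrichment()], or
#'   `NULL`.
#' @param pge_cases Output of [build_pge_cases()], or `NULL`.
#' @param age_estimates Output of [estimate_age()], or `NULL`.
#' @param disorder Output of [disorder_calls()], or `NULL`.
#' @return Tibble with columns `stage`, `n`, `sensitivity`, `specificity`,
#'   `accuracy` (NA where not applicable).
#' @export
recovery_report <- function(truth, protein_calls = NULL,
                            transcript_calls = NULL, pge_cases = NULL,
                            age_estimates = NULL, disorder = NULL) {
  check_events <- function(ids, what) {
    extra <- setdiff(ids, truth$event_id)
    if (length(extra)) {
      rlang::abort(paste0(what, " contains events absent from the truth: ",
                          paste(utils::head(extra, 5), collapse = ", ")),
                   class = "splicepeds_join_error")
    }
  }

  # positives: (event_id, group) pairs called positive; tested: event ids the
  # stage actually evaluated
  call_stage <- function(stage, tested, positives) {
    tr <- truth[truth$event_id %in% tested, ]
    key <- paste(positives$event_id, positives$group)
    hit_target <- !is.na(tr$target_group) &
      paste(tr$event_id, tr$target_group) %in% key
    any_call <- tr$event_id %in% positives$event_id
    tibble::tibble(
      stage = stage, n = nrow(tr),
      sensitivity = if (any(tr$specific)) mean(hit_target[tr$specific])
                    else NA_real_,
      specificity = if (any(!tr$specific)) mean(!any_call[!tr$specific])
                    else NA_real_,
      accuracy = NA_real_
    )
  }

  rows <- list()
  if (!is.null(protein_calls)) {
    check_events(unique(protein_calls$event_id), "protein_calls")
    pos <- protein_calls |>
      dplyr::filter(.data$unit_kind == "group",
                    .data$comparison == "main_vs_alt", .data$significant) |>
      dplyr::transmute(event_id = .data$event_id, group = .data$unit)
    rows$protein <- call_stage("protein_group",
                               unique(protein_calls$event_id), pos)
  }
  if (!is.null(transcript_calls)) {
    check_events(unique(transcript_calls$event_id), "transcript_calls")
    pos <- transcript_calls |>
      dplyr::filter(.data$enriched_side != "none") |>
      dplyr::select("event_id", "group")
    rows$transcript <- call_stage("transcript_group",
                                  unique(transcript_calls$event_id), pos)
  }
  if (!is.null(pge_cases)) {
    check_events(unique(pge_cases$event_id), "pge_cases")
    tr <- truth[truth$specific, ]
    key <- paste(pge_cases$event_id, pge_cases$group)
    rows$pge <- tibble::tibble(
      stage = "pge", n = nrow(pge_cases),
      sensitivity = if (nrow(tr)) {
        mean(paste(tr$event_id, tr$target_group) %in% key)
      } else NA_real_,
      specificity = NA_real_, accuracy = NA_real_
    )
  }
  if (!is.null(age_estimates)) {
    check_events(unique(age_estimates$exon_id), "age_estimates")
    cmp <- dplyr::inner_join(
      age_estimates[!is.na(age_estimates$bin), c("exon_id", "bin")],
      truth[, c("event_id", "age_bin")],
      by = c(exon_id = "event_id")
    )
    rows$age <- tibble::tibble(
      stage = "age_bin", n = nrow(cmp),
      sensitivity = NA_real_, specificity = NA_real_,
      accuracy = if (nrow(cmp)) mean(cmp$bin == cmp$age_bin) else NA_real_
    )
  }
  if (!is.null(disorder)) {
    check_events(unique(disorder$event_id), "disorder")
    cmp <- disorder |>
      dplyr::filter(!.data$excluded) |>
      dplyr::inner_join(truth[, c("event_id", "disordered")],
                        by = "event_id", suffix = c("_call", "_truth"))
    rows$disorder <- tibble::tibble(
      stage = "disorder", n = nrow(cmp),
      sensitivity = NA_real_, specificity = NA_real_,
      accuracy = if (nrow(cmp)) {
        mean(cmp$disordered_call == cmp$disordered_truth)
      } else NA_real_
    )
  }
  dplyr::bind_rows(rows)
}
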