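#' Run the full tissue-specific splicing analysis
#'
#' Orders the analysis stages end to end: PED aggregation and the minimum-
#' support filter, side normalisation (most-evidence side becomes "main",
#' independently for proteomics and transcriptomics), one-unit-versus-rest
#' Fisher tests at tissue and group level, the one-standard-deviation
#' transcript rule, construction of the protein-group-enrichment (PGE) case
#' set and its transcript concordance, percent-support correlations, and
#' exon-age and disorder annotation. Stages whose inputs are absent are
#' skipped and marked as such in the summary. Outputs are deterministic:
#' stable row ordering and fixed float formatting.
#'
#' @param detections Peptide detection table (see
#'   [validate_detection_table()]).
#' @param schema Proteomics tissue schema.
#' @param events Optional event table (mechanism/effect classes and curated
#'   ages; see [validate_event_table()]).
#' @param reads Optional junction read table (`event_id`, `group`, `side`,
#'   `reads`).
#' @param scores Optional per-residue disorder score table.
#' @param homology Optional homology hit table.
#' @param transcript_groups Transcriptomics group labels (default
#'   [reference_transcript_groups()]).
#' @param alpha,correction,min_peds,sd_threshold Analysis parameters; see
#'   [call_specificity()], [filter_events()],
#'   [call_transcript_enrichment()].
#' @param exclude_groups Groups excluded from PGE construction
#'   (default `"blood"`).
#' @param outdir Optional directory; when given, all result tables are
#'   written as TSV plus a `summary.json` of the stage counts.
#' @return A list with the result tables (`ped_profile`, `retained_events`,
#'   `protein_calls`, `event_flags`, `transcript_calls`, `pge_cases`,
#'   `concordance`, `support_points`, `correlations`, `ages`, `disorder`)
#'   and a `summary` list of counts.
#' @export
run_pipeline <- function(detections, schema,
                         events = NULL, reads = NULL, scores = NULL,
                         homology = NULL,
                         transcript_groups = reference_transcript_groups(),
                         alpha = 0.05, correction = "none", min_peds = 3,
                         sd_threshold = 1, exclude_groups = "blood",
                         outdir = NULL) {
  schema <- validate_tissue_schema(schema)
  if (!is.null(events)) events <- validate_event_table(events)

  profile <- build_ped_profile(detections, schema) |>
    normalize_sides()
  n_events_in <- length(unique(profile$event_id))
  retained <- filter_events(profile, min_peds = min_peds)
  profile_kept <- dplyr::filter(profile, .data$event_id %in% retained)

  summary <- list(
    n_events_input = n_events_in,
    n_events_retained = length(retained),
    min_peds = min_peds, alpha = alpha
  )

  protein_calls <- NULL; event_flags <- NULL
  if (length(retained)) {
    protein_calls <- call_specificity(profile_kept, alpha = alpha,
                                      correction = correction)
    event_flags <- specific_events(protein_calls)
    summary$n_tissue_specific <- sum(event_flags$tissue_specific)
    summary$n_group_specific <- sum(event_flags$group_specific)
    summary$n_specific <- sum(event_flags$specific)
  } else {
    summary$n_tissue_specific <- 0L
    summary$n_group_specific <- 0L
    summary$n_specific <- 0L
  }

  transcript_calls <- NULL; zprof <- NULL
  if (!is.null(reads) && length(retained)) {
    reads_kept <- dplyr::filter(reads, .data$event_id %in% retained)
    if (nrow(reads_kept)) {
      zprof <- transcript_z(reads_kept, groups = transcript_groups)
      zprof <- normalize_read_sides(zprof)
      transcript_calls <- call_transcript_enrichment(zprof,
                                                     threshold = sd_threshold)
      tse <- transcript_specific_events(transcript_calls)
      summary$n_transcript_events <- nrow(tse)
      summary$n_transcript_specific <- sum(tse$transcript_specific)
    }
  }

  pge_cases <- NULL; concordance <- NULL
  points <- NULL; correlations <- NULL
  if (!is.null(protein_calls)) {
    shared <- intersect(unique(schema$group), transcript_groups)
    pge_cases <- build_pge_cases(protein_calls, shared_groups = shared,
                                 exclude_groups = exclude_groups)
    summary$n_pge_cases <- nrow(pge_cases)
    if (!is.null(transcript_calls)) {
      concordance <- concordance_summary(pge_cases, transcript_calls)
      summary$n_concordant <- concordance$overall$n_concordant
      summary$concordance_fraction <- concordance$overall$fraction
      points <- support_points(profile_kept, reads_kept, transcript_calls)
      correlations <- tryCatch(
        support_correlation(points),
        splicepeds_undefined_correlation = function(e) NULL
      )
    }
  }

  ages <- NULL
  auto_ages <- if (!is.null(homology) && nrow(homology)) {
    estimate_age(homology)
  } else NULL
  curated <- if (!is.null(events)) {
    events[, c("event_id", "age_label")]
  } else NULL
  if (!is.null(auto_ages) || !is.null(curated)) {
    ages <- combine_ages(auto_ages, curated)
    if (!is.null(ages) && nrow(ages)) summary$n_aged <- nrow(ages)
  }

  disorder <- NULL
  if (!is.null(scores) && nrow(scores)) {
    disorder <- disorder_calls(scores)
    summary$n_disorder_called <- sum(!disorder$excluded)
    summary$n_disorder_excluded <- sum(disorder$excluded)
  }

  res <- list(ped_profile = profile_kept, retained_events = retained,
              protein_calls = protein_calls, event_flags = event_flags,
              z_profile = zprof, transcript_calls = transcript_calls,
              pge_cases = pge_cases, concordance = concordance,
              support_points = points, correlations = correlations,
              ages = ages, disorder = disorder, summary = summary)

  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

# Relabel main/alternative in a transcript z profile so that "main" is the
# side with most reads overall, mirroring normalize_sides() for PEDs.
normalize_read_sides <- function(zprof) {
  totals <- zprof |>
    dplyr::filter(.data$side %in% c("main", "alternative")) |>
    dplyr::group_by(.data$event_id, .data$side) |>
    dplyr::summarise(total = sum(.data$reads), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "side", values_from = "total",
                       values_fill = 0)
  if (!"main" %in% names(totals)) totals$main <- 0
  if (!"alternative" %in% names(totals)) totals$alternative <- 0
  swap <- vapply(seq_len(nrow(totals)), function(i) {
    m <- totals$main[i]; a <- totals$alternative[i]
    if (m == 0 && a == 0) return(FALSE)
    assigned <- assign_sides(m, a, ids = c("main", "alternative"))
    unname(assigned["main"]) != "main"
  }, logical(1))
  swap_events <- totals$event_id[swap]
  dplyr::mutate(zprof, side = ifelse(
    .data$event_id %in% swap_events & .data$side != "intersect",
    ifelse(.data$side == "main", "alternative", "main"),
    .data$side
  ))
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    if (!is.null(x) && is.data.frame(x) && nrow(x) >= 0) {
      write_output_tsv(x, file.path(outdir, name))
    }
  }
  w(res$ped_profile, "ped_profile.tsv")
  w(res$protein_calls, "protein_calls.tsv")
  w(res$event_flags, "event_flags.tsv")
  w(res$transcript_calls, "transcript_calls.tsv")
  w(res$pge_cases, "pge_cases.tsv")
  if (!is.null(res$concordance)) {
    w(res$concordance$by_group, "concordance_by_group.tsv")
    w(res$concordance$pairwise, "concordance_pairwise.tsv")
  }
  w(res$support_points, "support_points.tsv")
  w(res$correlations, "correlations.tsv")
  w(res$ages, "ages.tsv")
  w(res$disorder, "disorder.tsv")
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
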