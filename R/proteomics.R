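#' Count peptide-experiment detections (PEDs)
#'
#' A PED count is the number of distinct experiments in which a peptide was
#' detected, the unit of protein-level evidence used throughout the package.
#' Label-free tissue proteomics with replicates supports presence/absence per
#' experiment but not reliable quantification, so evidence is counted, not
#' weighed: a peptide seen in every experiment of a 79-experiment cohort has
#' 79 PEDs, a peptide seen once has 1. Duplicate (peptide, experiment) rows
#' are collapsed before counting.
#'
#' @param detections Detection table with columns `peptide` and
#'   `experiment_id` (see [validate_detection_table()]).
#' @param peptide Optional single peptide sequence; if given, returns its PED
#'   count as an integer (0 when absent). Otherwise returns a tibble of PED
#'   counts for all peptides.
#' @return Integer scalar, or a tibble with columns `peptide`, `peds`.
#' @export
count_peds <- function(detections, peptide = NULL) {
  stopifnot(all(c("peptide", "experiment_id") %in% names(detections)))
  if (!is.null(peptide)) {
    stopifnot(length(peptide) == 1)
    hits <- detections$experiment_id[detections$peptide == peptide]
    return(length(unique(hits)))
  }
  detections |>
    dplyr::distinct(.data$peptide, .data$experiment_id) |>
    dplyr::count(.data$peptide, name = "peds") |>
    dplyr::arrange(.data$peptide)
}

#' Validate a peptide detection table
#'
#' Checks column presence, side labels, and tissue membership in the schema.
#' Peptides mapping to more than one gene are rejected: they cannot provide
#' unambiguous isoform evidence.
#'
#' @param detections Data frame with columns `peptide`, `gene_id`, `event_id`,
#'   `side`, `experiment_id`, `tissue`.
#' @param schema Optional tissue schema; when given, every detection tissue
#'   must appear in it.
#' @return The validated tibble.
#' @export
validate_detection_table <- function(detections, schema = NULL) {
  need <- c("peptide", "gene_id", "event_id", "side", "experiment_id",
            "tissue")
  miss <- setdiff(need, names(detections))
  if (length(miss)) {
    rlang::abort(paste("detection table is missing columns:",
                       paste(miss, collapse = ", ")),
                 class = "splicepeds_schema_error")
  }
  bad <- which(!detections$side %in% side_labels())
  if (length(bad)) {
    rlang::abort(paste0("invalid side label in detection rows: ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 class = "splicepeds_schema_error")
  }
  multi <- detections |>
    dplyr::distinct(.data$peptide, .data$gene_id) |>
    dplyr::count(.data$peptide) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi)) {
    rlang::abort(paste0("peptides mapping to more than one gene: ",
                        paste(utils::head(multi$peptide, 5), collapse = ", ")),
                 class = "splicepeds_schema_error")
  }
  if (!is.null(schema)) {
    bad <- which(!detections$tissue %in% schema$tissue)
    if (length(bad)) {
      rlang::abort(paste0("detection tissue outside schema in rows: ",
                          paste(utils::head(bad, 5), collapse = ", ")),
                   class = "splicepeds_schema_error")
    }
  }
  tibble::as_tibble(detections)
}

#' Aggregate detections into per-event PED profiles
#'
#' For every event, PEDs are split into three types -- those supporting the
#' main side, the alternative side, and those that do not discriminate the
#' isoforms (the intersect) -- and summed per tissue and per tissue group.
#' Group counts are sums over member tissues, so tissue-level and group-level
#' rows are consistent by construction. The grid is complete: every
#' (event, unit, side) combination appears, with zero where nothing was
#' detected.
#'
#' @param detections Detection table (validated against `schema`).
#' @param schema Tissue schema of the cohort.
#' @return A long tibble with columns `event_id`, `unit_kind`
#'   (`"tissue"`/`"group"`), `unit`, `side`, `ped`.
#' @export
build_ped_profile <- function(detections, schema) {
  schema <- validate_tissue_schema(schema)
  detections <- validate_detection_table(detections, schema)
  detections <- dplyr::filter(detections, !is.na(.data$event_id))

  counts <- detections |>
    dplyr::distinct(.data$event_id, .data$side, .data$tissue, .data$peptide,
                    .data$experiment_id) |>
    dplyr::count(.data$event_id, .data$side, .data$tissue, name = "ped")

  events <- sort(unique(counts$event_id))
  if (!length(events)) {
    return(tibble::tibble(event_id = character(), unit_kind = character(),
                          unit = character(), side = character(),
                          ped = integer()))
  }

  grid <- tidyr::expand_grid(event_id = events, side = side_labels(),
                             tissue = schema$tissue)
  tissue_level <- grid |>
    dplyr::left_join(counts, by = c("event_id", "side", "tissue")) |>
    dplyr::mutate(ped = dplyr::coalesce(.data$ped, 0L))

  group_level <- tissue_level |>
    dplyr::left_join(schema[, c("tissue", "group")], by = "tissue") |>
    dplyr::group_by(.data$event_id, .data$side, unit = .data$group) |>
    dplyr::summarise(ped = sum(.data$ped), .groups = "drop") |>
    dplyr::mutate(unit_kind = "group")

  tissue_level <- tissue_level |>
    dplyr::rename(unit = "tissue") |>
    dplyr::mutate(unit_kind = "tissue")

  dplyr::bind_rows(tissue_level, group_level) |>
    dplyr::select("event_id", "unit_kind", "unit", "side", "ped") |>
    dplyr::arrange(.data$event_id, .data$unit_kind, .data$unit, .data$side)
}

#' Per-event PED totals by side
#'
#' Totals are taken over tissue-level rows (group rows are sums of the same
#' detections and would double count).
#'
#' @param profile A PED profile from [build_ped_profile()].
#' @return Tibble with columns `event_id`, `side`, `total`.
#' @export
ped_totals <- function(profile) {
  profile |>
    dplyr::filter(.data$unit_kind == "tissue") |>
    dplyr::group_by(.data$event_id, .data$side) |>
    dplyr::summarise(total = sum(.data$ped), .groups = "drop")
}

#' Relabel event sides so that "main" carries the most PEDs
#'
#' Applies [assign_sides()] per event to the profile's side totals: the side
#' with strictly more PEDs becomes `main`; on a tie the lexicographically
#' smaller of the current labels does. Intersect rows are untouched.
#'
#' @param profile A PED profile.
#' @return The profile with `main`/`alternative` labels possibly swapped
#'   per event.
#' @export
normalize_sides <- function(profile) {
  totals <- ped_totals(profile) |>
    tidyr::pivot_wider(names_from = "side", values_from = "total",
                       values_fill = 0L)
  if (!"main" %in% names(totals)) totals$main <- 0L
  if (!"alternative" %in% names(totals)) totals$alternative <- 0L
  swap <- vapply(seq_len(nrow(totals)), function(i) {
    m <- totals$main[i]; a <- totals$alternative[i]
    if (m == 0 && a == 0) return(FALSE)  # undetermined: leave as provided
    assigned <- assign_sides(m, a, ids = c("main", "alternative"))
    unname(assigned["main"]) != "main"
  }, logical(1))
  swap_events <- totals$event_id[swap]
  dplyr::mutate(profile, side = ifelse(
    .data$event_id %in% swap_events & .data$side != "intersect",
    ifelse(.data$side == "main", "alternative", "main"),
    .data$side
  ))
}

#' Filter events by minimum PED support per side
#'
#' Tissue specificity cannot be assessed for events with almost no evidence,
#' so an event enters the analysis only if *each* of its two sides is
#' supported by at least `min_peds` peptide-experiment detections (default 3,
#' the threshold used to construct the reference event set).
#'
#' @param profile A PED profile from [build_ped_profile()].
#' @param min_peds Minimum PED total required on each side.
#' @return Character vector of retained event ids (sorted).
#' @export
filter_events <- function(profile, min_peds = 3) {
  stopifnot(min_peds >= 1)
  keep <- ped_totals(profile) |>
    dplyr::filter(.data$side %in% c("main", "alternative")) |>
    tidyr::pivot_wider(names_from = "side", values_from = "total",
                       values_fill = 0L)
  if (!"main" %in% names(keep)) keep$main <- 0L
  if (!"alternative" %in% names(keep)) keep$alternative <- 0L
  sort(keep$event_id[keep$main >= min_peds & keep$alternative >= min_peds])
}
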