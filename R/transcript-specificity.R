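#' Standardise junction read support across tissue groups
#'
#' For each event and side, junction reads are standardised across the
#' transcriptomics tissue groups: z = (reads - mean) / sd, with the mean and
#' (by default population) standard deviation taken over the groups for that
#' side's own read vector. A side with identical reads everywhere (sd = 0)
#' gets z = 0 in every group. Missing (event, group, side) combinations are
#' treated as zero reads.
#'
#' @param reads Tibble with columns `event_id`, `group`, `side`, `reads`.
#' @param groups Character vector of all transcriptomics groups (defaults to
#'   the groups present in `reads`). At least two are required.
#' @param sd_type `"population"` (divide by n; default) or `"sample"`
#'   (divide by n - 1).
#' @return Tibble with columns `event_id`, `group`, `side`, `reads`, `mean`,
#'   `sd`, `z`.
#' @export
transcript_z <- function(reads, groups = NULL,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  need <- c("event_id", "group", "side", "reads")
  miss <- setdiff(need, names(reads))
  if (length(miss)) {
    rlang::abort(paste("read table is missing columns:",
                       paste(miss, collapse = ", ")),
                 class = "splicepeds_schema_error")
  }
  if (any(reads$reads < 0, na.rm = TRUE)) {
    rlang::abort("read counts must be non-negative",
                 class = "splicepeds_schema_error")
  }
  if (is.null(groups)) groups <- sort(unique(reads$group))
  if (length(groups) < 2) {
    rlang::abort("standardisation needs at least two tissue groups",
                 class = "splicepeds_insufficient_groups")
  }
  bad <- setdiff(unique(reads$group), groups)
  if (length(bad)) {
    rlang::abort(paste0("read groups outside schema: ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 class = "splicepeds_schema_error")
  }

  n <- length(groups)
  ev_ids <- unique(reads$event_id)
  sides <- unique(reads$side)
  full <- reads |>
    dplyr::group_by(.data$event_id, .data$group, .data$side) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop") |>
    tidyr::complete(event_id = ev_ids, group = groups, side = sides,
                    fill = list(reads = 0)) |>
    dplyr::group_by(.data$event_id, .data$side) |>
    dplyr::mutate(
      mean = mean(.data$reads),
      sd = if (sd_type == "population") {
        sqrt(sum((.data$reads - mean(.data$reads))^2) / n)
      } else {
        stats::sd(.data$reads)
      },
      z = ifelse(.data$sd > 0, (.data$reads - .data$mean) / .data$sd, 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$event_id, .data$group, .data$side)
  full
}

#' Look up a single standardised read value
#'
#' @param zprofile Output of [transcript_z()].
#' @param event Event id.
#' @param side Side label.
#' @param group Tissue group.
#' @return The z value (numeric scalar).
#' @export
side_z <- function(zprofile, event, side, group) {
  hit <- zprofile$z[zprofile$event_id == event & zprofile$side == side &
                      zprofile$group == group]
  if (length(hit) != 1) {
    rlang::abort("no unique (event, side, group) entry in z profile",
                 class = "splicepeds_schema_error")
  }
  hit
}

#' Call transcript-level tissue-group enrichment (the SD rule)
#'
#' A tissue group is called enriched for one side of a splice event when that
#' side's standardised junction-read support in the group exceeds the other
#' side's by at least `threshold` standard deviations (default 1). At most
#' one side can win a group; an event with at least one enriched group is
#' tissue-group specific at the transcript level.
#'
#' @param zprofile Output of [transcript_z()]; must contain `main` and
#'   `alternative` rows.
#' @param threshold Minimum z difference (standard deviations).
#' @return Tibble with columns `event_id`, `group`, `z_main`, `z_alt`,
#'   `enriched_side` (`"main"`, `"alternative"` or `"none"`).
#' @export
call_transcript_enrichment <- function(zprofile, threshold = 1) {
  wide <- zprofile |>
    dplyr::filter(.data$side %in% c("main", "alternative")) |>
    tidyr::pivot_wider(id_cols = c("event_id", "group"),
                       names_from = "side", values_from = "z")
  if (!all(c("main", "alternative") %in% names(wide))) {
    rlang::abort("z profile must contain both main and alternative sides",
                 class = "splicepeds_schema_error")
  }
  wide |>
    dplyr::mutate(
      z_main = .data$main, z_alt = .data$alternative,
      enriched_side = dplyr::case_when(
        .data$z_main - .data$z_alt >= threshold ~ "main",
        .data$z_alt - .data$z_main >= threshold ~ "alternative",
        .default = "none"
      )
    ) |>
    dplyr::select("event_id", "group", "z_main", "z_alt", "enriched_side") |>
    dplyr::arrange(.data$event_id, .data$group)
}

#' Events with transcript-level group-specific splicing
#'
#' @param transcript_calls Output of [call_transcript_enrichment()].
#' @return Tibble with columns `event_id`, `transcript_specific`.
#' @export
transcript_specific_events <- function(transcript_calls) {
  transcript_calls |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      transcript_specific = any(.data$enriched_side != "none"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$event_id)
}

#' Heatmap-ready matrix of z differences
#'
#' @param zprofile Output of [transcript_z()].
#' @return Numeric matrix (events x groups) of `z_main - z_alternative`.
#' @export
z_diff_matrix <- function(zprofile) {
  calls <- call_transcript_enrichment(zprofile, threshold = Inf)
  wide <- calls |>
    dplyr::mutate(dz = .data$z_main - .data$z_alt) |>
    tidyr::pivot_wider(id_cols = "event_id", names_from = "group",
                       values_from = "dz")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$event_id
  m
}
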