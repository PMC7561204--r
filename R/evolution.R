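#' Ordered clade ladder and age bins
#'
#' Homology hits are recorded against an ordered ladder of clades, youngest
#' first. The ladder maps onto four categorical age bins: `primate` (up to
#' roughly 75 million years), `theria` (75-160 My; includes the
#' euarchontoglires and mammalia splits), `tetrapoda` (160-400 My, after the
#' sarcopterygii split) and `ancient` (over 400 My, before the ancestors of
#' lobe-finned fish). Bins are categorical throughout; no numeric dating is
#' attempted.
#'
#' @return `clade_ladder()`: character vector of clades, youngest to oldest.
#' @export
clade_ladder <- function() {
  c("primates", "euarchontoglires", "theria", "mammalia",
    "tetrapoda", "sarcopterygii", "vertebrata")
}

#' @rdname clade_ladder
#' @param clade Character vector of clade labels from [clade_ladder()].
#' @return `clade_bin()`: the age bin of each clade.
#' @export
clade_bin <- function(clade) {
  map <- c(primates = "primate",
           euarchontoglires = "theria", theria = "theria",
           mammalia = "theria",
           tetrapoda = "tetrapoda",
           sarcopterygii = "ancient", vertebrata = "ancient")
  bad <- setdiff(unique(clade[!is.na(clade)]), names(map))
  if (length(bad)) {
    rlang::abort(paste0("unknown clades: ", paste(bad, collapse = ", ")),
                 class = "splicepeds_invalid_input")
  }
  unname(map[clade])
}

#' Is an alternative exon long enough for automatic age estimation?
#'
#' Very short exons produce unreliable homology searches, so automatic age
#' estimation is restricted to exons of at least 42 bases.
#'
#' @param exon_length_bases Exon length(s) in nucleotides.
#' @return Logical vector.
#' @export
eligible_exon <- function(exon_length_bases) {
  if (any(exon_length_bases < 0, na.rm = TRUE)) {
    rlang::abort("exon lengths must be non-negative",
                 class = "splicepeds_invalid_input")
  }
  exon_length_bases >= 42
}

#' Should a homology hit be counted?
#'
#' Only homologous sequences with fewer than four residue insertions relative
#' to the query are accepted as evidence for the exon's presence in the hit
#' species.
#'
#' @param insertion_residues Number of residue insertions in the aligned
#'   homologue (vectorised).
#' @return Logical vector.
#' @export
accept_hit <- function(insertion_residues) {
  if (any(insertion_residues < 0, na.rm = TRUE)) {
    rlang::abort("insertion counts must be non-negative",
                 class = "splicepeds_invalid_input")
  }
  insertion_residues < 4
}

#' Estimate exon ages from homology-hit tables
#'
#' Homology searches are run in two modes: against the translated exon alone
#' (`exon_only`) and against the exon joined to its flanking exon(s)
#' (`exon_plus_flanks`). Within each mode the most distant clade among
#' accepted hits (fewer than four residue insertions) is that mode's
#' predicted age; the final age is the *minimum* (most recent) of the
#' per-mode predictions, and the age bin follows from the final clade.
#' An exon with no accepted hit in any mode is reported with `NA` age
#' (undetermined), never defaulted; an exon with hits in only one mode takes
#' that mode's age.
#'
#' @param hits Tibble with columns `exon_id`, `mode` (`"exon_only"` or
#'   `"exon_plus_flanks"`), `hit_clade` (from [clade_ladder()]), and
#'   `insertions`.
#' @return Tibble with columns `exon_id`, `age_exon_only`,
#'   `age_exon_plus_flanks`, `final_age`, `bin`.
#' @export
estimate_age <- function(hits) {
  need <- c("exon_id", "mode", "hit_clade", "insertions")
  miss <- setdiff(need, names(hits))
  if (length(miss)) {
    rlang::abort(paste("homology table is missing columns:",
                       paste(miss, collapse = ", ")),
                 class = "splicepeds_schema_error")
  }
  bad <- setdiff(unique(hits$mode), c("exon_only", "exon_plus_flanks"))
  if (length(bad)) {
    rlang::abort(paste0("unknown search modes: ",
                        paste(bad, collapse = ", ")),
                 class = "splicepeds_schema_error")
  }
  ladder <- clade_ladder()
  hits$rank <- match(hits$hit_clade, ladder)
  if (anyNA(hits$rank)) {
    rlang::abort("homology hits contain clades outside the ladder",
                 class = "splicepeds_schema_error")
  }

  accepted <- hits[accept_hit(hits$insertions), , drop = FALSE]
  per_mode <- accepted |>
    dplyr::group_by(.data$exon_id, .data$mode) |>
    dplyr::summarise(rank = if (dplyr::n()) max(.data$rank) else NA_integer_,
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "mode", values_from = "rank",
                       names_prefix = "rank_")
  for (col in c("rank_exon_only", "rank_exon_plus_flanks")) {
    if (!col %in% names(per_mode)) per_mode[[col]] <- NA_integer_
  }

  all_exons <- tibble::tibble(exon_id = sort(unique(hits$exon_id)))
  out <- dplyr::left_join(all_exons, per_mode, by = "exon_id")
  final_rank <- pmin(out$rank_exon_only, out$rank_exon_plus_flanks,
                     na.rm = TRUE)
  final_rank[is.na(out$rank_exon_only) &
               is.na(out$rank_exon_plus_flanks)] <- NA_integer_
  tibble::tibble(
    exon_id = out$exon_id,
    age_exon_only = ladder[out$rank_exon_only],
    age_exon_plus_flanks = ladder[out$rank_exon_plus_flanks],
    final_age = ladder[final_rank],
    bin = clade_bin(ladder[final_rank])
  )
}

#' Combine automatic age estimates with curated labels
#'
#' Curated (manually determined) event ages are authoritative where present;
#' automatic estimates fill the gaps and are flagged as such.
#'
#' @param automatic Output of [estimate_age()] (keyed on `exon_id`, taken to
#'   equal the event id), or `NULL`.
#' @param curated Tibble with columns `event_id` and `age_label` (an age bin
#'   or `NA`/`"unknown"`), or `NULL`.
#' @return Tibble with columns `event_id`, `bin`, `source`
#'   (`"curated"`/`"automatic"`), dropping events with no age from either
#'   source.
#' @export
combine_ages <- function(automatic = NULL, curated = NULL) {
  cur <- NULL
  if (!is.null(curated)) {
    cur <- curated |>
      dplyr::filter(!is.na(.data$age_label),
                    .data$age_label %in% age_bins()) |>
      dplyr::transmute(event_id = .data$event_id, bin = .data$age_label,
                       source = "curated")
  }
  auto <- NULL
  if (!is.null(automatic)) {
    auto <- automatic |>
      dplyr::filter(!is.na(.data$bin)) |>
      dplyr::transmute(event_id = .data$exon_id, bin = .data$bin,
                       source = "automatic")
  }
  out <- dplyr::bind_rows(cur, auto)
  if (is.null(out) || !nrow(out)) {
    return(tibble::tibble(event_id = character(), bin = character(),
                          source = character()))
  }
  out |>
    dplyr::group_by(.data$event_id) |>
    dplyr::slice(1) |>  # curated rows were bound first
    dplyr::ungroup() |>
    dplyr::arrange(.data$event_id)
}
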