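#' Build the protein-group-enrichment (PGE) case set
#'
#' A PGE case is one (event, tissue group) pair in which one side of the
#' event is significantly *enriched* at the protein level at the group level.
#' Calls that are only significant at the tissue level, calls in the
#' "depleted" direction (the gene's evidence is down in the group and one
#' side merely less so), and calls in groups without a transcriptomics
#' counterpart (by default blood) are excluded. An event enriched in several
#' admissible groups contributes one case per group.
#'
#' @param calls Output of [call_specificity()] (must include group-level
#'   main-vs-alt calls).
#' @param shared_groups Groups present in both the proteomics and the
#'   transcriptomics analysis (default [shared_tissue_groups()]).
#' @param exclude_groups Groups to drop even if listed as shared
#'   (default `"blood"`).
#' @return Tibble with columns `event_id`, `group`, `enriched_side`.
#' @export
build_pge_cases <- function(calls, shared_groups = shared_tissue_groups(),
                            exclude_groups = "blood") {
  admissible <- setdiff(shared_groups, exclude_groups)
  calls |>
    dplyr::filter(.data$unit_kind == "group",
                  .data$comparison == "main_vs_alt",
                  .data$significant,
                  .data$direction == "enriched",
                  .data$enriched_side %in% c("main", "alternative"),
                  .data$unit %in% admissible) |>
    dplyr::distinct(event_id = .data$event_id, group = .data$unit,
                    enriched_side = .data$enriched_side) |>
    dplyr::arrange(.data$event_id, .data$group)
}

#' Percentage of a side's evidence falling in one group
#'
#' The denominator is the side's own total across all units, so a side whose
#' evidence is entirely restricted to a group scores 100.
#'
#' @param counts Tibble with columns `unit` (or `group`), `side`, and a count
#'   column (`ped`, `reads` or `n`).
#' @param side Side label.
#' @param group Unit label.
#' @return Percentage in `[0, 100]`.
#' @export
pct_support <- function(counts, side, group) {
  if ("group" %in% names(counts) && !"unit" %in% names(counts)) {
    counts$unit <- counts$group
  }
  count_col <- intersect(c("ped", "reads", "n"), names(counts))[1]
  if (is.na(count_col)) {
    rlang::abort("counts must have a ped, reads or n column",
                 class = "splicepeds_schema_error")
  }
  x <- counts[counts$side == side, , drop = FALSE]
  total <- sum(x[[count_col]])
  if (total <= 0) {
    rlang::abort("side total is zero: percent support undefined",
                 class = "splicepeds_undefined_support")
  }
  100 * sum(x[[count_col]][x$unit == group]) / total
}

#' Percent-support points for transcript-enriched events
#'
#' For every (event, group) with a transcript-level enrichment call, computes
#' the percentage of PEDs and of junction reads that fall in that group, for
#' both the transcript-enriched side and the depleted side. Each side's
#' percentage uses that side's own total as denominator. Sides with a zero
#' total are undefined and are dropped, not recorded as zero.
#'
#' @param ped_profile A PED profile from [build_ped_profile()].
#' @param reads Read table (`event_id`, `group`, `side`, `reads`).
#' @param transcript_calls Output of [call_transcript_enrichment()].
#' @return Tibble with one row per (event, group, side role):
#'   `event_id`, `group`, `side`, `role` (`"enriched"`/`"depleted"`),
#'   `pct_ped`, `pct_reads`.
#' @export
support_points <- function(ped_profile, reads, transcript_calls) {
  hits <- dplyr::filter(transcript_calls, .data$enriched_side != "none")
  if (!nrow(hits)) {
    return(tibble::tibble(event_id = character(), group = character(),
                          side = character(), role = character(),
                          pct_ped = numeric(), pct_reads = numeric()))
  }
  hits <- hits |>
    dplyr::mutate(depleted_side = ifelse(.data$enriched_side == "main",
                                         "alternative", "main")) |>
    tidyr::pivot_longer(c("enriched_side", "depleted_side"),
                        names_to = "role", values_to = "side") |>
    dplyr::mutate(role = sub("_side$", "", .data$role)) |>
    dplyr::select("event_id", "group", "side", "role")

  ped_pct <- ped_profile |>
    dplyr::filter(.data$unit_kind == "group") |>
    dplyr::group_by(.data$event_id, .data$side) |>
    dplyr::mutate(total = sum(.data$ped)) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$event_id, group = .data$unit, .data$side,
                     pct_ped = ifelse(.data$total > 0,
                                      100 * .data$ped / .data$total,
                                      NA_real_))
  read_pct <- reads |>
    dplyr::group_by(.data$event_id, .data$group, .data$side) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop_last") |>
    dplyr::group_by(.data$event_id, .data$side) |>
    dplyr::mutate(total = sum(.data$reads)) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$event_id, .data$group, .data$side,
                     pct_reads = ifelse(.data$total > 0,
                                        100 * .data$reads / .data$total,
                                        NA_real_))
  hits |>
    dplyr::left_join(ped_pct, by = c("event_id", "group", "side")) |>
    dplyr::left_join(read_pct, by = c("event_id", "group", "side")) |>
    dplyr::filter(!is.na(.data$pct_ped), !is.na(.data$pct_reads)) |>
    dplyr::arrange(.data$event_id, .data$group, .data$side)
}

#' Protein-transcript concordance summary
#'
#' Counts, per tissue group, how many transcript-enriched events are also
#' protein-enriched (PGE cases) in the same group; reports the overall
#' fraction of PGE cases that are transcript-enriched in their group; and
#' compares groups pairwise with two-sided Fisher tests on the 2x2 table
#' (concordant vs not) x (group 1 vs group 2).
#'
#' @param pge_cases Output of [build_pge_cases()].
#' @param transcript_calls Output of [call_transcript_enrichment()].
#' @param match_side Require the same side to be enriched in both analyses?
#'   Default `FALSE`: the two analyses label main/alternative by their own
#'   evidence, so only the group is matched.
#' @return A list with elements `by_group` (tibble: `group`, `n_transcript`,
#'   `n_concordant`), `overall` (tibble: `n_pge`, `n_concordant`,
#'   `fraction`), and `pairwise` (tibble: `group1`, `group2`, `p_value`).
#' @export
concordance_summary <- function(pge_cases, transcript_calls,
                                match_side = FALSE) {
  tcalls <- dplyr::filter(transcript_calls, .data$enriched_side != "none")
  join_by <- c("event_id", "group", if (match_side) "enriched_side")
  concordant <- dplyr::semi_join(pge_cases, tcalls, by = join_by)

  by_group <- tcalls |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_transcript = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(
      concordant |>
        dplyr::count(.data$group, name = "n_concordant"),
      by = "group"
    ) |>
    dplyr::mutate(n_concordant = dplyr::coalesce(.data$n_concordant, 0L)) |>
    dplyr::arrange(.data$group)

  overall <- tibble::tibble(
    n_pge = nrow(pge_cases),
    n_concordant = nrow(concordant),
    fraction = ifelse(nrow(pge_cases) > 0,
                      nrow(concordant) / nrow(pge_cases), NA_real_)
  )

  pairwise <- tibble::tibble(group1 = character(), group2 = character(),
                             p_value = numeric())
  if (nrow(by_group) >= 2) {
    combos <- utils::combn(by_group$group, 2)
    pairwise <- tibble::tibble(group1 = combos[1, ], group2 = combos[2, ])
    g <- function(col, grp) by_group[[col]][match(grp, by_group$group)]
    a <- g("n_concordant", pairwise$group1)
    b <- g("n_transcript", pairwise$group1) - a
    c_ <- g("n_concordant", pairwise$group2)
    d <- g("n_transcript", pairwise$group2) - c_
    pairwise$p_value <- fisher_p(a, b, c_, d)
  }

  list(by_group = by_group, overall = overall, pairwise = pairwise)
}

#' Correlation between percent PED and percent read support
#'
#' Pearson (default) or Spearman correlation between the percentage of PEDs
#' and the percentage of junction reads supporting each side of the
#' transcript-enriched events, per stratum (tissue group, or any grouping
#' column present in the points, e.g. an age bin).
#'
#' @param points Output of [support_points()], optionally with extra
#'   stratification columns joined on.
#' @param stratify_by Column to stratify on (default `"group"`).
#' @param method `"pearson"` or `"spearman"`.
#' @param min_points Minimum points per stratum (default 3); smaller strata
#'   are dropped.
#' @return Tibble with columns `stratum`, `n`, `r`.
#' @export
support_correlation <- function(points, stratify_by = "group",
                                method = c("pearson", "spearman"),
                                min_points = 3) {
  method <- match.arg(method)
  if (!stratify_by %in% names(points)) {
    rlang::abort(paste0("no column '", stratify_by, "' to stratify on"),
                 class = "splicepeds_schema_error")
  }
  points |>
    dplyr::group_by(stratum = .data[[stratify_by]]) |>
    dplyr::summarise(n = dplyr::n(),
                     sd_ped = stats::sd(.data$pct_ped),
                     sd_reads = stats::sd(.data$pct_reads),
                     r = if (dplyr::n() >= min_points &&
                             stats::sd(.data$pct_ped) > 0 &&
                             stats::sd(.data$pct_reads) > 0) {
                       stats::cor(.data$pct_ped, .data$pct_reads,
                                  method = method)
                     } else NA_real_,
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_points) |>
    (\(d) {
      if (any(is.na(d$r) & (d$sd_ped == 0 | d$sd_reads == 0))) {
        rlang::abort("constant percent vector: correlation undefined",
                     class = "splicepeds_undefined_correlation")
      }
      d
    })() |>
    dplyr::select("stratum", "n", "r") |>
    dplyr::arrange(.data$stratum)
}
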