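#' Build a one-unit-versus-rest contingency table
#'
#' Rows are the two compared evidence types (sides), columns are the selected
#' tissue or group versus all other units of the same kind. Cell `[i, 1]`
#' holds the PEDs of side *i* in the unit, cell `[i, 2]` the PEDs of side *i*
#' everywhere else, so row margins equal the profile's side totals.
#'
#' @param profile A PED profile from [build_ped_profile()].
#' @param event Event id.
#' @param unit Tissue or group label.
#' @param comparison One of `"main_vs_alt"`, `"main_vs_intersect"`,
#'   `"alt_vs_intersect"`.
#' @param unit_kind `"tissue"` or `"group"`; inferred from `unit` when `NULL`.
#' @return A 2x2 integer matrix with informative dimnames.
#' @export
make_table <- function(profile, event, unit, comparison = "main_vs_alt",
                       unit_kind = NULL) {
  sides <- comparison_sides(comparison)
  sub <- dplyr::filter(profile, .data$event_id == event)
  if (is.null(unit_kind)) {
    kinds <- unique(sub$unit_kind[sub$unit == unit])
    if (length(kinds) != 1) {
      rlang::abort(paste0("unit '", unit, "' not found (or ambiguous) ",
                          "in profile for event ", event),
                   class = "splicepeds_schema_error")
    }
    unit_kind <- kinds
  }
  sub <- dplyr::filter(sub, .data$unit_kind == !!unit_kind)
  if (!unit %in% sub$unit) {
    rlang::abort(paste0("unknown unit: ", unit),
                 class = "splicepeds_schema_error")
  }
  cells <- vapply(sides, function(s) {
    in_unit <- sum(sub$ped[sub$side == s & sub$unit == unit])
    total <- sum(sub$ped[sub$side == s])
    c(in_unit, total - in_unit)
  }, numeric(2))
  out <- t(cells)
  dimnames(out) <- list(side = sides, unit = c(unit, "rest"))
  storage.mode(out) <- "integer"
  out
}

comparison_sides <- function(comparison) {
  switch(comparison,
    main_vs_alt = c("main", "alternative"),
    main_vs_intersect = c("main", "intersect"),
    alt_vs_intersect = c("alternative", "intersect"),
    rlang::abort(paste0("unknown comparison: ", comparison),
                 class = "splicepeds_invalid_input")
  )
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null with all margins
#' fixed: the sum of the probabilities of every table at least as extreme
#' (probability not larger, up to a relative guard of 1e-7 against floating
#' point ties) as the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return p-value in `[0, 1]`.
#' @examples
#' fisher_two_sided(matrix(c(2, 2, 2, 2), 2))  # 1: no association
#' fisher_two_sided(matrix(c(5, 0, 0, 5), 2))  # 2/252
#' @export
fisher_two_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || anyNA(table)) {
    rlang::abort("need a 2x2 table of non-negative counts",
                 class = "splicepeds_invalid_input")
  }
  fisher_p(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
}

# Vectorised two-sided hypergeometric p-value for tables [[a, b], [c, d]].
fisher_p <- function(a, b, c, d) {
  mapply(function(a, b, c, d) {
    m <- a + b  # row 1 margin
    n <- c + d  # row 2 margin
    k <- a + c  # column 1 margin
    if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) return(1)
    x <- max(0, k - n):min(k, m)
    px <- stats::dhyper(x, m, n, k)
    pobs <- stats::dhyper(a, m, n, k)
    min(1, sum(px[px <= pobs * (1 + 1e-7)]))
  }, a, b, c, d)
}

#' Call tissue/group-specific splicing at the protein level
#'
#' For every event, unit and comparison, tests a one-unit-versus-rest 2x2
#' table with a two-sided Fisher exact test. The three comparisons per unit
#' are main vs alternative (the specificity call itself) and each side vs the
#' non-discriminating intersect peptides, which serve as a gene-expression
#' control: a significant main-vs-alt call is annotated as `enriched` when
#' the winning side's within-unit fraction of its PED total is at least the
#' intersect's fraction, and `depleted` otherwise (the whole gene is down in
#' that unit and one side merely less so).
#'
#' @param profile A PED profile.
#' @param alpha Significance threshold in (0, 1).
#' @param correction `"none"` (default, mirroring the uncorrected per-unit
#'   tests of the reference analysis) or `"bh"` for Benjamini-Hochberg across
#'   events within each unit and comparison.
#' @param unit_level `"both"`, `"tissue"` or `"group"`.
#' @param comparisons Character vector of comparisons to run.
#' @return Tibble with columns `event_id`, `unit_kind`, `unit`, `comparison`,
#'   `p_value`, `significant`, `enriched_side`, `direction`.
#' @export
call_specificity <- function(profile, alpha = 0.05,
                             correction = c("none", "bh"),
                             unit_level = c("both", "tissue", "group"),
                             comparisons = c("main_vs_alt",
                                             "main_vs_intersect",
                                             "alt_vs_intersect")) {
  correction <- match.arg(correction)
  unit_level <- match.arg(unit_level)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must be a probability strictly inside (0, 1)",
                 class = "splicepeds_invalid_parameter")
  }
  for (cmp in comparisons) comparison_sides(cmp)

  if (unit_level != "both") {
    profile <- dplyr::filter(profile, .data$unit_kind == !!unit_level)
  }

  totals <- profile |>
    dplyr::group_by(.data$event_id, .data$unit_kind, .data$side) |>
    dplyr::summarise(total = sum(.data$ped), .groups = "drop")
  wide <- profile |>
    dplyr::left_join(totals, by = c("event_id", "unit_kind", "side")) |>
    dplyr::mutate(frac = ifelse(.data$total > 0,
                                .data$ped / .data$total, NA_real_)) |>
    tidyr::pivot_wider(id_cols = c("event_id", "unit_kind", "unit"),
                       names_from = "side",
                       values_from = c("ped", "total", "frac"))
  for (col in c("ped_main", "ped_alternative", "ped_intersect",
                "total_main", "total_alternative", "total_intersect")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  for (col in c("frac_main", "frac_alternative", "frac_intersect")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }

  one_comparison <- function(cmp) {
    sides <- comparison_sides(cmp)
    a <- wide[[paste0("ped_", sides[1])]]
    b <- wide[[paste0("total_", sides[1])]] - a
    c_ <- wide[[paste0("ped_", sides[2])]]
    d <- wide[[paste0("total_", sides[2])]] - c_
    f1 <- wide[[paste0("frac_", sides[1])]]
    f2 <- wide[[paste0("frac_", sides[2])]]
    p <- fisher_p(a, b, c_, d)
    tibble::tibble(
      event_id = wide$event_id, unit_kind = wide$unit_kind, unit = wide$unit,
      comparison = cmp, p_value = p, frac_1 = f1, frac_2 = f2,
      frac_intersect = wide$frac_intersect
    )
  }

  calls <- dplyr::bind_rows(lapply(comparisons, one_comparison))
  if (correction == "bh") {
    calls <- calls |>
      dplyr::group_by(.data$unit_kind, .data$unit, .data$comparison) |>
      dplyr::mutate(p_adj = stats::p.adjust(.data$p_value, "BH")) |>
      dplyr::ungroup()
    calls$significant <- calls$p_adj < alpha
    calls$p_adj <- NULL
  } else {
    calls$significant <- calls$p_value < alpha
  }

  ge_na <- function(x, y) {
    # x >= y treating NA comparator as "no evidence against enrichment"
    ifelse(is.na(x), FALSE, ifelse(is.na(y), TRUE, x >= y))
  }
  is_ma <- calls$comparison == "main_vs_alt"
  win <- ifelse(ge_na(calls$frac_1, calls$frac_2), "main", "alternative")
  win[!is_ma] <- NA_character_
  ties <- is_ma & !is.na(calls$frac_1) & !is.na(calls$frac_2) &
    calls$frac_1 == calls$frac_2
  win[ties] <- "none"

  calls$enriched_side <- ifelse(calls$significant & is_ma, win, "none")
  win_frac <- ifelse(win == "main", calls$frac_1, calls$frac_2)
  calls$direction <- dplyr::case_when(
    !calls$significant ~ NA_character_,
    is_ma & ge_na(win_frac, calls$frac_intersect) ~ "enriched",
    is_ma ~ "depleted",
    ge_na(calls$frac_1, calls$frac_2) ~ "enriched",
    .default = "depleted"
  )

  calls |>
    dplyr::select("event_id", "unit_kind", "unit", "comparison", "p_value",
                  "significant", "enriched_side", "direction") |>
    dplyr::arrange(.data$event_id, .data$unit_kind, .data$unit,
                   .data$comparison)
}

#' Summarise specificity calls to one row per event
#'
#' An event is tissue-specific when any tissue-level main-vs-alt call is
#' significant, group-specific when any group-level one is, and specific when
#' either holds.
#'
#' @param calls Output of [call_specificity()].
#' @return Tibble with columns `event_id`, `tissue_specific`,
#'   `group_specific`, `specific`.
#' @export
specific_events <- function(calls) {
  calls |>
    dplyr::filter(.data$comparison == "main_vs_alt") |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      tissue_specific = any(.data$significant & .data$unit_kind == "tissue"),
      group_specific = any(.data$significant & .data$unit_kind == "group"),
      .groups = "drop"
    ) |>
    dplyr::mutate(specific = .data$tissue_specific | .data$group_specific) |>
    dplyr::arrange(.data$event_id)
}
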