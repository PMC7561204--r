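#' Fraction of disordered residues in a region
#'
#' A residue counts as disordered when its predicted disorder propensity is
#' strictly greater than 0.5; the region fraction is the share of such
#' residues. Thresholds are strict throughout: a residue scoring exactly 0.5
#' is not disordered.
#'
#' @param scores Numeric vector of per-residue disorder scores in `[0, 1]`
#'   (e.g. IUPred2 long-mode output), one per residue.
#' @return Fraction in `[0, 1]`.
#' @export
region_fraction <- function(scores) {
  if (!length(scores)) {
    rlang::abort("empty region: no residues to score",
                 class = "splicepeds_invalid_input")
  }
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    rlang::abort("disorder scores must lie in [0, 1]",
                 class = "splicepeds_invalid_input")
  }
  mean(scores > 0.5)
}

#' Call intrinsic disorder for one splice event
#'
#' Indels supply the inserted region's scores; substitutions supply both
#' swapped regions and the region with the highest disorder fraction
#' represents the event. The event is disordered when that fraction exceeds
#' one half (strictly). Events of four or fewer residues are too short for a
#' meaningful disorder call and are excluded.
#'
#' @param regions A numeric vector of scores, or a list of one or two such
#'   vectors (both regions of a substitution).
#' @return One-row tibble: `fraction`, `disordered`, `excluded`.
#' @export
call_event_disorder <- function(regions) {
  if (is.numeric(regions)) regions <- list(regions)
  if (!length(regions)) {
    rlang::abort("at least one scored region is required",
                 class = "splicepeds_incomplete_input")
  }
  lens <- vapply(regions, length, integer(1))
  if (max(lens) <= 4) {
    return(tibble::tibble(fraction = NA_real_, disordered = NA,
                          excluded = TRUE))
  }
  fracs <- vapply(regions, region_fraction, numeric(1))
  best <- max(fracs)
  tibble::tibble(fraction = best, disordered = best > 0.5, excluded = FALSE)
}

#' Disorder calls for a table of per-residue scores
#'
#' @param scores Tibble with columns `event_id`, `region_id`, `position`
#'   (1-based residue index) and `score`.
#' @return Tibble with one row per event: `event_id`, `fraction`,
#'   `disordered`, `excluded`.
#' @export
disorder_calls <- function(scores) {
  need <- c("event_id", "region_id", "position", "score")
  miss <- setdiff(need, names(scores))
  if (length(miss)) {
    rlang::abort(paste("score table is missing columns:",
                       paste(miss, collapse = ", ")),
                 class = "splicepeds_schema_error")
  }
  scores |>
    dplyr::arrange(.data$event_id, .data$region_id, .data$position) |>
    dplyr::group_by(.data$event_id) |>
    dplyr::group_modify(function(d, key) {
      call_event_disorder(split(d$score, d$region_id))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$event_id)
}
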