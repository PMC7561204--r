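#' Read and write the package's TSV interfaces
#'
#' All tables are UTF-8 tab-separated files with a header row and '.' decimal
#' separator. Writers round floating point columns to six significant digits
#' and sort rows on stable keys so that reruns produce byte-identical files.
#'
#' @param path File path.
#' @return Readers return validated tibbles; writers return `path`
#'   invisibly.
#' @name tsv_io
NULL

read_tsv_strict <- function(path, col_types) {
  out <- readr::read_tsv(path, col_types = col_types, progress = FALSE)
  prob <- readr::problems(out)
  if (nrow(prob)) {
    rlang::abort(paste0("parse problems in ", path, ", first at row ",
                        prob$row[1]),
                 class = "splicepeds_schema_error")
  }
  out
}

#' @rdname tsv_io
#' @export
read_detection_table <- function(path) {
  validate_detection_table(read_tsv_strict(path, readr::cols(
    peptide = readr::col_character(), gene_id = readr::col_character(),
    event_id = readr::col_character(), side = readr::col_character(),
    experiment_id = readr::col_character(), tissue = readr::col_character()
  )))
}

#' @rdname tsv_io
#' @export
read_event_table <- function(path) {
  validate_event_table(read_tsv_strict(path, readr::cols(
    event_id = readr::col_character(), gene_id = readr::col_character(),
    mechanism = readr::col_character(), effect = readr::col_character(),
    side_a_len = readr::col_integer(), side_b_len = readr::col_integer(),
    homologous_flag = readr::col_logical(),
    age_label = readr::col_character()
  )))
}

#' @rdname tsv_io
#' @export
read_read_table <- function(path) {
  read_tsv_strict(path, readr::cols(
    event_id = readr::col_character(), group = readr::col_character(),
    side = readr::col_character(), reads = readr::col_double()
  ))
}

#' @rdname tsv_io
#' @export
read_score_table <- function(path) {
  read_tsv_strict(path, readr::cols(
    event_id = readr::col_character(), region_id = readr::col_character(),
    position = readr::col_integer(), score = readr::col_double()
  ))
}

#' @rdname tsv_io
#' @export
read_homology_table <- function(path) {
  read_tsv_strict(path, readr::cols(
    exon_id = readr::col_character(), mode = readr::col_character(),
    hit_species = readr::col_character(),
    hit_clade = readr::col_character(),
    insertions = readr::col_integer()
  ))
}

#' @rdname tsv_io
#' @export
read_tissue_schema <- function(path) {
  validate_tissue_schema(read_tsv_strict(path, readr::cols(
    tissue = readr::col_character(), group = readr::col_character(),
    n_experiments = readr::col_integer()
  )))
}

#' @rdname tsv_io
#' @param x Table to write.
#' @param sort_keys Columns to sort on before writing (those present are
#'   used).
#' @export
write_output_tsv <- function(x, path,
                             sort_keys = c("event_id", "exon_id",
                                           "unit_kind", "unit", "group",
                                           "side", "comparison", "peptide",
                                           "region_id", "position",
                                           "experiment_id", "mode",
                                           "hit_clade", "tissue")) {
  keys <- intersect(sort_keys, names(x))
  if (length(keys)) x <- dplyr::arrange(x, dplyr::across(dplyr::all_of(keys)))
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.double),
                                      \(v) signif(v, 6)))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write all tables of a simulated cohort
#'
#' @param sim Output of [simulate_cohort()].
#' @param outdir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_output_tsv(sim$detections, file.path(outdir, "detections.tsv"))
  write_output_tsv(sim$events, file.path(outdir, "events.tsv"))
  write_output_tsv(sim$reads, file.path(outdir, "reads.tsv"))
  write_output_tsv(sim$scores, file.path(outdir, "scores.tsv"))
  write_output_tsv(sim$homology, file.path(outdir, "homology.tsv"))
  write_output_tsv(sim$schema, file.path(outdir, "tissue_schema.tsv"))
  write_output_tsv(sim$truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}
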