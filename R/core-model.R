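#' Controlled vocabularies for splice events
#'
#' A splice event is a gene-local splicing choice with two mutually exclusive
#' sequence outcomes ("sides"). Events are classified along two independent
#' axes: the splicing mechanism that generates them and the effect the choice
#' has on the resulting protein. Evidence (peptides, junction reads) maps to
#' one side, the other, or to sequence shared by both isoforms (the
#' "intersect").
#'
#' @return A character vector of the allowed labels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
splice_mechanisms <- function() {
  c("skipped_exon", "mutually_exclusive", "alt_5_splice_site",
    "alt_3_splice_site", "alt_promoter", "alt_polyA")
}

#' @rdname vocabularies
#' @export
effect_classes <- function() {
  c("indel", "micro_indel", "homologous_substitution",
    "c_terminal_substitution", "n_terminal_substitution",
    "internal_substitution", "two_proteins")
}

#' @rdname vocabularies
#' @export
side_labels <- function() c("main", "alternative", "intersect")

#' @rdname vocabularies
#' @export
age_bins <- function() c("primate", "theria", "tetrapoda", "ancient")

# Micro-indels are indels strictly smaller than this many residues.
MICRO_INDEL_MAX_AA <- 4L

#' Classify the protein-level effect of a splice event
#'
#' Deletions/insertions (one side contributes no residues) are "indels";
#' indels smaller than four residues -- micro-exons and NAGNAG-style tandem
#' splice-site choices that gain or lose a single residue -- are pooled as
#' micro-indels. Substitutions swapping homologous exons form their own
#' class, the remaining substitutions are labelled by their position in the
#' protein, and isoform pairs sharing no amino acid sequence at all are
#' "two proteins".
#'
#' Precedence: `two_proteins` (no shared sequence) beats
#' `homologous_substitution` (curated flag) beats micro-indel/indel beats the
#' positional substitution classes.
#'
#' @param side_a_len,side_b_len Lengths in amino acids of the event-specific
#'   region on each side (non-negative integers; an indel has one zero side).
#' @param position Where a substitution sits in the protein: `"internal"`,
#'   `"n_term"` or `"c_term"`. Ignored for indels.
#' @param shares_sequence Do the two isoforms share any amino acid sequence?
#' @param homologous Curated flag: are the swapped regions homologous exons?
#' @return Character vector of effect classes (see [effect_classes()]).
#' @examples
#' classify_effect(0, 1)                      # NAGNAG single-residue gain/loss
#' classify_effect(0, 4)                      # boundary: 4 aa is a plain indel
#' classify_effect(20, 25, position = "c_term")
#' @export
classify_effect <- function(side_a_len, side_b_len, position = "internal",
                            shares_sequence = TRUE, homologous = FALSE) {
  n <- max(length(side_a_len), length(side_b_len), length(position),
           length(shares_sequence), length(homologous))
  a <- rep_len(as.numeric(side_a_len), n)
  b <- rep_len(as.numeric(side_b_len), n)
  position <- rep_len(position, n)
  shares_sequence <- rep_len(shares_sequence, n)
  homologous <- rep_len(homologous, n)

  if (any(is.na(a) | is.na(b)) || any(a < 0 | b < 0)) {
    rlang::abort("side lengths must be non-negative amino acid counts",
                 class = "splicepeds_invalid_input")
  }
  if (any(a == 0 & b == 0)) {
    rlang::abort("an event must alter at least one residue on one side",
                 class = "splicepeds_invalid_input")
  }
  bad_pos <- !position %in% c("internal", "n_term", "c_term")
  if (any(bad_pos)) {
    rlang::abort("position must be one of internal, n_term, c_term",
                 class = "splicepeds_invalid_input")
  }

  is_indel <- pmin(a, b) == 0
  dplyr::case_when(
    !shares_sequence ~ "two_proteins",
    homologous ~ "homologous_substitution",
    is_indel & abs(a - b) < MICRO_INDEL_MAX_AA ~ "micro_indel",
    is_indel ~ "indel",
    position == "n_term" ~ "n_terminal_substitution",
    position == "c_term" ~ "c_terminal_substitution",
    .default = "internal_substitution"
  )
}

#' Assign main and alternative labels to the two sides of an event
#'
#' The main side of a splice event is the side supported by the most evidence
#' (PEDs for proteomics, junction reads for transcriptomics). Ties are broken
#' deterministically: the side with the lexicographically smaller identifier
#' becomes the main side.
#'
#' @param evidence_a,evidence_b Non-negative evidence counts for the two sides.
#' @param ids Length-2 character vector of side identifiers, in the same order
#'   as the evidence arguments.
#' @return Named character vector with elements `main` and `alternative`
#'   holding the corresponding identifiers.
#' @examples
#' assign_sides(10, 3, c("a", "b"))
#' assign_sides(5, 5, c("L", "R"))  # tie: "L" < "R", so "L" is main
#' @export
assign_sides <- function(evidence_a, evidence_b, ids = c("a", "b")) {
  stopifnot(length(ids) == 2, is.character(ids))
  if (is.na(evidence_a) || is.na(evidence_b) ||
      evidence_a < 0 || evidence_b < 0) {
    rlang::abort("evidence counts must be non-negative",
                 class = "splicepeds_invalid_input")
  }
  if (evidence_a == 0 && evidence_b == 0) {
    rlang::abort("both sides have zero evidence: sides are undetermined",
                 class = "splicepeds_undetermined_sides")
  }
  main_idx <- if (evidence_a > evidence_b) 1L
  else if (evidence_b > evidence_a) 2L
  else order(ids)[1L]  # tie: lexicographically smaller id is main
  c(main = ids[main_idx], alternative = ids[3L - main_idx])
}

#' Build and validate a tissue schema
#'
#' A tissue schema lists the tissues of a proteomics cohort, the tissue group
#' each belongs to (groups pool related tissues to amplify signal), and the
#' number of replicate experiments per tissue. Every tissue maps to exactly
#' one group; the sum of `n_experiments` is the total experiment count of the
#' cohort.
#'
#' @param tissue Character vector of tissue identifiers (unique).
#' @param group Character vector of group labels, one per tissue.
#' @param n_experiments Positive integer replicate count per tissue.
#' @return A tibble with columns `tissue`, `group`, `n_experiments`.
#' @export
tissue_schema <- function(tissue, group, n_experiments) {
  out <- tibble::tibble(tissue = as.character(tissue),
                        group = as.character(group),
                        n_experiments = as.integer(n_experiments))
  validate_tissue_schema(out)
}

#' @rdname tissue_schema
#' @param schema A data frame to validate.
#' @export
validate_tissue_schema <- function(schema) {
  need <- c("tissue", "group", "n_experiments")
  if (!all(need %in% names(schema))) {
    rlang::abort(paste("tissue schema needs columns:",
                       paste(need, collapse = ", ")),
                 class = "splicepeds_schema_error")
  }
  if (anyNA(schema$tissue) || anyNA(schema$group) ||
      anyNA(schema$n_experiments)) {
    rlang::abort("tissue schema contains missing values",
                 class = "splicepeds_schema_error")
  }
  if (anyDuplicated(schema$tissue)) {
    rlang::abort("each tissue must map to exactly one group",
                 class = "splicepeds_schema_error")
  }
  if (any(schema$n_experiments < 1)) {
    rlang::abort("every tissue needs at least one experiment",
                 class = "splicepeds_schema_error")
  }
  tibble::as_tibble(schema)
}

#' Reference proteomics tissue schema
#'
#' A synthetic emulation of the reference proteomics cohort: 30 tissues and
#' haematopoietic cell types (17 adult tissues, 7 foetal tissues, 6 purified
#' blood cell types), 79 replicate experiments in total (18 foetal, 61 adult
#' and haematopoietic; adult heart has five replicates, every tissue at least
#' two), pooled into 10 groups of related tissues. The grouping follows the
#' published group structure (e.g. nervous = frontal cortex, fetal brain,
#' spinal cord and retina); the per-tissue replicate split is a plausible
#' stand-in for the unpublished per-experiment table and is used as the
#' simulation default, not as real metadata.
#'
#' @return A tissue schema tibble (see [tissue_schema()]).
#' @export
reference_proteomics_schema <- function() {
  tissue_schema(
    tissue = c(
      "frontal_cortex", "spinal_cord", "retina", "fetal_brain",
      "heart", "fetal_heart",
      "esophagus", "colon", "rectum", "gallbladder", "pancreas", "fetal_gut",
      "liver", "fetal_liver",
      "ovary", "testis", "prostate", "fetal_ovary", "fetal_testis",
      "monocytes", "nk_cells", "cd4_tcells", "cd8_tcells", "b_cells",
      "platelets",
      "lung",
      "kidney", "urinary_bladder",
      "placenta",
      "adrenal_gland"
    ),
    group = c(
      rep("nervous", 4),
      rep("muscle", 2),
      rep("digestive", 6),
      rep("liver", 2),
      rep("reproductive", 5),
      rep("blood", 6),
      "respiratory",
      rep("urinary", 2),
      "placenta",
      "endocrine"
    ),
    n_experiments = c(
      3L, 2L, 3L, 3L,          # nervous (fetal brain 3)
      5L, 3L,                  # muscle: adult heart 5, fetal heart 3
      3L, 3L, 2L, 2L, 3L, 3L,  # digestive
      3L, 3L,                  # liver
      3L, 3L, 3L, 2L, 2L,      # reproductive
      3L, 2L, 2L, 2L, 2L, 2L,  # blood
      3L,                      # respiratory
      3L, 2L,                  # urinary
      2L,                      # placenta
      2L                       # endocrine
    )
  )
}

#' Reference transcriptomics tissue groups
#'
#' The transcriptomics cohort is grouped into 12 tissue groups: nine shared
#' with the proteomics grouping plus three (skin, fat, immune) with no
#' proteomics counterpart. The proteomics "blood" group has no transcriptomics
#' equivalent and is therefore absent here.
#'
#' @return Character vector of 12 group labels.
#' @export
reference_transcript_groups <- function() {
  c(shared_tissue_groups(), "skin", "fat", "immune")
}

#' Tissue groups shared by the proteomics and transcriptomics cohorts
#'
#' The nine groups present in both analyses; protein-group-enrichment (PGE)
#' cases are restricted to these (blood, proteomics-only, is excluded).
#'
#' @return Character vector of 9 group labels.
#' @export
shared_tissue_groups <- function() {
  c("nervous", "muscle", "digestive", "liver", "reproductive",
    "respiratory", "urinary", "placenta", "endocrine")
}

#' Uniform toy tissue schema
#'
#' Balanced schema for simulations and power checks: `n_groups` groups, each
#' with `tissues_per_group` tissues of `experiments_per_tissue` replicates.
#'
#' @param n_groups Number of tissue groups.
#' @param tissues_per_group Tissues in each group.
#' @param experiments_per_tissue Replicate experiments per tissue.
#' @param group_names Optional group labels (default `g01`, `g02`, ...).
#' @return A tissue schema tibble.
#' @export
uniform_schema <- function(n_groups = 10, tissues_per_group = 2,
                           experiments_per_tissue = 3, group_names = NULL) {
  if (is.null(group_names)) {
    group_names <- sprintf("g%02d", seq_len(n_groups))
  }
  stopifnot(length(group_names) == n_groups)
  tissue_schema(
    tissue = sprintf("%s_t%d", rep(group_names, each = tissues_per_group),
                     rep(seq_len(tissues_per_group), times = n_groups)),
    group = rep(group_names, each = tissues_per_group),
    n_experiments = rep(as.integer(experiments_per_tissue),
                        n_groups * tissues_per_group)
  )
}

#' Validate an event table
#'
#' @param events Data frame with columns `event_id`, `gene_id`, `mechanism`,
#'   `effect`, `side_a_len`, `side_b_len`, `homologous_flag`, `age_label`.
#' @return The validated tibble.
#' @export
validate_event_table <- function(events) {
  need <- c("event_id", "gene_id", "mechanism", "effect",
            "side_a_len", "side_b_len", "homologous_flag", "age_label")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    rlang::abort(paste("event table is missing columns:",
                       paste(miss, collapse = ", ")),
                 class = "splicepeds_schema_error")
  }
  bad <- which(!events$mechanism %in% splice_mechanisms())
  if (length(bad)) {
    rlang::abort(paste0("unknown mechanism in event table rows: ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 class = "splicepeds_schema_error")
  }
  bad <- which(!events$effect %in% effect_classes())
  if (length(bad)) {
    rlang::abort(paste0("unknown effect in event table rows: ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 class = "splicepeds_schema_error")
  }
  bad <- which(!(is.na(events$age_label) |
                   events$age_label %in% c(age_bins(), "unknown")))
  if (length(bad)) {
    rlang::abort(paste0("unknown age label in event table rows: ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 class = "splicepeds_schema_error")
  }
  if (anyDuplicated(events$event_id)) {
    rlang::abort("event ids must be unique", class = "splicepeds_schema_error")
  }
  tibble::as_tibble(events)
}
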