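# Two groups x two tissues x three experiments each: the smallest schema on
# which group pooling is non-trivial.
tiny_schema <- function() {
  tissue_schema(
    tissue = c("cortex", "retina", "colon", "pancreas"),
    group = c("nervous", "nervous", "digestive", "digestive"),
    n_experiments = c(3L, 3L, 3L, 3L)
  )
}

# Convenience constructor for detection rows.
det <- function(peptide, event, side, experiment, tissue, gene = "G1") {
  tibble::tibble(peptide = peptide, gene_id = gene, event_id = event,
                 side = side, experiment_id = experiment, tissue = tissue)
}

# Detections spreading a peptide over the first n experiments of the given
# tissues (experiment ids mirror the simulator's "<tissue>_e<i>" layout).
spread_det <- function(peptide, event, side, tissues, n_each, gene = "G1") {
  dplyr::bind_rows(lapply(tissues, function(ts) {
    det(peptide, event, side, paste0(ts, "_e", seq_len(n_each)), ts, gene)
  }))
}
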