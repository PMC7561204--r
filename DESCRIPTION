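Package: splicepeds
Title: Tissue-Specific Alternative Splicing from Peptide and Junction Read Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tissue-specific alternative splicing at the protein
    level by aggregating peptide-experiment detections (PEDs) over the two
    sides of each splice event, testing one-tissue-versus-rest enrichment
    with Fisher's exact test, and contrasting the protein-level calls with
    splice-junction read support at the transcript level (one-standard-
    deviation rule). Includes event classification by splicing mechanism
    and protein-level effect, protein-transcript concordance and
    percent-support correlations, exon evolutionary-age estimation from
    homology-hit tables, intrinsic-disorder region calling, a ground-truth
    synthetic cohort generator, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
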