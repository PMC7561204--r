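---
title: "Quantifying tissue-specific alternative splicing at the protein level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue-specific alternative splicing at the protein level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicepeds)
library(dplyr)
```

## The problem

Transcriptomics consistently finds that a majority of alternative splice
events differ between tissues, but whether those differences survive to the
protein level is much harder to establish: shotgun proteomics detects few
discriminating peptides per isoform, and detection is effectively
presence/absence. `splicepeds` implements an analysis designed for exactly
this regime. Its unit of protein evidence is the **PED**
(peptide-experiment detection): the number of distinct experiments in which
a peptide was identified. In a label-free cohort with replicates for every
tissue, a peptide found in all 79 experiments has 79 PEDs; one found once
has 1. PEDs are counted, never intensity-weighted, because presence across
replicated experiments is the only quantity this kind of data supports
robustly.

## Events, sides, and evidence types

A splice event is a single splicing choice with two mutually exclusive
sequence outcomes, its **sides**. Discriminating peptides (or junction
reads) map to one side or the other; evidence mapping to sequence shared by
both isoforms is the **intersect** and serves as a gene-expression control.
The **main** side is the one with most supporting evidence — assigned
independently for proteomics (PEDs) and transcriptomics (reads) by
`assign_sides()`/`normalize_sides()`. The evidence sources do not state how
to break ties, so the package breaks them lexicographically on the side
identifier, which makes reruns deterministic.

Events are classified along two axes (`classify_effect()`):

* **mechanism** — skipped exon, mutually exclusive exons, alternative 5'
  or 3' splice site, alternative promoter, alternative poly-A;
* **protein effect** — indel, micro-indel (indels strictly smaller than
  four residues, which covers micro-exons and NAGNAG single-residue
  gains/losses), homologous substitution (a curated flag, not computed
  here), N-terminal / C-terminal / internal substitution, and "two
  proteins" for isoform pairs sharing no sequence at all.

The precedence is: no shared sequence → two proteins; homologous flag →
homologous substitution; indel length `< 4` aa → micro-indel; indel;
otherwise positional substitution. The micro-indel threshold is applied to
the inserted/deleted segment (equivalently `|len_a − len_b|` when one side
is empty), which makes the single-residue NAGNAG case a micro-indel as it
should be.

## Protein-level specificity

Only events with at least `min_peds = 3` PEDs on *each* side enter the
analysis (`filter_events()`); below that no contingency test can reach
significance, so retaining such events would only dilute the denominator.
For every event and every tissue or tissue group, `call_specificity()`
builds one-unit-versus-rest 2×2 tables — rows are two evidence types,
columns are (unit, all other units) — for three comparisons: main vs
alternative, main vs intersect, alternative vs intersect. Each is tested
with a two-sided Fisher exact test (`fisher_two_sided()`, exact
hypergeometric enumeration; the test suite checks it against a brute-force
`choose()`-based oracle to 1e-12 and against `stats::fisher.test`).

Decisions the source procedure leaves open, and what this package does:

* **Alpha and correction.** Significance means `p < 0.05`, two-sided,
  uncorrected — the apparent procedure behind the published counts.
  Benjamini–Hochberg across events within each unit is available
  (`correction = "bh"`) but off by default.
* **Combining the three comparisons.** The main-vs-alt comparison drives
  the specificity call; the two intersect comparisons are computed and used
  for the direction annotation.
* **Enriched vs depleted.** The winning side of a significant main-vs-alt
  call is `enriched` when its within-unit fraction of its own PED total is
  at least the intersect's fraction, and `depleted` otherwise — a depleted
  call means the whole gene is down in the unit and one side merely less
  so. Depleted calls are reported but excluded from the PGE case set.

An event is *tissue-specific* if any tissue-level main-vs-alt call is
significant, *group-specific* if any group-level call is
(`specific_events()`). Grouping the 30 tissues into 10 related groups
pools replicates and amplifies signal, at the cost of group-level
granularity.

## Transcript-level specificity: the SD rule

Junction reads per (event, group, side) are standardised across groups
within each side: `z = (reads − mean) / sd`, population SD by default,
`z = 0` when the side is flat (`transcript_z()`). A group is called
enriched for a side when that side's z exceeds the other side's by at least
one standard deviation (`call_transcript_enrichment()`). The source text is
ambiguous about whether raw reads or standardised values are compared; the
z-difference reading is the one consistent with the published heat-map
descriptions ("more than one standard deviation of reads than the main
transcript"), and it makes the call invariant to each side's overall
expression scale — multiplying one side's reads by a constant changes
nothing, which is the behaviour a junction-usage statistic should have.

The SD rule is deliberately liberal: with realistic overdispersion almost
every event exceeds one standard deviation somewhere across 12 groups. This
matches the field's observation that roughly two-thirds or more of events
look tissue-specific at the transcript level, but it means transcript calls
should be read as a confirmation layer for protein calls, not as a
specificity filter in their own right.

## Concordance and percent support

`build_pge_cases()` collects the protein-group-enrichment case set: one
case per (event, group) with a significant, *enriched*-direction,
group-level call in a group shared by both cohorts (blood, which has no
transcriptomics counterpart, is excluded). `concordance_summary()` then
counts, per group, how many transcript-enriched events are also PGE cases
in the same group, the overall fraction of PGE cases confirmed at the
transcript level, and pairwise Fisher tests between groups. Matching is on
group only by default (`match_side = FALSE`): the main/alternative labels
are assigned per evidence source and may flip between the two, so requiring
side agreement would conflate label assignment with biology; it is
available as an option.

`support_points()` computes, for each transcript-enriched (event, group),
the percentage of PEDs and of reads in that group for both the enriched and
the depleted side — each side's percentage over that side's own total, so a
fully group-restricted side scores 100%. Sides with zero totals are
undefined and dropped, never scored as 0. `support_correlation()` reports
Pearson correlations (Spearman by flag; the published values are presented
as plain correlations, for which Pearson is the default reading) per group
or per any joined stratum such as age bin, and refuses constant vectors.

## Exon age and disorder

**Age** (`estimate_age()`): homology hits from two search modes — the
translated exon alone, and the exon joined to its flanking exon(s) — are
filtered to alignments with fewer than four residue insertions; within each
mode the most distant accepted clade is that mode's predicted age, and the
final age is the *minimum* of the two (a long-range hit that disappears
when flanks are attached is treated as spurious). Only exons of at least
42 bases are eligible (`eligible_exon()`). The clade ladder
(primates < euarchontoglires < theria < mammalia < tetrapoda <
sarcopterygii < vertebrata) is an explicit configuration mapped onto four
categorical bins: primate (≲75 My), theria (75–160), tetrapoda (160–400),
ancient (>400 My, before the lobe-finned fish split). Bins are categorical;
no numeric dating is attempted. Curated age labels, where present in the
event table, override automatic estimates (`combine_ages()`), and an exon
with no accepted hit is reported as undetermined, never defaulted.

**Disorder** (`disorder_calls()`): per-residue scores (IUPred2 long mode or
equivalent) are inputs, not computed. A residue is disordered when its
score exceeds 0.5 *strictly*; a region when more than half its residues
are. Indels supply the inserted region; substitutions supply both swapped
regions and the one with the highest disorder fraction represents the
event. Events of four or fewer residues are excluded — at that length the
region fraction is dominated by single residues.

## The synthetic cohort

`simulate_cohort()` generates every input table with known ground truth so
the whole pipeline is testable without any external download. The default
world mirrors the reference cohort: 255 events; 30 tissues / 79 replicate
experiments / 10 proteomics groups (`reference_proteomics_schema()`, a
documented synthetic stand-in for the unpublished per-tissue replicate
table, constrained to everything that is stated: nervous = frontal cortex,
fetal brain, spinal cord, retina; adult heart five replicates; 18 fetal
experiments; every tissue at least two); 12 transcriptomics groups, nine
shared. Defaults chosen once and documented:

* `fraction_specific = 95/255` — the reference tissue-specific fraction;
* alternative-side usage `psi_background = 0.2` everywhere,
  `psi_target = 0.8` in the target group of truly specific events (the
  main side takes the complement), i.e. the alternative isoform is the
  minor form except where it is the tissue's form;
* `p_detect = 0.5` per expressed discriminating peptide per experiment — a
  realistic label-free detection rate for moderately abundant proteins;
* reads are negative binomial, mean 100 per fully-used side per group,
  size 5 (typical bulk RNA-seq overdispersion; size ≥ 1e8 switches to
  Poisson as the vanishing-noise limit);
* disorder scores Beta(8, 2) for truly disordered regions and Beta(2, 8)
  for ordered ones — well separated on purpose, so disorder tests probe the
  calling logic, not the predictor;
* the age mix of the reference event set (7.8% primate, 15% theria, 25%
  tetrapoda, 52% ancient), with homology hits generated so that the
  min-of-two-modes rule recovers the true bin and each mode also carries a
  distant near-miss with ≥4 insertions that the filter must reject.

What the generator does **not** emulate: peptide detectability from
sequence, correlated replicates, paired proteomics/transcriptomics samples
(the real cohorts were unpaired), or biological coupling between age,
disorder and specificity. A green recovery test therefore establishes that
the statistical machinery recovers the truth its model class encodes — not
that the biology of any real cohort is reproduced.

## Numerical choices and degenerate inputs

* Fisher p-values use exact `dhyper` enumeration with the conventional
  `1 + 1e-7` relative guard against floating-point ties; tables with an
  empty row or column give `p = 1`.
* Population (n) standard deviation in the SD rule; `sd = 0` gives
  `z = 0`, so a flat side can never be called enriched.
* Both-sides-zero evidence is an error for `assign_sides()` (undetermined,
  not arbitrary); events with undetermined sides simply keep their
  provisional labels during normalisation.
* All writers sort on stable keys and serialise doubles at six significant
  digits, so reruns are byte-identical.
* PED counts are not normalised for unequal replicate counts per tissue
  (the raw-PED convention of the source analysis); an explicit schema makes
  the replicate structure visible to any caller who wants to weight.

## Known limitations

* With default overdispersion, the 1-SD transcript rule calls nearly every
  event group-specific somewhere; its value is directional confirmation of
  protein-level calls.
* Uncorrected per-unit Fisher tests are the reference procedure, not a
  recommendation; use `correction = "bh"` for inference beyond
  reproduction.
* The per-call false-positive rate of group-level Fisher calls on null
  cohorts is far below alpha (discrete tables are conservative), so power
  at small PED counts is limited — the motivation for the 3-PED floor and
  for tissue grouping.
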