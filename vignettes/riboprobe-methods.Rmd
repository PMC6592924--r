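---
title: "Methods: sample-centric FISH probe design from shotgun sequence tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sample-centric FISH probe design from shotgun sequence tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboprobe)
```

## The problem and the model

Conventional FISH probe design starts from a curated full-length 16S rRNA
database and comparative sequence analysis. That breaks down exactly where
FISH is most wanted: for uncultured, poorly referenced community members.
`riboprobe` implements the complementary, sample-centric route: take the
shotgun (metagenomic or metatranscriptomic) reads of the community itself,
extract fixed-length sequence tags from a 16S hypervariable region — here
V6 — and use the most abundant tag of the taxon of interest directly as
the probe template. One unique 33 nt tag ("ribotag") defines one OTU; the
probe is the 5'-most 17 nt of that tag; its name is `Ribo_<stem>_<length>`.

The workflow is: `tally_tags()` (extraction) → `annotate_table()`
(taxonomy) → `design_probe()` (template selection + truncation + Tm
advisory) → `evaluate_probe()` (in-silico coverage/specificity) →
`fold_enrichment()` / `purity()` (sorting outcomes) → `biovolume_fraction()`
/ `manders_mcc()` (image-based quantification).

## Tag extraction

The upstream tag extractor this package stands beside recognises the V6
flank with a sensitive, undisclosed recognition profile. We therefore model
the conserved flank as a user-configurable IUPAC anchor (`anchor()`):
pattern of at least 8 nt, at most 2 mismatches, `N` in a read never
matching. We make no claim of output parity with any external tool on real
reads; for synthetic data the planted `fixture_anchor()` makes extraction
exact by construction.

Conventions, fixed once:

* **Orientation.** Published probe pairs show the probe equal to the 5'
  prefix of its ribotag, so tags are stored in probe orientation; a read
  hit on the minus strand is reverse-complemented before extraction.
  Whether that orientation is the rRNA sense or antisense strand is
  deliberately left to evaluation time, where both orientations are
  searched.
* **One tag per read.** A read with several anchor hits keeps the best one
  (fewest mismatches, then leftmost in oriented coordinates, then the plus
  strand). This keeps tag counts and read counts comparable.
* **Windows.** The tag is the 33 nt immediately after the anchor's 3' end
  (offset configurable); the 81 nt representative shares the tag's 5' end.
  Whether the original tool centres or left-aligns its representative is
  not documented; we left-align, so `tag == substr(representative, 1, 33)`
  always holds. Coordinates are 0-based half-open.
* **Ties between identical tags.** The stored representative is the
  longest observed, ties resolved to the lexicographically smallest, making
  tables independent of read order.

Quality control is the end-scan rule: trim bases from both read ends while
the terminal Phred score is below 20, discard reads shorter than 30 nt.
Only those two thresholds are specified by the protocols this follows; a
windowed trimmer would need parameters nobody states, so the simplest
contract satisfying "from both ends" was chosen.

## Taxonomy annotation

`build_reference_db()` extracts the tag of every annotated reference; a
query tag is annotated by exact match, or failing that by all reference
tags at the minimal Hamming distance within `max_mm`. The annotation is the
lowest common ancestor (LCA) of every matched reference's ranked path;
equally-near tags pool their references before the LCA rather than picking
one arbitrarily — conservative by construction. Because database tags are
stored in the same probe orientation as sample tags, matching needs no
orientation logic.

This exact/near-match + LCA scheme is a declared surrogate for
database-alignment classifiers; it is exercised end-to-end on synthetic
data where the truth is known.

## Probe design

`truncate_probe()` removes 3' bases, keeping the 5' prefix — 17 nt by
default, the length that lets new probes share melting behaviour with the
published 17–25 nt FISH repertoire at the standard 46 °C hybridisation
temperature. Because that default was ultimately an empirical choice, a
Tm-driven alternative (`truncate_to_tm()`) truncates until the estimate
enters a user window instead.

`estimate_tm()` uses unified nearest-neighbour parameters (Allawi &
SantaLucia) with the entropic salt correction `0.368·(N−1)·ln[Na+]` and a
formamide term of −0.6 °C per percent. Defaults: `na_molar = 0.9` (the
0.9 M NaCl FISH hybridisation buffer) and `oligo_molar = 1e-9`. The 1 nM
total-strand default deserves a word: bench probe concentrations are
micromolar, but in-situ hybrids dissociate several degrees below
solution-phase predictions, and a low effective duplex concentration is the
simplest way to keep the advisory in the realistic range — for 14–20 nt
probes of ordinary composition it stays within ±8 °C of the classical
2·(A+T)+4·(G+C) rule, which was calibrated under comparable salt. The value
is labelled an advisory everywhere: working stringency must come from a
formamide dissociation curve, not from this number.

The formamide advisory reported by `design_probe()` is the percent
formamide at which the Tm estimate meets the hybridisation temperature
(rounded to 5%, clamped to 0–70%), again advisory only.

## In-silico evaluation

`match_probe()` is Hamming-only — tags are fixed-length, and indel
tolerance would blur the OTU definition itself; thermodynamic mismatch
weighting (mathFISH-style ΔG) is out of scope. `N` counts as a mismatch.
Both orientations are searched by default because reference strandedness
varies; every hit records its orientation for auditing.

Coverage is hit-targets / all-targets; specificity is hit-targets /
all-hit-subjects. A subject is a target when the query label equals any
resolved rank of its taxonomy. Tag-table evaluations report both
read-weighted (count-weighted) and unweighted (OTU-level) versions, since
a probe can cover the dominant tag of a taxon (high read coverage) while
missing sibling OTUs (low OTU coverage). Degenerate denominators are
reported as explicit `NA`, never 0/0: an absent target yields
`n_target_subjects == 0` with null coverage, and zero total hits yield
null specificity.

`compare_probe_vs_tag()` quantifies what probe truncation costs: the
fraction of tag counts matching the probe (5'-prefix rule, exact — the
analyses this mirrors are exact) versus matching the full 33 nt tag, plus
the co-sorted tags that share the prefix without being the target OTU.
The prefix relation guarantees `frac_matching_probe >=
frac_matching_tag`.

## Enrichment statistics

A community profile is tag counts annotated to the taxon divided by total
tag counts in the sample. Tags with no annotation — or unresolved at the
requested rank — fall into an explicit `unannotated` bucket, so every
profile sums to 1 (tolerance 1e-9 in all checks). Note the consequence: a
tag resolved only to genus counts as unannotated in a species-level
profile; rank roll-up sums are exact among fully resolved annotations.

Fold enrichment is post/pre abundance, reported both as the real ratio
and floor-truncated ("up to 93 fold" for 0.9866/0.0106 = 93.08). A target
absent pre-sort gives an explicitly flagged null rather than infinity:
shallow pre-sort sequencing of a rare target routinely yields zero tags.

## Imaging statistics

The biovolume fraction is the segmented target volume over the segmented
general-bacterial (EUB338-channel) volume. Proprietary surface
segmentation is replaced by its published post-filter: an absolute
intensity threshold, strictly `> 10` by default and configurable. The
voxel volume cancels in the ratio but is carried so absolute biovolumes
can be reported. 2-D and 3-D arrays are treated identically.

Manders' coefficients use the thresholded form (`M1` = channel-1 intensity
inside channel-2's above-threshold set over channel-1's own
above-threshold intensity; `M2` symmetric); `thr = 0` on strictly positive
signal recovers the unthresholded form. Empty above-threshold sets flag
the coefficient as undefined.

For dissociation curves no published selection rule exists — curves are
shown, choices are not formalised — so the package's own rule is explicit
and exposed: recommend the highest formamide concentration retaining at
least `retain_fraction` (default 0.9) of the curve's maximum mean
intensity, and label the output a recommendation.

## What the synthetic data emulates — and what it does not

`simulate_references()` builds 16S-like references (conserved flank +
15 nt fixture anchor + unique 33 nt variable region + conserved flank)
under a nested 7-rank synthetic taxonomy; `simulate_reads()` draws reads
with abundance-proportional reference choice, uniform start, equiprobable
strands, substitution errors at a set rate and qualities encoding that
rate. Defaults are chosen once as realistic study conditions: 120 nt reads
(post-trimming Illumina scale), 0.001 per-base error (Q30), geometric
rank-abundance with ratio 0.7 (a long-tailed community shape).
`sort_model()` emulates FISH–FACS: probe-matching reads (5'-prefix rule on
the extracted tag) captured with probability 1 by default, others leaking
at 6.7e-4 — the carry-over that takes a ~1.15% target to a ~94.5%
post-sort share in one round, matching observed single-round sorting.
`simulate_images()` constructs (not samples) channel pairs whose
above-threshold sets overlap exactly as requested, so Manders coefficients
have exact expected values.

The generator is substitution-only: tags are fixed-length and the matcher
is Hamming-based, so indels could only cause anchor misses, which are
covered separately by truncated-read cases. It has no 16S phylogenetic
covariance (synthetic variable regions are independent random 33-mers, so
cross-taxon near-matches are far rarer than in real communities), no
chimeras, and no amplification bias. Passing tests therefore demonstrate
the correctness of the computational contracts under known truth — not
probe performance on real communities, where conserved-region homology and
database incompleteness dominate.

## Validation design and problem sizes

Every derived expectation in the test suite is computed by an independent
oracle (plain-loop brute force for every mismatch scan, hand counts for
every ratio) rather than by the code under test. Validation problem sizes
were fixed as: 500 random probe/subject instances (probe 10–33 nt, subject
up to 200 nt, 0–2 mismatches) for matcher/oracle parity; 10,000 reads for
abundance recovery within three binomial standard errors; 12,000 reads for
sort-purity recovery against the closed form
`p·c / (p·c + (1−p)·k)`. In the recovery runs annotation uses `max_mm = 2`,
matched to the error model: at 0.001–0.002 per-base error a tag carries
two or more substitutions with negligible probability, so near-matching
reclaims error variants without cross-taxon ambiguity on independent
random tags.

## Known limitations

* The anchor is a user supplied surrogate; sensitivity on real reads
  depends entirely on its quality, and no parity with the original
  extraction tool is claimed.
* Hamming-only matching; no indels, no thermodynamic mismatch weighting.
* The Tm and formamide numbers are advisories with a deliberately simple
  concentration model; they seed, never replace, empirical dissociation
  curves.
* Species-level profiles treat genus-only annotations as unannotated
  rather than redistributing them.
* The imaging module quantifies masks and intensities; it does no cell
  counting, deconvolution or background subtraction.
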