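# riboprobe

Design and evaluate FISH probes directly from the shotgun sequencing data
of the community you are studying — no global 16S reference database
required at design time.

The package is aimed at microbial ecologists working on complex,
under-referenced communities (activated sludge, sediments, host-associated
consortia) who want to visualise or physically sort an OTU seen in their
own metagenomic or metatranscriptomic reads, including taxa with no
cultured representative or no full-length 16S record.

## The approach

Shotgun reads crossing the V6 hypervariable region of the 16S rRNA are
recognised by a conserved flanking anchor and reduced to a fixed-length
**ribotag** (33 nt by default): one unique tag = one sample-centric OTU,
with an 81 nt representative retained when the read allows. The probe for
a target taxon is derived from its most abundant tag by 3′ truncation,

```
probe = tag[1..17]            (5′ end kept, 3′ end removed)
name  = Ribo_<stem>_<length>  e.g. Ribo_Thau1029_17
```

so that new probes melt in the same range as the published 17–25 nt FISH
repertoire at the standard 46 °C hybridisation temperature. The toolkit
then quantifies, in silico and from images:

* **coverage** = target OTUs hit / target OTUs, and
  **specificity** = target OTUs hit / all OTUs hit, under mismatch-tolerant
  (Hamming) search of both orientations;
* **relative abundance** = tags annotated to the taxon / total tags in the
  sample, with an explicit `unannotated` bucket;
* **fold enrichment** = post-sort / pre-sort abundance (floor-truncated
  integer alongside the ratio);
* **biovolume fraction** = segmented target volume / segmented EUB338
  volume (absolute intensity threshold, strictly > 10 by default);
* **Manders' co-localisation coefficients** M1, M2 in the thresholded
  form;
* a nearest-neighbour **Tm advisory** (unified parameters, salt-corrected,
  −0.6 °C per % formamide) for each probe candidate.

A synthetic-data module generates references, communities, error-bearing
reads, probe-sorted samples and two-channel images with known ground
truth, so the full pipeline is testable offline.

## Worked example

A synthetic community of 8 taxa in which the target genus sits at ~1%
abundance, sequenced at 20,000 reads, probed and sorted:

```r
library(riboprobe)

refs  <- simulate_references(8, seed = 101)
comm  <- synthetic_community(refs,
           abundance = c(0.40, 0.25, 0.16, 0.10, 0.05, 0.03, 0.007, 0.003))
reads <- simulate_reads(comm, 20000, seed = 102)

anc <- fixture_anchor()
tt  <- tally_tags(quality_trim(reads), anc, sample_id = "pre")
db  <- build_reference_db(refs, anc, name = "synthetic")
tt  <- annotate_table(tt, db, max_mm = 2)

(probe <- design_probe(tt, "Genus_4", stem = "Gen4v6"))
#> Ribo_Gen4v6_17  5'-TCACGATCTTTATCCCT-3'  (17 nt)
#>   target: Genus_4
#>   source tag: TCACGATCTTTATCCCTGGAGATAAGTTGGGAG
#>   Tm advisory 50.1 C; ~5% formamide at 46 C (advisory only)

evaluate_probe(probe, tt, "Genus_4")
#> specificity_report: Ribo_Gen4v6_17 (5'-TCACGATCTTTATCCCT-3') vs
#>   tag_table, target 'Genus_4', <=0 mm
#>   targets hit 1/2 (coverage 0.500); non-target hits 0 (specificity 1.000)

sorted <- simulate_sort(reads, sort_model(probe$sequence), seed = 103)
post   <- annotate_table(tally_tags(sorted, anc, sample_id = "post"),
                         db, max_mm = 2)
fold_enrichment(profile(tt, "pre"), profile(post, "post"), "Genus_4")
#> enrichment of 'Genus_4': 0.0104 -> 0.9338 (90.22 fold; 90 fold truncated)

imgs <- simulate_images(overlap_fraction = 0.8, seed = 104)
manders_mcc(imgs$ch1, imgs$ch2, 10, 10)
#> Manders' MCC: M1 = 0.800, M2 = 0.800
```

Reading the numbers: the probe is the 17 nt 5′ prefix of the genus's
dominant ribotag; its Tm advisory (50.1 °C) suggests ~5% formamide at the
46 °C reference. It covers 1 of the genus's 2 OTUs but hits nothing else
(specificity 1.0). One simulated sort takes the genus from 1.04% to 93.4%
of tags — a 90-fold enrichment once floor-truncated — with the uncovered
sibling OTU and carry-over accounting for the remainder. The constructed
image pair overlaps 80% voxel-for-voxel, and both Manders coefficients
recover 0.800 exactly.

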