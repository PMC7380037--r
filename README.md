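# trophodiet

Diet metabarcoding analysis of generalist consumers, contrasted with paired
environmental DNA.

High-throughput amplicon sequencing of stomach contents yields a MOTU-by-sample
read-count table: hundreds of molecular taxa per consumer, riddled with the
consumer's own DNA, tag-switching artefacts, contaminants and parasite reads.
`trophodiet` turns such tables into defensible diet descriptions for ecologists
studying trophic networks. It was built around the analysis pattern of
multi-estuary studies of the brown shrimp *Crangon crangon*, where pooled
stomach samples are paired with sediment eDNA samples from the same sites so
that what is *eaten* can be compared with what is *available*.

The package covers four stages, each usable on its own:

1. **Table I/O and validation** — a `motu_table` joins non-negative integer
   read counts to per-MOTU taxonomy and per-sample metadata (stomach /
   sediment / empty-stomach / negative-control), with strict cross-file
   validation and lossless TSV round-trips.
2. **Refinement cascade** (`run_cascade()`) — ordered, provenance-logged
   filters: merging MOTUs assigned to the same species; zeroing cells below 1%
   of a MOTU's total reads (tag-switching renormalization); removing bacterial
   / human / terrestrial contaminants by taxonomy rule; zeroing cells with
   four or fewer reads; discarding MOTUs with more than 10% of their reads in
   PCR-negative controls; removing the focal consumer (and other non-diet
   taxa such as a pervasive endoparasitic fungus); and dropping samples with
   fewer than 1,000 diet reads. Every stage reports MOTUs, samples and reads
   in/out, with removal reasons that reconcile exactly.
3. **Selectivity scoring** (`diet_summary()`, `phylum_summary()`) — per MOTU:
   presence, zero-inclusive mean relative read abundance, Jacobs' selectivity
   index evaluated on within-site (stomach, sediment) pairs,

   D = (r − p) / (r + p − 2 r p),   r = proportion in diet, p = in environment,

   and the trophic-significance score TS = a · f · (D + 1) (mean abundance ×
   presence fraction × shifted selectivity), binned High (> 10% of the TS
   total), Medium (1–10%) or Low (< 1%).
4. **Community statistics** — Bray–Curtis dissimilarities (optionally on
   square-root-transformed proportions), Mantel tests, one-way and nested
   PERMANOVA, Hurlbert rarefaction with a resampling counterpart, and
   sample-based MOTU accumulation curves after read rarefaction. These wrap
   vegan behind a seed-reproducible interface.

A synthetic-data generator (`simulate_diet_dataset()`) emulates the full
sampling design — paired stomach/sediment tables across estuaries and sites,
pooled stomachs, a ~28% focal-consumer read fraction, a ubiquitous fungal
taxon, multiplicative consumption preferences, tag-jump leakage and control
contamination — with complete ground truth, so every stage of the pipeline is
testable without any sequencing data.

## A worked example

Simulate a six-estuary study (24 sites, 72 pooled stomach samples, 24 sediment
eDNA samples, 3 PCR-negative controls), refine it, and score prey selectivity:

```r
library(trophodiet)

sim <- simulate_diet_dataset(sim_config(), seed = 7)
sim$table
#> motu_table: 35 MOTUs x 102 samples, 4,032,754 reads
#>   samples: stomach=72, sediment=24, empty_stomach=3, negative_control=3
#>   sites: 25 in 7 estuaries

res <- run_cascade(sim$table, filter_config())
res$report
#> filter_report: 7 stage(s)
#>   merge_species_motus        MOTUs 35 -> 35 | samples 102 -> 102 | reads 4,032,754 -> 4,032,754 (removed 0)
#>   renormalize_tag_switching  MOTUs 35 -> 35 | samples 102 -> 102 | reads 4,032,754 -> 3,587,376 (removed 445,378)
#>   remove_contaminants        MOTUs 35 -> 33 | samples 102 -> 102 | reads 3,587,376 -> 3,576,993 (removed 10,383)
#>   min_reads_filter           MOTUs 33 -> 33 | samples 102 -> 102 | reads 3,576,993 -> 3,576,989 (removed 4)
#>   negative_control_filter    MOTUs 33 -> 32 | samples 102 -> 99 | reads 3,576,989 -> 3,576,835 (removed 154)
#>   remove_focal_taxa          MOTUs 32 -> 30 | samples 99 -> 99 | reads 3,576,835 -> 1,274,945 (removed 2,301,890)
#>   sample_depth_filter        MOTUs 30 -> 30 | samples 99 -> 96 | reads 1,274,945 -> 1,274,945 (removed 0)
```

The focal consumer and the fungus dominate the raw stomach reads (64% here),
exactly as in real gut metabarcoding; the cascade removes them, the simulated
contaminants and the tag-jump noise. Selectivity of the surviving diet table
against the paired sediment samples:

```r
diet <- subset(res$table, sample_types = "stomach")
env  <- subset(res$table, sample_types = "sediment")
diet_summary(diet, env)
#> diet_summary: 13 MOTU(s) reported (threshold 0.005 mean rel. abundance) of 30; 72 stomach samples
#>           Phylum        Species Presence (%) Abundance (%) Selectivity (D)       TS Category
#>         Annelida Prey taxon 026         48.6     4.5 ± 0.6       1.0 ± 0.0 4.34e-02   Medium
#>       Arthropoda Prey taxon 025         69.4    21.1 ± 1.9       1.0 ± 0.0 2.93e-01     High
#>  Bacillariophyta Prey taxon 021         59.7     3.5 ± 0.4       0.9 ± 0.0 3.89e-02   Medium
#>  Bacillariophyta Prey taxon 029         20.8     1.4 ± 0.4       1.0 ± 0.0 5.66e-03      Low
#>         Chordata Prey taxon 012          4.2     0.8 ± 0.5      -1.0 ± 0.0 7.88e-06      Low
#>         Chordata Prey taxon 020         41.7     4.3 ± 0.7       0.8 ± 0.1 3.15e-02   Medium
#>         Chordata Prey taxon 028         50.0    15.9 ± 2.1       1.0 ± 0.0 1.59e-01     High
#>         Cnidaria Prey taxon 022         56.9     5.8 ± 0.8       1.0 ± 0.0 6.54e-02   Medium
#>         Cnidaria Prey taxon 030         45.8     9.4 ± 1.6       1.0 ± 0.0 8.59e-02   Medium
#>         Mollusca Prey taxon 019         41.7     0.9 ± 0.2       0.5 ± 0.1 5.29e-03      Low
#>         Mollusca Prey taxon 027         58.3    16.2 ± 2.0       1.0 ± 0.0 1.89e-01     High
#>       Rhodophyta Prey taxon 015         29.2     2.1 ± 0.4      -0.8 ± 0.0 1.19e-03      Low
#>       Rhodophyta Prey taxon 023         55.6    12.4 ± 1.5       1.0 ± 0.0 1.38e-01     High
```

Reading a row: "Prey taxon 025" occurred in 69.4% of retained stomach samples,
averaged 21.1% of diet reads, and was essentially absent from the paired
sediment (D = 1.0: exclusive selection), giving it the highest
trophic-significance share (High). Strongly avoided taxa (D near −1, e.g.
"Prey taxon 015", simulated with a preference weight far below 1) score Low
even when moderately abundant. Against the generator's truth, the estimated D
ordering recovers the simulated preference ordering with Spearman ρ ≈ 0.95.

The same records aggregate to phyla with `phylum_summary()`, community-level
contrasts run through `bray_curtis()`, `mantel_test()` and `permanova()`, and
`run_pipeline("pipeline.yaml", out_dir)` orchestrates the whole chain from one
config file (see `inst/cli/trophodiet.R` for a shell entry point).

The package also ships a published prey-selectivity summary for adult
*C. crangon* across six European estuaries (`read_prey_summary()`): 21
family-level-or-better prey MOTUs with ≥ 0.5% mean stomach abundance, of which
20 are resolved to species — handy as a reference for the reporting rules and
the TS arithmetic.

## Scope

The package starts from a MOTU table: raw-read bioinformatics (pair merging,
demultiplexing, chimera removal, clustering, taxonomic assignment) belongs to
upstream tools (obitools, SWARM, ecotag and kin). Ordination (nMDS, CCA) and
environmental-covariate modelling are out of scope; distance matrices are
exportable for those. No correction is attempted for digestion-rate,
PCR-recovery or secondary-predation biases.
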