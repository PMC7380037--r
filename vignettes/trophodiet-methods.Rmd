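---
title: "Methods: from MOTU tables to prey selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MOTU tables to prey selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophodiet)
```

## The problem

Gut-content metabarcoding of a generalist consumer produces a MOTU-by-sample
read-count table in which the biological signal — what the animal ate — is
buried under the consumer's own DNA (often the single largest read fraction),
parasites amplified from the gut tissue, reagent and handling contaminants,
and tag-switching artefacts that scatter a small fraction of every sample's
reads into other samples of the same sequencing library. The additional
question this package addresses is *selectivity*: given a paired sample of
the locally available community (here, sediment eDNA collected at the same
site), which prey are taken disproportionately to their availability?

`trophodiet` implements that workflow as four modules — validated table I/O,
a provenance-logged refinement cascade, per-taxon selectivity scoring, and
distance-based community comparison — plus a generative simulator with known
ground truth used throughout the test suite.

## The refinement cascade

`run_cascade()` applies, in a configurable order, seven stages. The default
order follows the natural narrative of a metabarcoding refinement: taxonomic
deduplication first, then read-level noise, then biological exclusions, then
sample-level exclusions.

| stage | rule (defaults) | boundary |
|---|---|---|
| `merge_species_motus` | MOTUs of rank *species* with identical names summed cell-wise; representative keeps the highest best-identity | — |
| `renormalize_tag_switching` | zero cells `< 1%` of the MOTU's total reads | strict `<` |
| `remove_contaminants` | drop MOTUs matching taxonomy rules (kingdom = Bacteria, Homo sapiens, …) | — |
| `min_reads_filter` | zero cells with four or fewer reads, drop emptied MOTUs | `≤ 4` removed |
| `negative_control_filter` | drop MOTUs with `> 10%` of reads in PCR-negative controls; controls consumed | strict `>` |
| `remove_focal_taxa` | drop the consumer and other designated non-diet taxa; log per-sample focal proportions | — |
| `sample_depth_filter` | drop stomach samples with `< 1000` remaining diet reads | strict `<` |

Inequality boundaries are deliberately asymmetric: the tag-switching and
negative-control rules are strict (a cell exactly at 1% of its MOTU's total,
or a MOTU with exactly 10% of reads in controls, is retained), while the
minimum-reads rule removes "four or fewer". These conventions follow the
usual phrasing of the corresponding refinement steps in COI metabarcoding
practice and are pinned by unit tests at the exact boundary values.

Two genuinely open design points are resolved as follows, with the
alternative kept selectable:

* **Cell-level vs. MOTU-level minimum reads.** "Removed on a sample-by-sample
  basis" is read as per-cell zeroing (`min_reads_mode = "cell"`), with rows
  that become all-zero dropped. The alternative — dropping any MOTU whose row
  maximum is below the threshold — is `min_reads_mode = "motu"`.
* **The renormalization rule.** Tag-jump correction procedures vary in
  detail across pipelines; the implementation here uses the row-fraction
  rule (zero any occurrence below `tag_switch_threshold` of the MOTU's total
  reads, default 1%) as a clean, testable formulation of the same idea. The
  threshold is exposed in `filter_config()`. Note the statistical character
  of this rule: with *n* samples, a MOTU spread evenly across samples has
  per-cell fractions near 1/*n*, so for studies with ≈100 samples the 1%
  default is only sensible because real MOTU distributions are strongly
  aggregated; see the simulator notes below.

Every stage emits a report record (MOTUs/samples/reads in and out, plus the
removed ids with reasons) and the suite asserts exact reconciliation:
`reads_in − reads_out` equals the sum of enumerated removals at every stage,
and stage *k*'s input equals stage *k−1*'s output. Threshold stages are
idempotent; `merge_species_motus` conserves reads exactly; no stage ever
increases a cell.

Negative-control columns are consumed by their stage: they inform the
control filter and never reach diet statistics. Empty-stomach samples are
carried as a sample type but excluded from diet statistics by default (they
fail the depth filter in practice, and `diet_summary()` only uses samples of
type `stomach`).

## Selectivity scoring

All selectivity quantities work on **relative read abundances** within a
sample. For a MOTU with diet proportion $r$ and environmental proportion
$p$, Jacobs' index

$$D = \frac{r - p}{r + p - 2rp} \in [-1, 1]$$

is $+1$ for exclusive selection, $0$ for consumption proportional to
availability, and $-1$ for total avoidance; unlike the raw forage ratio it
is insensitive to prey depletion. $D$ is undefined at $r = p = 0$ and
$r = p = 1$; the implementation returns `NA` there and the caller excludes
such pairs.

`paired_selectivity()` evaluates $D$ on every (stomach sample, same-site
sediment sample) pair and summarises per MOTU as the mean with a sample
standard error over informative pairs. Two conventions needed fixing:

* **Pair inclusion.** A pair where the MOTU occurs in neither member carries
  no electivity information and is excluded (default
  `pair_inclusion = "either"`); conditioning on stomach presence only is
  available as `"stomach"`. Excluding $0/0$ pairs rather than imputing a
  value is the only choice that avoids manufacturing selectivity out of
  shared absence.
* **SE definition.** The standard error is the sample SD over informative
  pairs divided by $\sqrt{n_\text{pairs}}$; a single informative pair
  reports SE 0 rather than NA so that "seen once, exclusively in the diet"
  prints as $1.0 \pm 0.0$.

The per-MOTU summary (`diet_summary()`) reports the zero-inclusive mean
relative abundance $a$ over **all** retained stomach samples (not only those
where the MOTU occurs — the convention under which a locally dominant but
patchy prey shows a modest study-wide mean), the presence fraction $f$, and
the trophic-significance score

$$TS = a \cdot f \cdot (D + 1) \in [0, 2],$$

using the MOTU's mean $D$. Each record's share `relative_TS = TS / ΣTS` is
normalised over **all** MOTUs (the reporting threshold of 0.5% mean
abundance only restricts which rows are shown; the full set is kept in
`attr(, "full")`). Categories: High above 10% of the TS total, Low below 1%,
Medium the closed interval between — the only exhaustive, order-preserving
completion of the conventional "high > 10%, medium 1–9%, low < 1%" bins.
Percent displays round half-up to one decimal; computations keep full
precision.

`phylum_summary()` aggregates counts to phylum *before* computing the same
descriptors, grouping MOTUs without a phylum assignment as `"unassigned"`.

## Community statistics

Bray–Curtis dissimilarities, the Mantel test, PERMANOVA, Hurlbert
rarefaction and accumulation curves are standard operations, delegated to
vegan behind a thin, seed-reproducible interface; the package's tests check
them against independently written oracles (direct formula evaluation, full
enumeration of label permutations at $n \le 6$, and the hypergeometric
closed form).

Numerical conventions:

* Permutation p-values use the add-one estimator $(1 + b)/(1 + m)$, which
  never returns zero; every permutation result records its seed and is
  bit-reproducible from it.
* Nested PERMANOVA (e.g. sites within estuaries) uses sequential sums of
  squares with the outer factor fitted first, and unrestricted permutation
  of labels. Restricted (strata-aware) permutation schemes are a sensible
  refinement but are not implemented; with unrestricted permutation the
  nested term's test is approximate.
* The square-root transform, when requested, applies to relative abundances
  (variance stabilisation for ordination-style analyses); proportions are
  not re-closed after transformation, matching standard practice.
* Rarefaction defaults to the closed form
  $E[S] = \sum_i \left(1 - \binom{N - N_i}{d} / \binom{N}{d}\right)$;
  the resampling estimator (default 500 draws) exists for parity with
  permutation-based workflows and agrees within Monte-Carlo error.
* Accumulation curves rarefy each sample once (a seeded draw without
  replacement) and then average cumulative richness over random sample
  orderings, so the endpoint equals the pooled richness of the rarefied
  samples and the curve is monotone.

## The simulator and what it does (not) emulate

`simulate_diet_dataset()` generates the full sampling design: 6 estuaries ×
4 sites × (1 pooled sediment sample + 3 pooled-stomach replicates of 8
stomachs), 3 empty-stomach pools, 3 PCR-negative controls. Its generative
model is deliberately the simplest one under which Jacobs' $D$ is a monotone
function of preference:

* a log-normal base community (σ = 1.5) perturbed per site by a Dirichlet
  draw — `site_concentration = 4` makes communities strongly aggregated, so
  that abundant taxa occur in roughly 20–55% of stomach samples while
  dominating locally, the pattern seen in real estuarine benthos (and the
  regime in which the 1% renormalization rule is meaningful at ≈100
  samples);
* diet proportions proportional to availability × preference,
  $r_s \propto p_s w$, with default preferences spanning 0.02–50 on a log
  scale;
* stomach samples drawn as one multinomial per pool over (focal taxon 28%,
  fungal taxon 36%, contaminants 0.3%, prey the remainder) at 50,000 reads;
  sediment samples at 18,000 reads with 1% focal and 0.1% fungal fractions.
  The sediment depth default matches the expected diet-informative reads
  per stomach pool (≈ 0.357 × 50,000), so that the consumed and available
  communities are observed with equal effort: with unequal effort the
  row-fraction renormalization rule zeroes the shallower side's cells
  preferentially and injects a spurious selectivity signal even under
  neutral consumption. Both depths are configurable for sensitivity work;
* tag-switching as read-conserving reassignment of a binomial fraction
  (default 0.2%) of each sample's reads to uniformly chosen other samples,
  controls included — a simplification of library cross-talk, whose rate the
  underlying studies do not quantify;
* reagent contamination of the controls as Poisson reads of a dedicated
  synthetic MOTU, so the negative-control filter has something real to
  remove.

Ground truth (per-site proportions, preferences, every injected jump and
contamination event, focal/fungal counts) is returned alongside the table,
and `recovery_report()` joins estimates against it.

What passing tests on this simulator demonstrate: that the cascade removes
exactly what its rules target, that selectivity estimation recovers
preference *rank order* (Spearman ρ ≥ 0.9 across replicate seeds at the
default depths) and is approximately unbiased under neutral consumption
(per-taxon mean $D$ averaged over 10 replicate seeds within ±0.15 for taxa
with ≥ 50 expected diet reads per sample — a bias bound; a single seed's
per-taxon mean $D$ carries sampling noise of SD ≈ 0.09 because threshold
crossings are correlated within sites). What they do **not** demonstrate:
robustness to PCR amplification bias, digestion-rate differences between
prey, secondary predation, primer affinity gaps (e.g. chlorophytes under COI
primers), or reference-database error — none of which the generator models.

## Problem sizes

The shipped tests run the default simulation (35 MOTUs × 102 samples,
~4 × 10⁶ reads) twenty times for the recovery checks, 500 exchangeable-null
replicates at n = 15 with 199 permutations each for the calibration checks,
and full permutation enumeration at n ≤ 6; the whole suite completes in
well under a minute on one CPU, and `scripts/acceptance.R` in a similar
time. These sizes were chosen to keep Monte-Carlo error well below the
asserted tolerances.

## Limitations

* Relative read abundance is treated as the analysis currency throughout;
  the package intentionally reports category bins (High/Medium/Low) for
  trophic significance because read proportions are at best
  semi-quantitative.
* The site pairing assumes exactly one (pooled) sediment sample per site;
  multiple sediment replicates must be combined before pairing.
* The nested PERMANOVA permutes labels freely; p-values for the outer
  factor should be read accordingly.
* The renormalization rule is a declared formalisation of tag-jump
  correction, not a reimplementation of any specific pipeline's script.
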