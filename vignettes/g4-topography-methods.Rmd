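---
title: "Methods: dual-method G4 detection and genomic topography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-method G4 detection and genomic topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4topo)
```

## The problem

G-quadruplexes (G4s) are four-stranded nucleic-acid structures formed
by stacked quartets of guanines.  Their genomic footprint — putative
G4-forming sequences — can be predicted from primary sequence, and
their placement relative to functional sites (promoters, terminators,
splice sites, replication origins) carries regulatory signal.  This
package implements a complete small-scale laboratory for that kind of
analysis: two complementary detectors, rules for reconciling their call
sets, density and metaprofile statistics, circular-chromosome strand
asymmetry around the replication origin, structural decomposition of
the calls, and a synthetic-genome generator that plants known structure
so every stage can be validated against ground truth.

## Detection

**Consensus motif (`scan_regex`).**  The canonical G4 consensus is
`G≥3 N1–7 G≥3 N1–7 G≥3 N1–7 G≥3`: four runs of at least three
guanines separated by loops of one to seven nucleotides.  Matching is
non-overlapping, left to right, with greedy run and loop quantifiers —
ordinary regular-expression semantics.  The reverse strand is scanned
on the reverse complement and coordinates are mapped back.  Two
conservative choices: loop characters are restricted to unambiguous
`A/C/G/T` (an ambiguity code cannot be asserted to form the structure),
and overlap handling *within* a method is delegated to `merge_hits()`,
which unions any spans sharing at least one base pair.  All grammar
parameters (`min_run`, `loop_min`, `loop_max`, `n_runs`) are exposed in
`detect_params()`.

**Windowed G-richness (`call_hunter`).**  Each base in a maximal run of
*k* guanines scores `+min(k, 4)`; each base in a C-run scores
`−min(k, 4)`; everything else scores zero and terminates runs.  Window
means over `w = 25` bp are thresholded at `s = 1.5` (the setting with
an estimated false-discovery rate below 10%): means `≥ s` seed G-rich
("+") regions, means `≤ −s` C-rich ("−") regions.  Overlapping
same-sign qualifying windows merge into one region, which is trimmed to
start and end on its majority letter.  The recorded score is the
maximum-magnitude qualifying window mean in the region, signed by
strand; a region-wide aggregate would also be defensible, but the
maximum is the sharper summary of "how strong is the best evidence
here" and keeps `|score| ≥ s` as an invariant.  The scoring rule is
exactly antisymmetric under reverse complement, which the tests assert
bit-for-bit.

## Reconciling call sets and densities

Two hits from different methods are "common" when their overlap covers
at least 50% of **either** span (equivalently, of the shorter span);
ties at the threshold count.  Mapping a catalog onto an external
reference interval set uses the same rule at 10%.  Both are
`findOverlaps`-based and are cross-checked against all-pairs oracles.

Density is reported in two flavours, because both appear in practice:
G4 base pairs per megabase examined (a coverage ratio) and G4 count per
megabase.  Subcompartment densities merge the compartment's annotations
first and then intersect with the merged catalog, so neither side is
double-counted.  An empty compartment is an error, not a zero — a
species without annotated exons has an undefined exonic density.

## Metaprofiles around anchor sites

Anchors are TSS and TES (5′ and 3′ gene ends in transcriptional
orientation) and splice donors/acceptors (intron boundaries, derived by
unioning exons per gene and taking the gaps).  For each anchor, offsets
run over `[-F, F)` with `F = 500` by default, increasing downstream in
the transcriptional direction; offset 0 is the anchor base.  A hit
contributes one count at **every** offset it covers (per-bp coverage —
the "distribution of G4 base pairs" reading; counting only hit starts
is available via `count_mode = "start"`).  Hits on the anchor's own
strand are tallied as nontemplate (sense), opposite-strand hits as
template.  Windows truncated by a contig edge simply contribute no
counts at the missing offsets; the enrichment divisor still uses the
full offset set, which matches a global-mean normalisation.

Enrichment at an offset is its pooled count divided by the mean count
over the window, so the mean enrichment is exactly 1 — an identity the
tests assert to 1e-9.  Cohorts are pooled by summing counts across
species before normalising (per-species averaging is possible by
normalising each profile first).  Confidence bands resample species
with replacement (default 1000 replicates), recompute the enrichment
per replicate, and take per-offset 2.5/97.5 percentiles; a
single-species cohort collapses the band onto the point estimate
exactly.

One numerical subtlety motivated an extra summary.  Per-bp coverage is
serially correlated along the window — one ~28-bp motif raises ~28
adjacent offsets together — so *per-offset* band exclusion is noisy
even when a regional effect is decisive.  `mc_region_band()` therefore
computes the band of the **mean enrichment over a region** under the
same resampling scheme; this is the summary used for recovery checks.

A second subtlety concerns normalisation when an effect fills half the
window.  If a factor *f* elevates the rate over the entire upstream
half, the window-mean-normalised upstream enrichment is bounded by
`2f/(f+1) < 2` regardless of *f* — the elevated half drags the
normaliser up.  The unbiased way to read a planted factor back is the
ratio of the upstream regional mean to a far-field regional mean (the
downstream half in the default design), which equals *f* in
expectation; `enrichment_profile()` and `mc_region_band()` accept
`reference_offsets` for exactly this purpose.  The default remains
window-mean normalisation.

## Circular chromosomes and the replication origin

The origin midpoint is `(start + end) / 2` of the annotated oriC span.
Positions map to signed offsets in `(-L/2, L/2]` via modular
arithmetic; the absolute offset is the circular distance
`min(|P−Q|, L−|P−Q|)`.  The chromosome is discretised into 1001 bins of
signed offset with the centre bin holding oriC and the extreme bins the
terminus.  (The alternative reading — centre bin at the terminus — is
rejected because the enrichment is defined *relative to oriC*; the
binning is oriC-centred and documented as such.)  A hit is assigned by
its midpoint, except that a hit spanning bin boundaries counts in every
bin it touches.  Forward- and reverse-strand hits are tallied
separately and each strand is normalised by its own mean bin count; a
strand with no hits gets an undefined (NA) enrichment rather than zero.

GC skew is `(G − C)/(G + C)` over non-overlapping 25-bp windows,
assigned to the bin of the window midpoint and averaged per bin;
windows with `G + C = 0` are skipped and counted, not scored zero,
because the statistic is a ratio.  Leading/lagging labelling is a
*convention*: under the default, the fork on the positive-offset
replichore moves towards increasing coordinates, so a "+" hit at
positive offset is leading-oriented.  The convention is invertible by a
flag and the GC-skew track is always reported alongside, so the
biological label is never hard-wired into stored counts.

Linear origin analyses (e.g. eukaryotic origin maps) use point origins
at span midpoints with a ±2-kb window, per-strand coverage counts, and
per-strand window-mean normalisation; `origins_with_hit_fraction()`
reports the fraction of origins with at least one catalog hit in the
window.

## Structural decomposition

`decompose_g4()` splits a sequence into maximal G-runs (≥3 by default)
and the loops between them.  The defining phrase for a G-run in the
source literature is ambiguous between ≥3 and >3; ≥3 is adopted
because it matches the consensus grammar, and `min_run` makes the
strict reading one argument away.  Windowed-score hits may begin or end
mid-loop after trimming, so leading/trailing non-run sequence is
captured as flanks and excluded from loops; flanks + runs + loops
always reconstruct the input exactly (property-tested on random
strings).  Note that loops of *scanned* hits may legally contain short
G tracts (regex backtracking), so loop-length support is only
guaranteed to be within `[loop_min, loop_max]` for motifs sampled from
the grammar.

## The synthetic-genome generator

`generate_genome()` emulates the statistical structure the analyses
assume, not real genomes:

* i.i.d. background at a configurable GC (default 0.45, mid-range for
  the genomes such surveys span); circular chromosomes realise a
  per-replichore skew by giving the forward strand G probability
  `gc·(1+a)/2` and C probability `gc·(1−a)/2` on the positive
  replichore and the mirror on the other, so the planted window skew is
  exactly `a`;
* non-overlapping gene models (uniform placement within per-gene
  blocks, ≥600-bp margins) with equal-length exons and derived introns;
* consensus motifs planted at a baseline rate (default 100 per Mb, a
  moderate-GC figure) genome-wide, plus `(factor − 1)`× extra rate in
  promoter windows (500 bp upstream of the TSS), terminator windows
  (500 bp downstream of the TES) and splice windows (±100 bp around
  intron boundaries), giving a total in-region rate of `factor ×`
  baseline;
* planted strands uniform on linear chromosomes and leading-oriented
  with probability `leading_bias` on circular ones.

Planted spans keep ≥8 bp of separation, and guard zones of 8 bp on
each side are scrubbed of the run letter so no planted run can extend
or bridge — this guarantees the scanner recovers every planted motif at
its exact coordinates, which the tests assert.  The genome is
re-scanned after planting: motifs that arise from the background are
*kept* and labelled (scrubbing them would distort composition), and
recovery measurements compare against this realized truth.  Two
consequences worth knowing: on skewed circular chromosomes
background-arising motifs are intrinsically leading-biased (the G-rich
strand *is* the leading strand), so bias recovery is measured on
planted motifs; and with compact gene models the splice windows fall
inside the TSS profile window, so promoter and splice factors should be
planted in separate cohorts when profiling (the analysis scripts do).

Cohorts draw per-species seeds from a master seed and jitter the
baseline rate log-normally (sd 0.1) so species differ in abundance;
everything is bit-reproducible given the seed.

What passing tests on these genomes do **not** show: real genomes have
isochores, repeats, skewed codon usage, correlated gene structure and
phylogenetic dependence between species.  The generator validates the
*algorithms* — coordinate handling, normalisation, resampling — not
biological effect sizes.

## Problem sizes and defaults

The recovery experiments use 50 linear species of 200 kb with 50 genes
and a 3× promoter factor, and 20 circular genomes of 500 kb with
leading bias 0.8 and skew amplitude 0.2 — large enough that binomial
error on the recovered quantities is a few percent, small enough to run
in seconds to minutes.  The demonstration scripts under `analysis/` use
16-species cohorts of the same shape.  Key defaults: window 25 bp,
threshold 1.5, score cap 4, flank 500 bp, 1001 circular bins, 25-bp
skew windows, 1000 Monte-Carlo replicates, overlap fractions 0.5
(cross-method) and 0.1 (reference mapping).

## Known limitations

* The windowed caller follows the published algorithm's structure
  (run-capped scores, window merging, majority-letter trimming) but is
  an independent implementation; region boundaries may differ from
  other implementations in edge cases of trimming.
* Hits never wrap the origin of the linear coordinate system on
  circular chromosomes (the generator avoids planting across it, and
  scanning treats the sequence linearly), matching common practice but
  slightly under-counting near position 0 on real circular genomes.
* Multi-origin chromosomes, RNA G4s, and thermodynamic stability are
  out of scope.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(genome_length = 200000L, n_genes = 50L,
                       promoter_factor = 3)
cohort <- generate_cohort(10L, spec, seed = 1L)
profs <- lapply(cohort, function(g) {
  hits <- merge_hits(scan_genome(g$genome, "regex"))
  genes <- g$features[g$features$kind == "gene", ]
  occupancy_profile(hits, collect_anchors(genes, "TSS"), 500L)
})
mc_region_band(profs, c(-500L, 0L), mc_params(1000L, seed = 2L),
               reference_offsets = 0:499)
```
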