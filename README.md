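# g4topo

Dual-method detection of putative G-quadruplex (G4) forming sequences
and analysis of their genomic topography.

G4s are four-stranded structures formed by stacked quartets of
guanines; their sequence signature — four G-runs separated by short
loops — can be mapped genome-wide, and where those motifs sit relative
to transcription start/end sites, splice sites and replication origins
is where the biology is.  `g4topo` is for computational biologists who
want that whole workflow in one auditable package: call motifs two
independent ways, reconcile the call sets, and measure densities,
strand-aware metaprofiles with resampling confidence bands, and
replication-associated strand asymmetry — with a synthetic-genome
generator that plants known structure so every step can be verified
against ground truth, no downloads required.

## Methods at a glance

* **Consensus motif scanner** — non-overlapping greedy matches of
  `G≥3 N1–7 G≥3 N1–7 G≥3 N1–7 G≥3` on both strands (`scan_regex`).
* **Windowed G-richness caller** — per-base scores (+k capped at 4 for
  a G-run of length k, negative for C-runs), window means over
  w = 25 bp thresholded at |s| ≥ 1.5, merged and trimmed to the
  majority letter (`call_hunter`).
* **Reconciliation** — two calls are common when their overlap covers
  ≥ 50% of either span; mapping onto external references uses the same
  rule at 10% (`common_hits`, `map_to_reference`).
* **Topography** — per-bp occupancy around TSS/TES/splice anchors in
  transcriptional orientation, template vs nontemplate, enrichment
  `E(o) = c(o) / mean(c)` (mean ≡ 1), and species-resampling
  Monte-Carlo bands, N = 1000 (`occupancy_profile`, `mc_confidence`).
* **Replication** — 1001 oriC-centred circular bins via
  `d(P,Q) = min(|P−Q|, L−|P−Q|)`, strand-split bin enrichment, 25-bp
  GC skew `(G−C)/(G+C)`, leading-strand fractions, and ±2-kb linear
  origin profiles (`bin_circular`, `gc_skew_binned`,
  `leading_fraction`).
* **Structure** — G-run/loop decomposition and length distributions
  (`decompose_g4`, `length_distributions`).
* **Simulation** — genomes with configurable GC, gene models with
  introns, planted motifs with promoter/terminator/splice rate factors,
  per-replichore GC skew and leading-strand bias, plus exact ground
  truth (`synthetic_spec`, `generate_genome`, `generate_cohort`).

See `vignettes/g4-topography-methods.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(g4topo)

# human-telomere-type repeat on "+", its complement motif on "-"
scan_regex("TTAGGGTTAGGGTTAGGGTTAGGGAAACCCGATCCCATTCCCTGTCCCT")
#>   contig_id start end strand method score              sequence
#> 1    contig     3  24      +  regex    NA GGGTTAGGGTTAGGGTTAGGG
#> 2    contig    27  48      -  regex    NA CCCGATCCCATTCCCTGTCCC

# plant a 3x promoter enrichment in ten 200-kb genomes and read it back
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
#> estimate      low     high
#> 2.868327 1.939505 5.028368
```

The `estimate` is the mean G4 coverage enrichment over the 500 bp
upstream of the TSS relative to the downstream far-field: the planted
3× factor is recovered (2.87), and the 95% resampling band excludes 1,
i.e. the upstream excess is not a cohort-sampling artefact.  Catalog
densities come in both field conventions:

```r
g <- cohort[[1]]
m <- merge_hits(scan_genome(g$genome, "both"), genome = g$genome)
genome_density(m, g$genome$length)
#>   region_label g4_bp g4_count region_bp density_bp_per_mb density_count_per_mb
#> 1       genome  1025       35    200000              5125                  175
```

## The analysis series

Numbered drivers under `analysis/` run the pipeline end to end on
demonstration cohorts and write tables under `results/`:

| script | what it shows |
|---|---|
| `01_simulate.R` | cohort simulation and planted/realized truth accounting |
| `02_detect.R` | both detectors plus 50%-rule reconciliation |
| `03_density.R` | genome/gene/exon/CDS/intron densities, gene-overlap fractions |
| `04_topography.R` | TSS/TES/splice metaprofiles with Monte-Carlo bands |
| `05_replication.R` | oriC-centred strand asymmetry and GC skew |
| `06_structure.R` | G-run/loop length distributions |

Run any of them from the repository root, e.g.
`Rscript analysis/04_topography.R`.

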