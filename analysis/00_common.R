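# Shared cohort definitions for the numbered analysis scripts.
# Every script regenerates what it needs from these fixed seeds, so each
# is independently runnable and the whole series is deterministic.

library(g4topo)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

# Demonstration cohort: annotated linear genomes with a 3x promoter
# planting factor (a small-scale version of the recovery experiment the
# acceptance script runs at full size).  Promoter and splice factors are
# planted in separate cohorts: with compact gene models the first splice
# window (+300 +/- 100 of the TSS) falls inside the TSS profile window,
# so mixing the factors would confound the promoter read-out.
demo_linear_cohort <- function() {
  spec <- synthetic_spec(genome_length = 200000L, n_genes = 50L,
                         promoter_factor = 3)
  generate_cohort(16L, spec, seed = 4001L)
}

demo_splice_cohort <- function() {
  spec <- synthetic_spec(genome_length = 200000L, n_genes = 50L,
                         splice_factor = 3)
  generate_cohort(16L, spec, seed = 4003L)
}

# Circular bacterial-like chromosomes with planted GC skew and
# leading-strand G4 bias.
demo_circular_cohort <- function() {
  spec <- synthetic_spec(genome_length = 200000L, topology = "circular",
                         skew_amp = 0.2, leading_bias = 0.8,
                         n_genes = 0L)
  generate_cohort(6L, spec, seed = 4002L)
}

scan_both <- function(genome) {
  list(regex = scan_genome(genome, "regex"),
       hunter = scan_genome(genome, "hunter"))
}
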