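#!/usr/bin/env Rscript
# G-run / loop decomposition of the catalog: length distributions of
# whole motifs, G-runs and loops.

source("analysis/00_common.R")

lin <- demo_linear_cohort()

hits <- do.call(rbind, lapply(lin, function(g)
  scan_genome(g$genome, "regex")))
ld <- length_distributions(hits)

tab <- rbind(cbind(table_name = "total_length", ld$total_length),
             cbind(table_name = "g_run_length", ld$g_run_length),
             cbind(table_name = "loop_length", ld$loop_length))
write_tsv_report(tab, file.path(RESULTS_DIR,
                                "06_length_distributions.tsv"))

wmed <- function(d) d$value[which(cumsum(d$count) >= sum(d$count) / 2)[1L]]
cat("Catalog of", nrow(hits), "consensus motifs:\n")
cat("  median motif length:", wmed(ld$total_length), "bp\n")
cat("  median G-run length:", wmed(ld$g_run_length), "bp\n")
cat("  median loop length: ", wmed(ld$loop_length), "bp",
    "(support", min(ld$loop_length$value), "-",
    max(ld$loop_length$value), ")\n")
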