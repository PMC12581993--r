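#!/usr/bin/env Rscript
# G4 density genome-wide and per genomic subcompartment, plus the
# fraction of genes harbouring at least one G4.

source("analysis/00_common.R")

lin <- demo_linear_cohort()

dens_rows <- list()
gene_rows <- list()
for (g in lin) {
  merged <- merge_hits(scan_genome(g$genome, "both"), genome = g$genome)
  d <- genome_density(merged, g$genome$length)
  for (k in c("gene", "exon", "CDS", "intron")) {
    f <- g$features[g$features$kind == k, , drop = FALSE]
    if (nrow(f) > 0L) d <- rbind(d, compartment_density(merged, f, k))
  }
  d$species <- g$genome$contig_id
  dens_rows[[g$genome$contig_id]] <- d
  gof <- gene_overlap_fraction(merged,
                               g$features[g$features$kind == "gene", ],
                               partition_by_biotype = TRUE)
  gof$species <- g$genome$contig_id
  gene_rows[[g$genome$contig_id]] <- gof
}
dens <- do.call(rbind, dens_rows)
gof <- do.call(rbind, gene_rows)
write_tsv_report(dens, file.path(RESULTS_DIR, "03_density.tsv"))
write_tsv_report(gof, file.path(RESULTS_DIR, "03_gene_overlap.tsv"))

avg <- tapply(dens$density_count_per_mb, dens$region_label, mean)
cat("Mean G4 density (count per Mb) by compartment:\n")
print(round(avg, 2))
cat("Median fraction of genes with >= 1 G4:",
    round(stats::median(gof$fraction[gof$set == "all"]), 3), "\n")
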