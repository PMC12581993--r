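#!/usr/bin/env Rscript
# Circular-chromosome analysis relative to oriC: strand-split binned
# enrichment, GC-skew co-track, and leading-strand fractions.

source("analysis/00_common.R")

circ <- demo_circular_cohort()

profiles <- list()
lead_n <- 0
lead_tot <- 0
for (g in circ) {
  planted <- g$truth$realized[g$truth$realized$origin == "planted", ,
                              drop = FALSE]
  lead_n <- lead_n + round(leading_fraction(planted, g$ori) *
                           nrow(planted))
  lead_tot <- lead_tot + nrow(planted)
  cp <- bin_circular(g$truth$realized, g$ori, 1001L)
  cp$gc_skew <- gc_skew_binned(g$genome[1L, , drop = FALSE], g$ori,
                               25L, 1001L)
  profiles[[g$genome$contig_id]] <- cp
}
pooled <- bin_enrichment(pool_circular(profiles))
tab <- circular_table(pooled)
tab$gc_skew <- round(tab$gc_skew, 4)
tab$enrichment_fwd <- round(tab$enrichment_fwd, 4)
tab$enrichment_rev <- round(tab$enrichment_rev, 4)
tab$offset_mid <- round(tab$offset_mid, 1)
write_tsv_report(tab, file.path(RESULTS_DIR, "05_origin_polar.tsv"))

ok <- !is.na(tab$gc_skew) & tab$offset_mid != 0
agree <- mean(sign(tab$gc_skew[ok]) == sign(tab$offset_mid[ok]))
d <- tab$enrichment_fwd - tab$enrichment_rev
right <- tab$offset_mid > 0
cat("Pooled leading-strand fraction of planted G4s:",
    round(lead_n / lead_tot, 3), "(planted bias 0.8)\n")
cat("GC-skew sign agrees with the replichore on",
    round(100 * agree, 1), "% of usable bins\n")
cat("Forward-minus-reverse enrichment: ",
    round(mean(d[right], na.rm = TRUE), 2), " (right replichore) vs ",
    round(mean(d[!right], na.rm = TRUE), 2),
    " (left) - the asymmetry reverses across oriC.\n", sep = "")
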