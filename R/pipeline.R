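#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> scan -> reconcile ->
#' density -> topography -> origin -> loops pipeline.  Omitted
#' parameters fall back to the standard analysis defaults (window 25,
#' threshold 1.5, flank 500, 1001 circular bins, 25-bp skew windows,
#' 1000 Monte-Carlo replicates, overlap fractions 0.5 and 0.1).
#'
#' @param synthetic [synthetic_spec()] used by the simulate stage.
#' @param detect [detect_params()].
#' @param mc [mc_params()].
#' @param flank Metaprofile half-window (bp).
#' @param n_bins Circular bins.
#' @param skew_window GC-skew window (bp).
#' @param common_min_frac Cross-method reconciliation overlap fraction.
#' @param reference_min_frac Reference-mapping overlap fraction.
#' @param out_dir Output directory.
#' @param seed Pipeline seed (drives simulation and Monte-Carlo).
#' @return List of class `g4_run_config`.
#' @export
run_config <- function(synthetic = synthetic_spec(),
                       detect = detect_params(),
                       mc = mc_params(),
                       flank = 500L, n_bins = 1001L, skew_window = 25L,
                       common_min_frac = 0.5, reference_min_frac = 0.1,
                       out_dir = tempfile("g4topo_run_"), seed = 1L) {
  stopifnot(inherits(synthetic, "g4_synthetic_spec"),
            inherits(detect, "g4_detect_params"),
            flank >= 1L, n_bins >= 3L, skew_window >= 1L,
            common_min_frac > 0, common_min_frac <= 1,
            reference_min_frac > 0, reference_min_frac <= 1)
  structure(list(synthetic = synthetic, detect = detect, mc = mc,
                 flank = as.integer(flank), n_bins = as.integer(n_bins),
                 skew_window = as.integer(skew_window),
                 common_min_frac = common_min_frac,
                 reference_min_frac = reference_min_frac,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "g4_run_config")
}

#' Run the full pipeline on one synthetic genome
#'
#' Stages, in dependency order: simulate the genome, scan with both
#' detectors, merge per method, reconcile the two call sets, compute
#' genome/compartment densities and gene-overlap fractions, build
#' TSS/TES (and, when introns exist, splice-site) profiles, run the
#' circular-origin analysis when the chromosome is circular, and
#' tabulate run/loop length distributions.  All outputs are written
#' deterministically (sorted rows, fixed column order, no timestamps),
#' so a rerun with the same config yields byte-identical files.
#'
#' @param config [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest data.frame.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "g4_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list()
  note <- function(stage, rows, file) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, rows = rows, file = file, stringsAsFactors = FALSE)
  }

  ## simulate
  sim_spec <- config$synthetic
  sim_spec$seed <- config$seed
  sim <- generate_genome(sim_spec)
  write_fasta(sim$genome, out("genome.fa"))
  write_gff_features(sim$features, out("annotation.gff3"))
  if (nrow(sim$truth$planted) > 0L)
    write_bed(data.frame(contig_id = sim$truth$planted$contig_id,
                         start = sim$truth$planted$start,
                         end = sim$truth$planted$end,
                         name = sim$truth$planted$category,
                         score = "0",
                         strand = sim$truth$planted$strand),
              out("truth.bed"))
  else writeLines(character(0), out("truth.bed"))
  note("simulate", nrow(sim$truth$planted), "truth.bed")

  ## scan
  rx <- scan_genome(sim$genome, "regex", config$detect)
  hu <- scan_genome(sim$genome, "hunter", config$detect)
  hits_bed <- function(h) data.frame(
    contig_id = h$contig_id, start = h$start, end = h$end,
    name = h$method,
    score = ifelse(is.na(h$score), "0", formatC(h$score, format = "g")),
    strand = h$strand)
  write_bed(hits_bed(rx), out("hits_regex.bed"))
  write_bed(hits_bed(hu), out("hits_hunter.bed"))
  note("scan_regex", nrow(rx), "hits_regex.bed")
  note("scan_hunter", nrow(hu), "hits_hunter.bed")

  ## reconcile
  venn <- common_hits(rx, hu, config$common_min_frac)
  write_tsv_report(venn$counts, out("venn.tsv"))
  note("reconcile", nrow(venn$pairs), "venn.tsv")

  ## density
  merged <- merge_hits(rbind(rx, hu), genome = sim$genome)
  dens <- genome_density(merged, sum(sim$genome$length))
  for (k in c("gene", "exon", "CDS", "intron")) {
    f <- sim$features[sim$features$kind == k, , drop = FALSE]
    if (nrow(f) > 0L)
      dens <- rbind(dens, compartment_density(merged, f, k))
  }
  write_tsv_report(dens, out("density.tsv"))
  genes <- sim$features[sim$features$kind == "gene", , drop = FALSE]
  if (nrow(genes) > 0L) {
    gof <- gene_overlap_fraction(merged, genes,
                                 partition_by_biotype = TRUE)
    write_tsv_report(gof, out("gene_overlap.tsv"))
    note("gene_overlap", nrow(gof), "gene_overlap.tsv")
  }
  note("density", nrow(dens), "density.tsv")

  ## topography
  profs <- list()
  if (nrow(genes) > 0L) {
    for (kind in c("TSS", "TES")) {
      anch <- collect_anchors(genes, kind)
      pr <- occupancy_profile(merged, anch, config$flank)
      if (sum(pr$counts_total) > 0L) pr <- enrichment_profile(pr)
      profs[[kind]] <- pr
      write_tsv_report(profile_table(pr),
                       out(paste0("profile_", tolower(kind), ".tsv")))
      note(paste0("topo_", tolower(kind)), pr$n_anchors,
           paste0("profile_", tolower(kind), ".tsv"))
    }
    introns <- sim$features[sim$features$kind == "intron", ,
                            drop = FALSE]
    if (nrow(introns) > 0L) {
      for (kind in c("SS5", "SS3")) {
        anch <- collect_anchors(introns, kind)
        pr <- occupancy_profile(merged, anch, config$flank)
        if (sum(pr$counts_total) > 0L) pr <- enrichment_profile(pr)
        profs[[kind]] <- pr
        write_tsv_report(profile_table(pr),
                         out(paste0("profile_", tolower(kind), ".tsv")))
        note(paste0("topo_", tolower(kind)), pr$n_anchors,
             paste0("profile_", tolower(kind), ".tsv"))
      }
    }
  }

  ## origin analysis (circular only)
  circ <- NULL
  if (!is.null(sim$ori)) {
    circ <- bin_enrichment(bin_circular(merged, sim$ori, config$n_bins))
    circ$gc_skew <- gc_skew_binned(sim$genome[1L, , drop = FALSE],
                                   sim$ori, config$skew_window,
                                   config$n_bins)
    write_tsv_report(circular_table(circ), out("origin_polar.tsv"))
    note("origin", circ$n_bins, "origin_polar.tsv")
  }

  ## loops
  ld <- length_distributions(merged[!is.na(merged$sequence), ,
                                    drop = FALSE])
  loops_df <- rbind(
    cbind(table_name = "total_length", ld$total_length),
    cbind(table_name = "g_run_length", ld$g_run_length),
    cbind(table_name = "loop_length", ld$loop_length))
  write_tsv_report(loops_df, out("loops.tsv"))
  note("loops", nrow(loops_df), "loops.tsv")

  ## manifest: parameter echo + row counts (no timestamps)
  man <- do.call(rbind, manifest)
  write_tsv_report(man, out("manifest.tsv"))
  echo <- data.frame(
    parameter = c("seed", "window", "threshold", "flank", "n_bins",
                  "skew_window", "mc_n_reps", "common_min_frac",
                  "reference_min_frac", "genome_length", "topology"),
    value = c(config$seed, config$detect$window,
              config$detect$threshold, config$flank, config$n_bins,
              config$skew_window, config$mc$n_reps,
              config$common_min_frac, config$reference_min_frac,
              sim_spec$genome_length, sim_spec$topology))
  write_tsv_report(echo, out("parameters.tsv"))

  invisible(list(sim = sim, hits_regex = rx, hits_hunter = hu,
                 merged = merged, venn = venn, density = dens,
                 profiles = profs, circular = circ, loops = ld,
                 manifest = man))
}
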