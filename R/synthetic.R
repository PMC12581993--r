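#' Specification for a synthetic genome with planted G4s
#'
#' Describes one simulated species: an i.i.d. background of the given
#' GC content (optionally a circular chromosome whose two replichores
#' carry opposite planted GC skew), non-overlapping gene models with
#' introns, and consensus G4 motifs planted at a baseline rate that is
#' multiplied near promoters, terminators and splice sites.  On
#' circular chromosomes planted motifs are leading-strand oriented with
#' probability `leading_bias`.
#'
#' @param genome_length Genome length in bp.
#' @param gc Background GC content in (0, 1).
#' @param topology `"linear"` or `"circular"`.
#' @param ori_mid Origin midpoint (circular; default the chromosome
#'   midpoint).
#' @param skew_amp Planted per-replichore GC skew in `[-1, 1]`: the
#'   positive-offset replichore gets forward-strand skew `+skew_amp`,
#'   the other `-skew_amp`.
#' @param n_genes Number of genes (0 for an unannotated chromosome).
#' @param exons_per_gene Exons per gene.
#' @param gene_len,exon_len Gene and exon lengths in bp.
#' @param baseline_g4_rate Planted G4s per Mb genome-wide.
#' @param promoter_factor,tes_factor,splice_factor Rate multipliers in
#'   the promoter window (500 bp upstream of the TSS), the terminator
#'   window (500 bp downstream of the TES) and the splice windows
#'   (+/- 100 bp around each intron boundary).
#' @param leading_bias Probability a planted motif on a circular
#'   chromosome is leading-oriented (0.5 = unbiased).
#' @param run_len_range,loop_len_range Integer ranges for planted
#'   G-run and loop lengths.
#' @param prot_coding_frac Fraction of genes labelled protein-coding.
#' @param contig_id Contig name.
#' @param seed RNG seed.
#' @return List of class `g4_synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length = 200000L, gc = 0.45,
                           topology = c("linear", "circular"),
                           ori_mid = NULL, skew_amp = 0,
                           n_genes = 50L, exons_per_gene = 3L,
                           gene_len = 2000L, exon_len = 300L,
                           baseline_g4_rate = 100,
                           promoter_factor = 1, tes_factor = 1,
                           splice_factor = 1, leading_bias = 0.5,
                           run_len_range = c(3L, 5L),
                           loop_len_range = c(1L, 7L),
                           prot_coding_frac = 0.8,
                           contig_id = "chr1", seed = 1L) {
  topology <- match.arg(topology)
  if (is.null(ori_mid)) ori_mid <- genome_length %/% 2L
  stopifnot(genome_length > 0L, gc > 0, gc < 1,
            skew_amp >= -1, skew_amp <= 1, n_genes >= 0L,
            baseline_g4_rate >= 0, promoter_factor >= 0,
            tes_factor >= 0, splice_factor >= 0,
            leading_bias >= 0, leading_bias <= 1,
            run_len_range[1L] >= 3L,
            diff(range(run_len_range)) >= 0,
            loop_len_range[1L] >= 1L)
  structure(list(
    genome_length = as.integer(genome_length), gc = gc,
    topology = topology, ori_mid = as.integer(ori_mid),
    skew_amp = skew_amp, n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    gene_len = as.integer(gene_len), exon_len = as.integer(exon_len),
    baseline_g4_rate = baseline_g4_rate,
    promoter_factor = promoter_factor, tes_factor = tes_factor,
    splice_factor = splice_factor, leading_bias = leading_bias,
    run_len_range = as.integer(run_len_range),
    loop_len_range = as.integer(loop_len_range),
    prot_coding_frac = prot_coding_frac,
    contig_id = contig_id, seed = as.integer(seed)),
    class = "g4_synthetic_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Draw one consensus G4 motif string
#'
#' Run lengths and loop lengths are uniform over their ranges; loop
#' bases are drawn from {A, C, T} so a loop can never extend an
#' adjacent G-run.  The result matches the consensus grammar as one
#' full-length hit.  Uses the current RNG state.
#'
#' @param run_len_range,loop_len_range Integer ranges `c(min, max)`.
#' @param n_runs Number of G-runs.
#' @return Uppercase motif string.
#' @export
sample_g4 <- function(run_len_range = c(3L, 5L),
                      loop_len_range = c(1L, 7L), n_runs = 4L) {
  rl <- run_len_range[1L] - 1L +
    sample.int(run_len_range[2L] - run_len_range[1L] + 1L, n_runs,
               replace = TRUE)
  ll <- loop_len_range[1L] - 1L +
    sample.int(loop_len_range[2L] - loop_len_range[1L] + 1L,
               n_runs - 1L, replace = TRUE)
  loops <- vapply(ll, function(k)
    paste(sample(c("A", "C", "T"), k, replace = TRUE), collapse = ""),
    character(1))
  parts <- character(2L * n_runs - 1L)
  parts[seq(1L, by = 2L, length.out = n_runs)] <- strrep("G", rl)
  parts[seq(2L, by = 2L, length.out = n_runs - 1L)] <- loops
  paste(parts, collapse = "")
}

# clip [start,end) regions to [0, L) and drop empties
.clip_regions <- function(df, L) {
  df$start <- pmax(df$start, 0L)
  df$end <- pmin(df$end, L)
  df[df$end > df$start, , drop = FALSE]
}

#' Generate one synthetic genome with planted G4s
#'
#' Produces the background sequence, gene/exon/CDS/intron annotation,
#' planted motifs with ground truth, and (for circular chromosomes) the
#' origin specification.  After planting, the genome is re-scanned so
#' the realized truth set reflects what a detector can actually see;
#' motifs that arise from the background are kept and labelled
#' `"background"`.
#'
#' @param spec [synthetic_spec()].
#' @return List: `genome` (data.frame as from [parse_fasta()]),
#'   `features`, `truth` (list `planted`, `realized`), `ori`
#'   ([origin_spec()] or NULL), `spec`.
#' @export
generate_genome <- function(spec) {
  .with_seed(spec$seed, .generate_genome_impl(spec))
}

.generate_genome_impl <- function(spec) {
  L <- spec$genome_length
  ct <- spec$contig_id
  guard <- spec$loop_len_range[2L] + 1L
  ori <- if (spec$topology == "circular")
    origin_spec(ct, spec$ori_mid, L, "circular") else NULL

  ## background sequence
  chars <- character(L)
  if (spec$topology == "circular" && spec$skew_amp != 0) {
    off <- signed_offset(0:(L - 1L), ori)
    right <- off > 0
    pg_r <- spec$gc * (1 + spec$skew_amp) / 2
    pc_r <- spec$gc * (1 - spec$skew_amp) / 2
    pat <- (1 - spec$gc) / 2
    chars[right] <- sample(c("A", "C", "G", "T"), sum(right),
                           replace = TRUE,
                           prob = c(pat, pc_r, pg_r, pat))
    chars[!right] <- sample(c("A", "C", "G", "T"), sum(!right),
                            replace = TRUE,
                            prob = c(pat, pg_r, pc_r, pat))
  } else {
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c((1 - spec$gc) / 2, spec$gc / 2,
                             spec$gc / 2, (1 - spec$gc) / 2))
  }

  ## gene models
  features <- NULL
  margin <- 600L
  if (spec$n_genes > 0L) {
    E <- spec$exons_per_gene
    intron_len <- if (E > 1L)
      (spec$gene_len - E * spec$exon_len) %/% (E - 1L) else 0L
    if (E > 1L && intron_len < 1L)
      stop("infeasible gene model: exons do not fit in gene_len")
    glen <- E * spec$exon_len + max(E - 1L, 0L) * intron_len
    block <- L %/% spec$n_genes
    if (block < glen + 2L * margin)
      stop("infeasible packing: ", spec$n_genes, " genes of ", glen,
           " bp (+", margin, " bp margins) do not fit in ", L, " bp")
    rows <- list()
    for (g in seq_len(spec$n_genes)) {
      b0 <- (g - 1L) * block
      gstart <- b0 + margin +
        sample.int(block - glen - 2L * margin + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      biotype <- if (stats::runif(1) < spec$prot_coding_frac)
        "protein_coding" else "noncoding"
      gid <- sprintf("g%03d", g)
      ex_starts <- gstart + (seq_len(E) - 1L) *
        (spec$exon_len + intron_len)
      rows[[g]] <- rbind(
        data.frame(contig_id = ct, start = gstart, end = gstart + glen,
                   strand = strand, kind = "gene", gene_id = gid,
                   biotype = biotype, stringsAsFactors = FALSE),
        data.frame(contig_id = ct, start = ex_starts,
                   end = ex_starts + spec$exon_len, strand = strand,
                   kind = "exon", gene_id = gid, biotype = biotype,
                   stringsAsFactors = FALSE),
        if (biotype == "protein_coding")
          data.frame(contig_id = ct, start = ex_starts,
                     end = ex_starts + spec$exon_len, strand = strand,
                     kind = "CDS", gene_id = gid, biotype = biotype,
                     stringsAsFactors = FALSE))
    }
    features <- do.call(rbind, rows)
    row.names(features) <- NULL
  } else {
    features <- data.frame(contig_id = character(), start = integer(),
                           end = integer(), strand = character(),
                           kind = character(), gene_id = character(),
                           biotype = character(), stringsAsFactors = FALSE)
  }
  genes <- features[features$kind == "gene", , drop = FALSE]
  introns <- derive_introns(features[features$kind == "exon", ,
                                     drop = FALSE])
  if (nrow(introns) > 0L) features <- rbind(features, introns)

  ## planting regions: factor-elevated windows + genome-wide baseline
  plus <- genes$strand == "+"
  reg <- list()
  if (nrow(genes) > 0L) {
    reg$promoter <- .clip_regions(data.frame(
      start = ifelse(plus, genes$start - 500L, genes$end),
      end = ifelse(plus, genes$start, genes$end + 500L)), L)
    reg$tes <- .clip_regions(data.frame(
      start = ifelse(plus, genes$end, genes$start - 500L),
      end = ifelse(plus, genes$end + 500L, genes$start)), L)
  }
  if (nrow(introns) > 0L) {
    b <- c(introns$start, introns$end)
    reg$splice <- .clip_regions(
      data.frame(start = b - 100L, end = b + 100L), L)
  }

  rate_bp <- spec$baseline_g4_rate / 1e6
  planted <- list()
  occupied <- IRanges::IRanges()   # planted spans inflated by the guard

  plant_set <- function(regions, rate_per_bp, category) {
    lens <- regions$end - regions$start
    lambda <- rate_per_bp * sum(lens)
    n <- stats::rpois(1L, lambda)
    if (n == 0L) return(NULL)
    out <- vector("list", n)
    for (k in seq_len(n)) {
      for (try in 1:50) {
        ri <- sample.int(nrow(regions), 1L, prob = lens)
        pos <- regions$start[ri] +
          sample.int(lens[ri], 1L) - 1L
        motif <- sample_g4(spec$run_len_range, spec$loop_len_range)
        len <- nchar(motif)
        if (pos - guard < 0L || pos + len + guard > L) next
        span <- IRanges::IRanges(pos + 1L - guard, pos + len + guard)
        if (length(IRanges::findOverlaps(span, occupied)) > 0L) next
        if (spec$topology == "circular") {
          offm <- signed_offset((2L * pos + len - 1L) %/% 2L, ori)
          lead <- stats::runif(1) < spec$leading_bias
          strand <- if ((offm > 0) == lead) "+" else "-"
        } else {
          strand <- sample(c("+", "-"), 1L)
        }
        occupied <<- c(occupied, span)
        out[[k]] <- data.frame(
          contig_id = ct, start = pos, end = pos + len,
          strand = strand, category = category,
          motif = motif, stringsAsFactors = FALSE)
        break
      }
    }
    do.call(rbind, out)
  }

  planted$background <- plant_set(
    data.frame(start = 0L, end = L), rate_bp, "background_rate")
  if (!is.null(reg$promoter) && spec$promoter_factor > 1)
    planted$promoter <- plant_set(reg$promoter,
                                  rate_bp * (spec$promoter_factor - 1),
                                  "promoter")
  if (!is.null(reg$tes) && spec$tes_factor > 1)
    planted$tes <- plant_set(reg$tes, rate_bp * (spec$tes_factor - 1),
                             "tes")
  if (!is.null(reg$splice) && spec$splice_factor > 1)
    planted$splice <- plant_set(reg$splice,
                                rate_bp * (spec$splice_factor - 1),
                                "splice")
  planted <- do.call(rbind, planted)

  ## write motifs into the background, with guard zones that cannot
  ## extend or bridge a planted run
  if (!is.null(planted) && nrow(planted) > 0L) {
    for (i in seq_len(nrow(planted))) {
      s <- planted$start[i]; e <- planted$end[i]
      m <- if (planted$strand[i] == "+") planted$motif[i]
           else revcomp(planted$motif[i])
      chars[(s + 1L):e] <- strsplit(m, "", fixed = TRUE)[[1L]]
      bad <- if (planted$strand[i] == "+") "G" else "C"
      gidx <- c((s - guard + 1L):s, (e + 1L):(e + guard))
      gidx <- gidx[gidx >= 1L & gidx <= L]
      hitg <- gidx[chars[gidx] == bad]
      if (length(hitg))
        chars[hitg] <- sample(c("A", "T"), length(hitg), replace = TRUE)
    }
    planted$sequence <- ifelse(planted$strand == "+", planted$motif,
                               vapply(planted$motif, revcomp,
                                      character(1), USE.NAMES = FALSE))
    if (spec$topology == "circular") {
      offm <- signed_offset(((planted$start + planted$end - 1L) %/% 2L),
                            ori)
      planted$orientation <- ifelse(
        (planted$strand == "+") == (offm > 0), "leading", "lagging")
    }
    planted$motif <- NULL
    planted <- planted[order(planted$start), , drop = FALSE]
    row.names(planted) <- NULL
  } else {
    planted <- data.frame(contig_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          category = character(), sequence = character(),
                          stringsAsFactors = FALSE)
  }

  genome <- data.frame(contig_id = ct,
                       sequence = paste(chars, collapse = ""),
                       length = L, topology = spec$topology,
                       stringsAsFactors = FALSE)

  ## realized truth: re-scan and label
  realized <- scan_regex(genome[1L, , drop = FALSE])
  if (nrow(realized) > 0L) {
    key <- paste(realized$start, realized$end, realized$strand)
    pkey <- paste(planted$start, planted$end, planted$strand)
    realized$origin <- ifelse(key %in% pkey, "planted", "background")
  } else {
    realized$origin <- character(0)
  }

  list(genome = genome, features = features,
       truth = list(planted = planted, realized = realized),
       ori = ori, spec = spec)
}

#' Generate a cohort of synthetic species
#'
#' Each species gets an independent seed drawn from the cohort seed and
#' a log-normally jittered baseline G4 rate, so species differ in
#' overall G4 abundance while sharing the planted structure.
#' Deterministic given `(seed, n_species, spec)`.
#'
#' @param n_species Number of species (>= 1).
#' @param spec Template [synthetic_spec()].
#' @param between_species_jitter SD of the log-normal rate jitter
#'   (0 = identical rates).
#' @param seed Cohort seed.
#' @return List of per-species results from [generate_genome()];
#'   species contigs are renamed `sp001`, `sp002`, ...
#' @export
generate_cohort <- function(n_species, spec,
                            between_species_jitter = 0.1, seed = 1L) {
  stopifnot(n_species >= 1L)
  draws <- .with_seed(seed, list(
    seeds = sample.int(2147483646L, n_species),
    jit = exp(stats::rnorm(n_species, 0, between_species_jitter))))
  lapply(seq_len(n_species), function(i) {
    sp <- spec
    sp$seed <- draws$seeds[i]
    sp$baseline_g4_rate <- spec$baseline_g4_rate * draws$jit[i]
    sp$contig_id <- sprintf("sp%03d", i)
    generate_genome(sp)
  })
}
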