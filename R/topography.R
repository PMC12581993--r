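#' Collect anchor sites from gene or intron features
#'
#' TSS is the 5' gene end in transcriptional orientation (start for "+",
#' end-1 for "-"); TES the 3' end.  For introns, SS5 (donor) is the
#' intron's transcriptional start boundary and SS3 (acceptor) its
#' transcriptional end boundary.
#'
#' @param features Gene features (for `TSS`/`TES`) or intron features
#'   (for `SS5`/`SS3`).
#' @param kind One of `"TSS"`, `"TES"`, `"SS5"`, `"SS3"`.
#' @return data.frame: `contig_id`, `position` (0-based bp), `strand`,
#'   `kind`, `gene_id`.
#' @export
collect_anchors <- function(features, kind = c("TSS", "TES", "SS5", "SS3")) {
  kind <- match.arg(kind)
  plus <- features$strand == "+"
  pos <- switch(kind,
    TSS = ifelse(plus, features$start, features$end - 1L),
    TES = ifelse(plus, features$end - 1L, features$start),
    SS5 = ifelse(plus, features$start, features$end - 1L),
    SS3 = ifelse(plus, features$end - 1L, features$start))
  data.frame(contig_id = features$contig_id, position = as.integer(pos),
             strand = features$strand, kind = kind,
             gene_id = features$gene_id, stringsAsFactors = FALSE,
             row.names = NULL)
}

.empty_profile <- function(kind, flank) {
  n <- 2L * flank
  structure(list(
    kind = kind, flank = flank, offsets = seq.int(-flank, flank - 1L),
    counts_template = integer(n), counts_nontemplate = integer(n),
    counts_total = integer(n), enrichment = NULL, ci_low = NULL,
    ci_high = NULL, n_species = 1L, n_anchors = 0L),
    class = "g4_profile")
}

#' Strand-aware occupancy profile around anchor sites
#'
#' For each anchor and offset o in [-flank, flank), the genomic position
#' is the anchor plus o oriented by the anchor strand (offsets increase
#' downstream in the transcriptional direction).  Each hit contributes
#' one count at every offset it covers (per-bp coverage).  Hits on the
#' anchor's own strand accrue to the nontemplate (sense) counts,
#' opposite-strand hits to the template counts.  Window positions off
#' the contig are simply absent (truncated windows, no padding).
#'
#' @param hits Hit data.frame.
#' @param anchors Anchor data.frame from [collect_anchors()] (one kind).
#' @param flank Half-window size F in bp; offsets span `[-F, F)`.
#' @param count_mode `"coverage"` (default, per-bp) or `"start"` (one
#'   count at the hit's 5' start offset only).
#' @return A `g4_profile` with counts filled.
#' @export
occupancy_profile <- function(hits, anchors, flank = 500L,
                              count_mode = c("coverage", "start")) {
  count_mode <- match.arg(count_mode)
  stopifnot(length(unique(anchors$kind)) <= 1L)
  prof <- .empty_profile(if (nrow(anchors)) anchors$kind[1L] else "TSS",
                         as.integer(flank))
  prof$n_anchors <- nrow(anchors)
  if (nrow(anchors) == 0L || nrow(hits) == 0L) return(prof)
  tmpl <- integer(2L * flank)
  ntmpl <- integer(2L * flank)
  for (ct in unique(anchors$contig_id)) {
    an <- anchors[anchors$contig_id == ct, , drop = FALSE]
    h <- hits[hits$contig_id == ct, , drop = FALSE]
    if (nrow(h) == 0L) next
    for (i in seq_len(nrow(an))) {
      p <- an$position[i]
      sel <- which(h$start < p + flank + 1L & h$end > p - flank)
      for (j in sel) {
        if (an$strand[i] == "+") {
          o1 <- h$start[j] - p
          o2 <- h$end[j] - p - 1L           # inclusive offset bounds
        } else {
          o1 <- p - h$end[j] + 1L
          o2 <- p - h$start[j]
        }
        if (count_mode == "start") {
          # 5' start of the hit in transcriptional orientation
          o1 <- if (an$strand[i] == "+") h$start[j] - p
                else p - h$end[j] + 1L
          o2 <- o1
        }
        o1 <- max(o1, -flank)
        o2 <- min(o2, flank - 1L)
        if (o1 > o2) next
        idx <- (o1 + flank + 1L):(o2 + flank + 1L)
        if (h$strand[j] == an$strand[i]) {
          ntmpl[idx] <- ntmpl[idx] + 1L
        } else {
          tmpl[idx] <- tmpl[idx] + 1L
        }
      }
    }
  }
  prof$counts_template <- tmpl
  prof$counts_nontemplate <- ntmpl
  prof$counts_total <- tmpl + ntmpl
  prof
}

#' Fill per-offset enrichment in a profile
#'
#' Enrichment at offset o is the total count at o divided by the mean
#' total count over a reference offset set (by default the full
#' window, so mean enrichment over the window is exactly 1).
#'
#' @param profile A `g4_profile` with counts.
#' @param reference_offsets Optional integer vector of offsets whose
#'   mean count is the normalisation denominator (default: all offsets,
#'   the window-mean normalisation).
#' @return The profile with `enrichment` filled.
#' @export
enrichment_profile <- function(profile, reference_offsets = NULL) {
  tot <- profile$counts_total
  if (sum(tot) == 0L) stop("empty profile: all counts are zero")
  denom <- if (is.null(reference_offsets)) mean(tot)
           else mean(tot[profile$offsets %in% reference_offsets])
  if (denom == 0) stop("reference offsets have zero mean count")
  profile$enrichment <- tot / denom
  profile$enrichment_template <-
    if (sum(profile$counts_template) > 0L)
      profile$counts_template / mean(profile$counts_template) else NULL
  profile$enrichment_nontemplate <-
    if (sum(profile$counts_nontemplate) > 0L)
      profile$counts_nontemplate / mean(profile$counts_nontemplate)
    else NULL
  profile
}

#' Pool per-species profiles
#'
#' @param profiles List of `g4_profile`s of one kind and flank.
#' @return A pooled `g4_profile` (counts summed; `n_species` set).
#' @export
pool_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  flank <- profiles[[1L]]$flank
  kind <- profiles[[1L]]$kind
  for (p in profiles) stopifnot(p$flank == flank, p$kind == kind)
  out <- .empty_profile(kind, flank)
  out$counts_template <- Reduce(`+`, lapply(profiles, `[[`,
                                            "counts_template"))
  out$counts_nontemplate <- Reduce(`+`, lapply(profiles, `[[`,
                                               "counts_nontemplate"))
  out$counts_total <- out$counts_template + out$counts_nontemplate
  out$n_species <- length(profiles)
  out$n_anchors <- sum(vapply(profiles, `[[`, integer(1), "n_anchors"))
  out
}

#' Monte-Carlo parameters
#'
#' @param n_reps Number of resampling replicates (the study default is
#'   1000).
#' @param lower_pct,upper_pct Percentile bounds of the band.
#' @param seed RNG seed.
#' @export
mc_params <- function(n_reps = 1000L, lower_pct = 2.5, upper_pct = 97.5,
                      seed = 1L) {
  stopifnot(n_reps >= 1L, lower_pct >= 0, lower_pct < upper_pct,
            upper_pct <= 100)
  list(n_reps = as.integer(n_reps), lower_pct = lower_pct,
       upper_pct = upper_pct, seed = as.integer(seed))
}

#' Monte-Carlo confidence bands over a species cohort
#'
#' Each replicate resamples the species with replacement (same count),
#' sums their counts, and recomputes the enrichment; the bands are the
#' per-offset lower/upper percentiles over replicates.  The returned
#' profile's point estimate is the pooled (all species, no resampling)
#' enrichment.  Fully reproducible given `mc$seed`.
#'
#' @param per_species_profiles List of count-filled `g4_profile`s, one
#'   per species.
#' @param mc [mc_params()].
#' @param reference_offsets Passed through to [enrichment_profile()].
#' @return Pooled `g4_profile` with `enrichment`, `ci_low`, `ci_high`.
#' @export
mc_confidence <- function(per_species_profiles, mc = mc_params(),
                          reference_offsets = NULL) {
  pooled <- pool_profiles(per_species_profiles)
  pooled <- enrichment_profile(pooled, reference_offsets)
  reps <- .mc_replicates(per_species_profiles, mc, pooled$offsets,
                         reference_offsets)
  qs <- apply(reps, 2L, stats::quantile,
              probs = c(mc$lower_pct, mc$upper_pct) / 100,
              na.rm = TRUE, names = FALSE)
  pooled$ci_low <- qs[1L, ]
  pooled$ci_high <- qs[2L, ]
  pooled
}

# replicate-by-offset matrix of resampled enrichments
.mc_replicates <- function(per_species_profiles, mc, offsets,
                           reference_offsets = NULL) {
  n_sp <- length(per_species_profiles)
  stopifnot(n_sp >= 1L)
  M <- do.call(rbind, lapply(per_species_profiles, `[[`, "counts_total"))
  ref_idx <- if (is.null(reference_offsets)) seq_along(offsets)
             else which(offsets %in% reference_offsets)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(mc$seed)
  reps <- matrix(NA_real_, nrow = mc$n_reps, ncol = ncol(M))
  for (r in seq_len(mc$n_reps)) {
    pick <- sample.int(n_sp, n_sp, replace = TRUE)
    tot <- colSums(M[pick, , drop = FALSE])
    denom <- mean(tot[ref_idx])
    reps[r, ] <- if (denom > 0) tot / denom else NA_real_
  }
  reps
}

#' Monte-Carlo band of a regional mean enrichment
#'
#' Resamples species with replacement exactly as [mc_confidence()] and
#' returns the percentile band of the mean enrichment over a region of
#' offsets, a steadier summary than per-offset bands when coverage is
#' serially correlated along the window (one hit spans many adjacent
#' offsets).
#'
#' @inheritParams mc_confidence
#' @param region_offsets Offsets over which the mean is taken (either a
#'   vector of offsets or a `c(from, to)` half-open range).
#' @return Named numeric: `estimate`, `low`, `high`.
#' @export
mc_region_band <- function(per_species_profiles, region_offsets,
                           mc = mc_params(), reference_offsets = NULL) {
  pooled <- pool_profiles(per_species_profiles)
  pooled <- enrichment_profile(pooled, reference_offsets)
  if (length(region_offsets) == 2L &&
      region_offsets[2L] > region_offsets[1L] + 1L)
    region_offsets <- seq.int(region_offsets[1L],
                              region_offsets[2L] - 1L)
  idx <- which(pooled$offsets %in% region_offsets)
  if (length(idx) == 0L) stop("empty offset range")
  reps <- .mc_replicates(per_species_profiles, mc, pooled$offsets,
                         reference_offsets)
  means <- rowMeans(reps[, idx, drop = FALSE])
  qs <- stats::quantile(means,
                        probs = c(mc$lower_pct, mc$upper_pct) / 100,
                        na.rm = TRUE, names = FALSE)
  c(estimate = mean(pooled$enrichment[idx]), low = qs[1L],
    high = qs[2L])
}

#' Mean enrichment over an offset range
#'
#' The regional fold-enrichment summary: mean of the per-offset
#' enrichment over the requested offsets.
#'
#' @param profile Enrichment-filled `g4_profile`.
#' @param offset_range Integer vector of offsets (within `[-F, F)`), or
#'   a length-2 `c(from, to)` range taken as `[from, to)`.
#' @return A single number.
#' @export
fold_enrichment_region <- function(profile, offset_range) {
  if (is.null(profile$enrichment)) stop("profile has no enrichment")
  if (length(offset_range) == 2L &&
      offset_range[2L] > offset_range[1L] + 1L)
    offset_range <- seq.int(offset_range[1L], offset_range[2L] - 1L)
  idx <- which(profile$offsets %in% offset_range)
  if (length(idx) == 0L) stop("empty offset range")
  mean(profile$enrichment[idx])
}

#' @export
print.g4_profile <- function(x, ...) {
  cat("g4_profile:", x$kind, " flank =", x$flank,
      " anchors =", x$n_anchors, " species =", x$n_species, "\n")
  cat("  total counts:", sum(x$counts_total), "\n")
  if (!is.null(x$enrichment))
    cat("  enrichment mean:", format(mean(x$enrichment)), "\n")
  invisible(x)
}

#' Profile as a tidy table
#'
#' @param profile A `g4_profile`.
#' @return data.frame: offset, counts, enrichment and bands when
#'   present.
#' @export
profile_table <- function(profile) {
  df <- data.frame(offset = profile$offsets,
                   counts_template = profile$counts_template,
                   counts_nontemplate = profile$counts_nontemplate,
                   counts_total = profile$counts_total)
  if (!is.null(profile$enrichment)) df$enrichment <- profile$enrichment
  if (!is.null(profile$ci_low)) {
    df$ci_low <- profile$ci_low
    df$ci_high <- profile$ci_high
  }
  df
}
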