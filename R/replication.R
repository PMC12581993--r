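#' Origin-of-replication specification for one chromosome
#'
#' For a circular chromosome the origin midpoint is `(start + end) / 2`
#' of the annotated oriC span.
#'
#' @param contig_id Contig name.
#' @param ori_mid 0-based origin midpoint in bp.
#' @param chrom_len Chromosome length in bp.
#' @param topology `"circular"` or `"linear"`.
#' @export
origin_spec <- function(contig_id, ori_mid, chrom_len,
                        topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(ori_mid >= 0, ori_mid < chrom_len)
  list(contig_id = contig_id, ori_mid = as.numeric(ori_mid),
       chrom_len = as.numeric(chrom_len), topology = topology)
}

#' Circular distance between two positions
#'
#' `d(P, Q) = min(|P - Q|, L - |P - Q|)`; symmetric and bounded by
#' `L / 2`.
#'
#' @param p,q Positions in `[0, chrom_len)` (vectorised).
#' @param chrom_len Chromosome length.
#' @return Distance(s) in bp.
#' @export
circ_distance <- function(p, q, chrom_len) {
  if (any(p < 0 | p >= chrom_len | q < 0 | q >= chrom_len))
    stop("positions must lie in [0, chrom_len)")
  d <- abs(p - q)
  pmin(d, chrom_len - d)
}

#' Signed circular offset from the origin
#'
#' Maps a position to a signed offset in `(-L/2, L/2]` relative to the
#' origin midpoint; the absolute value equals [circ_distance()] from
#' oriC.  Positive offsets form the "right" replichore under the
#' package's plotting convention.
#'
#' @param p Position(s) in `[0, chrom_len)`.
#' @param ori An [origin_spec()] with circular topology.
#' @return Signed offset(s) in bp.
#' @export
signed_offset <- function(p, ori) {
  if (ori$topology != "circular")
    stop("signed offsets are defined for circular chromosomes only")
  L <- ori$chrom_len
  if (any(p < 0 | p >= L)) stop("positions must lie in [0, chrom_len)")
  off <- ((p - ori$ori_mid + L / 2) %% L) - L / 2
  off[off == -L / 2] <- L / 2     # antipode maps to the positive bound
  off
}

.bin_of_offset <- function(off, L, n_bins) {
  b <- floor((off + L / 2) / (L / n_bins))
  pmin(pmax(b, 0), n_bins - 1L)
}

#' Bin hits on a circular chromosome relative to oriC
#'
#' The chromosome is discretised into `n_bins` bins of signed origin
#' offset; the centre bin `(n_bins - 1) / 2` holds offset 0 (oriC) and
#' the extreme bins the terminus.  A hit is assigned to the bin of its
#' midpoint, except that a hit spanning bin boundaries is counted in
#' every bin its span touches.  Forward- and reverse-strand hits are
#' tallied separately.
#'
#' @param hits Hit data.frame on the circular contig.
#' @param ori [origin_spec()].
#' @param n_bins Number of bins (odd; default 1001).
#' @return List of class `g4_circular_profile`: `n_bins`, `counts_fwd`,
#'   `counts_rev`, plus slots filled by [bin_enrichment()] and
#'   [gc_skew_binned()].
#' @export
bin_circular <- function(hits, ori, n_bins = 1001L) {
  n_bins <- as.integer(n_bins)
  L <- ori$chrom_len
  cf <- integer(n_bins)
  cr <- integer(n_bins)
  h <- hits[hits$contig_id == ori$contig_id, , drop = FALSE]
  for (i in seq_len(nrow(h))) {
    mid <- (h$start[i] + h$end[i] - 1L) %/% 2L
    b_mid <- .bin_of_offset(signed_offset(mid %% L, ori), L, n_bins)
    pos <- (h$start[i]:(h$end[i] - 1L)) %% L
    bins <- unique(.bin_of_offset(signed_offset(pos, ori), L, n_bins))
    if (length(bins) == 1L) bins <- b_mid
    if (h$strand[i] == "-") cr[bins + 1L] <- cr[bins + 1L] + 1L
    else cf[bins + 1L] <- cf[bins + 1L] + 1L
  }
  structure(list(n_bins = n_bins, chrom_len = L, counts_fwd = cf,
                 counts_rev = cr, enrichment_fwd = NULL,
                 enrichment_rev = NULL, gc_skew = NULL, n_genomes = 1L),
            class = "g4_circular_profile")
}

#' Pool circular profiles over genomes
#'
#' Per-genome binned counts are summed; GC-skew tracks are averaged
#' over genomes that carry one.
#'
#' @param profiles List of `g4_circular_profile`s with equal `n_bins`.
#' @export
pool_circular <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  nb <- profiles[[1L]]$n_bins
  for (p in profiles) stopifnot(p$n_bins == nb)
  out <- profiles[[1L]]
  out$counts_fwd <- Reduce(`+`, lapply(profiles, `[[`, "counts_fwd"))
  out$counts_rev <- Reduce(`+`, lapply(profiles, `[[`, "counts_rev"))
  skews <- lapply(profiles, `[[`, "gc_skew")
  skews <- skews[!vapply(skews, is.null, logical(1))]
  out$gc_skew <- if (length(skews))
    rowMeans(do.call(cbind, skews), na.rm = TRUE) else NULL
  out$enrichment_fwd <- NULL
  out$enrichment_rev <- NULL
  out$n_genomes <- length(profiles)
  out
}

#' Per-strand bin enrichment
#'
#' Enrichment of a bin is its count divided by the mean bin count of
#' the same strand (so the mean enrichment per strand is exactly 1).  A
#' strand with zero total counts gets `NA` enrichment (undefined, not
#' zero).
#'
#' @param profile A `g4_circular_profile` with counts.
#' @return The profile with `enrichment_fwd`/`enrichment_rev` filled.
#' @export
bin_enrichment <- function(profile) {
  norm <- function(cnt) {
    if (sum(cnt) == 0L) return(rep(NA_real_, length(cnt)))
    cnt / mean(cnt)
  }
  profile$enrichment_fwd <- norm(profile$counts_fwd)
  profile$enrichment_rev <- norm(profile$counts_rev)
  profile
}

#' Binned GC skew around the origin
#'
#' The chromosome is tiled with non-overlapping windows of
#' `window` bp; each window's skew is `(G - C) / (G + C)` on the
#' forward strand; windows with `G + C = 0` are skipped.  Each window is
#' assigned to the circular bin of its midpoint and the bin value is the
#' mean of its windows (`NA` for bins with no usable window).
#'
#' @param record One-row genome data.frame or sequence string.
#' @param ori [origin_spec()].
#' @param window Skew window in bp (default 25).
#' @param n_bins Number of circular bins.
#' @return Numeric vector of length `n_bins`; attribute
#'   `n_skipped_windows` counts G+C = 0 windows.
#' @export
gc_skew_binned <- function(record, ori, window = 25L, n_bins = 1001L) {
  g <- .get_seq(record)
  L <- nchar(g$seq)
  chars <- strsplit(g$seq, "", fixed = TRUE)[[1L]]
  cg <- cumsum(chars == "G")
  cc <- cumsum(chars == "C")
  n_win <- L %/% window
  if (n_win == 0L) {
    out <- rep(NA_real_, n_bins)
    attr(out, "n_skipped_windows") <- 0L
    return(out)
  }
  st <- (seq_len(n_win) - 1L) * window          # 0-based window starts
  en <- st + window
  gs <- cg[en] - c(0L, cg[st[-1L]])
  cs <- cc[en] - c(0L, cc[st[-1L]])
  tot <- gs + cs
  skew <- ifelse(tot > 0L, (gs - cs) / tot, NA_real_)
  mid <- st + window %/% 2L
  bins <- .bin_of_offset(signed_offset(mid, ori), L, n_bins)
  out <- rep(NA_real_, n_bins)
  ok <- !is.na(skew)
  agg <- tapply(skew[ok], bins[ok], mean)
  out[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  attr(out, "n_skipped_windows") <- sum(!ok)
  out
}

#' Fraction of hits in leading-strand orientation
#'
#' Under the default convention the fork on the positive-offset
#' replichore moves towards increasing coordinates, so a hit is
#' leading-oriented iff (strand "+" and its midpoint's signed offset
#' > 0) or (strand "-" and offset < 0).  Midpoints at exactly offset 0
#' are excluded.  The convention is invertible with `invert`.
#'
#' @param hits Strand-annotated hit data.frame (nonempty).
#' @param ori [origin_spec()] with circular topology.
#' @param invert Swap the leading/lagging labelling.
#' @return Fraction in `[0, 1]`.
#' @export
leading_fraction <- function(hits, ori, invert = FALSE) {
  h <- hits[hits$contig_id == ori$contig_id & hits$strand %in% c("+", "-"),
            , drop = FALSE]
  if (nrow(h) == 0L) stop("no stranded hits on ", ori$contig_id)
  mid <- ((h$start + h$end - 1L) %/% 2L) %% ori$chrom_len
  off <- signed_offset(mid, ori)
  keep <- off != 0
  h <- h[keep, , drop = FALSE]
  off <- off[keep]
  if (nrow(h) == 0L) stop("all hit midpoints at the origin")
  leading <- (h$strand == "+" & off > 0) | (h$strand == "-" & off < 0)
  if (invert) leading <- !leading
  mean(leading)
}

#' Per-strand occupancy and enrichment around linear origin points
#'
#' For origin midpoints on a linear chromosome, counts per-bp hit
#' coverage at each offset in `[-halfwin, halfwin)` split by hit
#' strand, and normalises each strand by its own window-mean count.
#'
#' @param hits Hit data.frame.
#' @param origins Interval data.frame; each origin is taken at the
#'   midpoint of its span.
#' @param halfwin Half-window in bp (default 2000, a 4-kb window).
#' @return data.frame: `offset`, `counts_fwd`, `counts_rev`,
#'   `enrichment_fwd`, `enrichment_rev` (enrichment `NA` for a strand
#'   with no counts).
#' @export
linear_origin_profile <- function(hits, origins, halfwin = 2000L) {
  n <- 2L * halfwin
  cf <- integer(n)
  cr <- integer(n)
  for (ct in unique(origins$contig_id)) {
    ors <- origins[origins$contig_id == ct, , drop = FALSE]
    h <- hits[hits$contig_id == ct, , drop = FALSE]
    if (nrow(h) == 0L) next
    mids <- (ors$start + ors$end - 1L) %/% 2L
    for (p in mids) {
      sel <- which(h$start < p + halfwin & h$end > p - halfwin)
      for (j in sel) {
        o1 <- max(h$start[j] - p, -halfwin)
        o2 <- min(h$end[j] - p - 1L, halfwin - 1L)
        if (o1 > o2) next
        idx <- (o1 + halfwin + 1L):(o2 + halfwin + 1L)
        if (h$strand[j] == "-") cr[idx] <- cr[idx] + 1L
        else cf[idx] <- cf[idx] + 1L
      }
    }
  }
  enr <- function(cnt) if (sum(cnt) == 0L) rep(NA_real_, n)
                       else cnt / mean(cnt)
  data.frame(offset = seq.int(-halfwin, halfwin - 1L),
             counts_fwd = cf, counts_rev = cr,
             enrichment_fwd = enr(cf), enrichment_rev = enr(cr))
}

#' Fraction of origins with at least one nearby hit
#'
#' @param origins Interval data.frame (nonempty); origins taken at span
#'   midpoints.
#' @param hits Hit data.frame.
#' @param halfwin Half-window in bp; an origin counts if its
#'   `[mid - halfwin, mid + halfwin + 1)` window shares >= 1 bp with a
#'   hit (`halfwin = 0` requires a hit covering the midpoint base).
#' @return Fraction in `[0, 1]`.
#' @export
origins_with_hit_fraction <- function(origins, hits, halfwin = 2000L) {
  stopifnot(nrow(origins) > 0L)
  has <- logical(nrow(origins))
  for (ct in unique(origins$contig_id)) {
    io <- which(origins$contig_id == ct)
    h <- hits[hits$contig_id == ct, , drop = FALSE]
    if (nrow(h) == 0L) next
    mids <- (origins$start[io] + origins$end[io] - 1L) %/% 2L
    win <- IRanges::IRanges(start = mids - halfwin + 1L,
                            end = mids + halfwin + 1L)
    has[io] <- IRanges::countOverlaps(win, .as_iranges(h)) > 0L
  }
  mean(has)
}

#' Circular profile as a tidy table
#'
#' @param profile A `g4_circular_profile`.
#' @return data.frame keyed by bin with signed offset midpoint, counts,
#'   enrichments and GC skew when present.
#' @export
circular_table <- function(profile) {
  nb <- profile$n_bins
  bw <- profile$chrom_len / nb
  df <- data.frame(
    bin = seq_len(nb) - 1L,
    offset_mid = (seq_len(nb) - 1L) * bw + bw / 2 - profile$chrom_len / 2,
    counts_fwd = profile$counts_fwd,
    counts_rev = profile$counts_rev)
  if (!is.null(profile$enrichment_fwd)) {
    df$enrichment_fwd <- profile$enrichment_fwd
    df$enrichment_rev <- profile$enrichment_rev
  }
  if (!is.null(profile$gc_skew)) df$gc_skew <- as.numeric(profile$gc_skew)
  df
}
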