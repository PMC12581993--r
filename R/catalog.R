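#' Reconcile two call sets under the fractional-overlap rule
#'
#' A pair (x in A, y in B) matches iff their overlap in bp is at least
#' `min_frac` times the length of either of the two spans (equivalently,
#' `min_frac` times the shorter span).  Ties at exactly the threshold
#' count as matched.  Each hit is "matched" if it has at least one
#' matching partner; `common` counts matched pairs.
#'
#' @param a,b Hit data.frames.
#' @param min_frac Fractional-overlap threshold in (0, 1]; 0.5 is the
#'   cross-method reconciliation rule.
#' @return A list with `counts` (data.frame: `only_a`, `only_b`,
#'   `common`, `matched_a`, `matched_b`) and `pairs` (data.frame of
#'   matched row indices `a_idx`, `b_idx`).
#' @export
common_hits <- function(a, b, min_frac = 0.5) {
  stopifnot(min_frac > 0, min_frac <= 1)
  pairs <- .frac_overlap_pairs(a, b, min_frac)
  counts <- data.frame(
    only_a = nrow(a) - length(unique(pairs$a_idx)),
    only_b = nrow(b) - length(unique(pairs$b_idx)),
    common = nrow(pairs),
    matched_a = length(unique(pairs$a_idx)),
    matched_b = length(unique(pairs$b_idx))
  )
  list(counts = counts, pairs = pairs)
}

.frac_overlap_pairs <- function(a, b, min_frac) {
  empty <- data.frame(a_idx = integer(), b_idx = integer())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  out <- list()
  for (ct in intersect(unique(a$contig_id), unique(b$contig_id))) {
    ia <- which(a$contig_id == ct)
    ib <- which(b$contig_id == ct)
    ra <- .as_iranges(a[ia, , drop = FALSE])
    rb <- .as_iranges(b[ib, , drop = FALSE])
    ov <- IRanges::findOverlaps(ra, rb)
    if (length(ov) == 0L) next
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(ra[qi], rb[si]))
    la <- IRanges::width(ra)[qi]
    lb <- IRanges::width(rb)[si]
    keep <- w >= min_frac * pmin(la, lb)
    if (any(keep))
      out[[ct]] <- data.frame(a_idx = ia[qi[keep]], b_idx = ib[si[keep]])
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Map hits onto a reference interval set
#'
#' A hit is matched iff it overlaps some reference interval by at least
#' `min_frac` of either span (default 10%, the experimental-concordance
#' rule).
#'
#' @param hits Hit data.frame.
#' @param reference Interval data.frame (`contig_id`, `start`, `end`).
#' @param min_frac Fractional-overlap threshold.
#' @return A list: `matched` (logical per hit), `fraction_matched`, and
#'   `pairs` (matched hit/reference index pairs).
#' @export
map_to_reference <- function(hits, reference, min_frac = 0.1) {
  stopifnot(min_frac > 0, min_frac <= 1)
  pairs <- .frac_overlap_pairs(hits, reference, min_frac)
  matched <- seq_len(nrow(hits)) %in% pairs$a_idx
  list(matched = matched,
       fraction_matched = if (nrow(hits)) mean(matched) else NA_real_,
       pairs = data.frame(hit_idx = pairs$a_idx, ref_idx = pairs$b_idx))
}

.density_row <- function(label, g4_bp, g4_count, region_bp) {
  data.frame(
    region_label = label,
    g4_bp = g4_bp,
    g4_count = g4_count,
    region_bp = region_bp,
    density_bp_per_mb = if (region_bp > 0) g4_bp / region_bp * 1e6 else NA,
    density_count_per_mb = if (region_bp > 0) g4_count / region_bp * 1e6
                           else NA,
    stringsAsFactors = FALSE
  )
}

#' Genome-wide G4 density
#'
#' Both density flavours are reported: G4 bp per Mb of sequence examined
#' (the bp-ratio definition) and G4 count per Mb.
#'
#' @param hits Hit data.frame, already merged (no double counting).
#' @param genome_bp Total bp examined (> 0).
#' @param label Region label for the report row.
#' @return One-row density report data.frame.
#' @export
genome_density <- function(hits, genome_bp, label = "genome") {
  if (genome_bp <= 0) stop("genome_bp must be positive")
  g4_bp <- sum(hits$end - hits$start)
  .density_row(label, g4_bp, nrow(hits), genome_bp)
}

#' G4 density within a genomic subcompartment
#'
#' Features are merged per contig first (overlapping annotations within
#' a subcompartment collapse); `g4_bp` is the total overlap between
#' merged hits and merged features, `region_bp` the total merged feature
#' length.  The count flavour counts hits with >= 1 bp in the merged
#' compartment.
#'
#' @param hits Hit data.frame (pre-merged).
#' @param features Feature data.frame of one kind.
#' @param label Region label.
#' @return One-row density report data.frame.
#' @export
compartment_density <- function(hits, features, label = "compartment") {
  if (nrow(features) == 0L)
    stop("no annotated compartment: empty feature set for ", label)
  g4_bp <- 0L
  region_bp <- 0L
  n_in <- 0L
  for (ct in unique(features$contig_id)) {
    rf <- IRanges::reduce(.as_iranges(
      features[features$contig_id == ct, , drop = FALSE]))
    region_bp <- region_bp + sum(IRanges::width(rf))
    h <- hits[hits$contig_id == ct, , drop = FALSE]
    if (nrow(h) == 0L) next
    rh <- IRanges::reduce(.as_iranges(h))
    g4_bp <- g4_bp + sum(IRanges::width(IRanges::intersect(rh, rf)))
    n_in <- n_in + sum(IRanges::countOverlaps(.as_iranges(h), rf) > 0L)
  }
  .density_row(label, g4_bp, n_in, region_bp)
}

#' Fraction of genes harbouring at least one G4
#'
#' A gene counts as harbouring a G4 if any hit shares >= 1 bp with its
#' span.  With `partition_by_biotype = TRUE` the fraction is also given
#' separately for protein-coding and noncoding genes.
#'
#' @param hits Hit data.frame.
#' @param genes Feature data.frame of kind `gene` (nonempty).
#' @param partition_by_biotype Also split by biotype.
#' @return data.frame with columns `set`, `n_genes`, `n_with_g4`,
#'   `fraction`.
#' @export
gene_overlap_fraction <- function(hits, genes,
                                  partition_by_biotype = FALSE) {
  stopifnot(nrow(genes) > 0L)
  has <- logical(nrow(genes))
  for (ct in unique(genes$contig_id)) {
    ig <- which(genes$contig_id == ct)
    h <- hits[hits$contig_id == ct, , drop = FALSE]
    if (nrow(h) == 0L) next
    has[ig] <- IRanges::countOverlaps(
      .as_iranges(genes[ig, , drop = FALSE]), .as_iranges(h)) > 0L
  }
  row <- function(set, idx) data.frame(
    set = set, n_genes = length(idx), n_with_g4 = sum(has[idx]),
    fraction = if (length(idx)) mean(has[idx]) else NA_real_,
    stringsAsFactors = FALSE)
  out <- row("all", seq_len(nrow(genes)))
  if (partition_by_biotype) {
    out <- rbind(out,
                 row("protein_coding",
                     which(genes$biotype == "protein_coding")),
                 row("noncoding", which(genes$biotype == "noncoding")))
  }
  out
}
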