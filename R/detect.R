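#' Detection parameters for both G4 callers
#'
#' Bundles the consensus-motif grammar (runs of at least `min_run` G,
#' `n_runs` runs, loops of `loop_min`..`loop_max` nucleotides) and the
#' windowed-score parameters (window width `window`, calling threshold
#' `threshold`, per-base run score capped at `score_cap`).  Defaults are
#' the standard G4 consensus G>=3 N1-7 x4 and the recommended windowed
#' settings w = 25, s = 1.5 (score threshold with an estimated FDR
#' below 10%).
#'
#' @param min_run Minimum G-run length (>= 2).
#' @param loop_min,loop_max Loop length bounds (1 <= loop_min <= loop_max).
#' @param n_runs Number of G-runs in the consensus (>= 2).
#' @param window Sliding-window width in bp (>= 1).
#' @param threshold Window-mean score threshold (> 0).
#' @param score_cap Cap on the per-base run score.
#' @return A list of class `g4_detect_params`.
#' @export
detect_params <- function(min_run = 3L, loop_min = 1L, loop_max = 7L,
                          n_runs = 4L, window = 25L, threshold = 1.5,
                          score_cap = 4L) {
  stopifnot(min_run >= 2L, loop_min >= 1L, loop_min <= loop_max,
            n_runs >= 2L, window >= 1L, threshold > 0, score_cap >= 1L)
  structure(list(min_run = as.integer(min_run),
                 loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max),
                 n_runs = as.integer(n_runs),
                 window = as.integer(window),
                 threshold = threshold,
                 score_cap = as.integer(score_cap)),
            class = "g4_detect_params")
}

.empty_hits <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             strand = character(), method = character(), score = numeric(),
             sequence = character(), stringsAsFactors = FALSE)
}

.hit_df <- function(contig_id, start, end, strand, method, score, sequence) {
  data.frame(contig_id = contig_id, start = as.integer(start),
             end = as.integer(end), strand = strand, method = method,
             score = score, sequence = sequence, stringsAsFactors = FALSE,
             row.names = NULL)
}

.get_seq <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    list(seq = x$sequence, id = x$contig_id)
  } else {
    list(seq = x, id = "contig")
  }
}

#' Scan for consensus G4 motifs with a regular expression
#'
#' Matches the grammar (G-run of >= `min_run`) x `n_runs`, interleaved
#' with loops of `loop_min`..`loop_max` unambiguous nucleotides, on the
#' forward strand; the reverse strand is scanned on the reverse
#' complement and coordinates are mapped back.  Matches are
#' non-overlapping per strand, found left to right with greedy run and
#' loop quantifiers.  Ambiguity letters (including N) match neither
#' runs nor loops.
#'
#' @param record A one-row genome data.frame (see [parse_fasta()]) or a
#'   plain uppercase sequence string.
#' @param params [detect_params()].
#' @param contig_id Contig name used when `record` is a bare string.
#' @return Hit data.frame: `contig_id`, `start`, `end` (0-based
#'   half-open, forward-reference coordinates), `strand`, `method`
#'   (`"regex"`), `score` (NA), `sequence` (forward-reference slice).
#' @export
scan_regex <- function(record, params = detect_params(),
                       contig_id = NULL) {
  g <- .get_seq(record)
  if (!is.null(contig_id)) g$id <- contig_id
  p <- params
  pat <- sprintf("G{%d,}(?:[ACGT]{%d,%d}G{%d,}){%d}",
                 p$min_run, p$loop_min, p$loop_max, p$min_run,
                 p$n_runs - 1L)
  fwd <- .regex_strand(g$seq, pat)
  L <- nchar(g$seq)
  rcm <- .regex_strand(revcomp(g$seq), pat)
  out <- list()
  if (nrow(fwd) > 0L)
    out$f <- .hit_df(g$id, fwd$start, fwd$end, "+", "regex", NA_real_,
                     substring(g$seq, fwd$start + 1L, fwd$end))
  if (nrow(rcm) > 0L) {
    st <- L - rcm$end
    en <- L - rcm$start
    ord <- order(st)
    out$r <- .hit_df(g$id, st[ord], en[ord], "-", "regex", NA_real_,
                     substring(g$seq, st[ord] + 1L, en[ord]))
  }
  if (length(out) == 0L) return(.empty_hits())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  row.names(res) <- NULL
  res
}

# non-overlapping greedy matches; returns 0-based half-open starts/ends
.regex_strand <- function(seq, pat) {
  m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(), end = integer()))
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L, end = as.integer(m) - 1L + len)
}

#' Per-base G/C run scores
#'
#' Every base in a maximal run of k consecutive G scores
#' `+min(k, score_cap)`; every base in a maximal run of k consecutive C
#' scores `-min(k, score_cap)`; all other characters score 0 and
#' terminate runs.
#'
#' @inheritParams scan_regex
#' @return Integer vector of per-base scores, one per base.
#' @export
base_scores <- function(record, params = detect_params()) {
  g <- .get_seq(record)
  chars <- strsplit(g$seq, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) return(integer(0))
  r <- rle(chars)
  val <- integer(length(r$lengths))
  isg <- r$values == "G"
  isc <- r$values == "C"
  val[isg] <- pmin(r$lengths[isg], params$score_cap)
  val[isc] <- -pmin(r$lengths[isc], params$score_cap)
  rep.int(val, r$lengths)
}

#' Call G4 regions with the windowed G-richness score
#'
#' Window means of [base_scores()] over every window of width `w` are
#' thresholded at `s` (G-rich, "+" strand) and `-s` (C-rich, "-"
#' strand); overlapping same-sign qualifying windows are merged into one
#' region, the region is trimmed to start and end on its majority letter
#' (G for "+", C for "-"), and the recorded score is the
#' maximum-magnitude qualifying window mean inside the region (signed:
#' negative for "-" regions).
#'
#' @inheritParams scan_regex
#' @return Hit data.frame with `method = "hunter"`.
#' @export
call_hunter <- function(record, params = detect_params(),
                        contig_id = NULL) {
  g <- .get_seq(record)
  if (!is.null(contig_id)) g$id <- contig_id
  w <- params$window
  s <- params$threshold
  n <- nchar(g$seq)
  if (n < w) {
    message("contig ", g$id, " shorter than window (", n, " < ", w,
            "); no windowed calls")
    return(.empty_hits())
  }
  sc <- base_scores(g$seq, params)
  cs <- cumsum(c(0, sc))
  means <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
  chars <- strsplit(g$seq, "", fixed = TRUE)[[1L]]
  pos <- .hunter_regions(which(means >= s), means, w, chars, "G")
  neg <- .hunter_regions(which(means <= -s), means, w, chars, "C")
  out <- list()
  if (nrow(pos) > 0L)
    out$p <- .hit_df(g$id, pos$start, pos$end, "+", "hunter", pos$score,
                     substring(g$seq, pos$start + 1L, pos$end))
  if (nrow(neg) > 0L)
    out$n <- .hit_df(g$id, neg$start, neg$end, "-", "hunter", neg$score,
                     substring(g$seq, neg$start + 1L, neg$end))
  if (length(out) == 0L) return(.empty_hits())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  row.names(res) <- NULL
  res
}

# idx: 1-based starts of qualifying windows; letter: majority letter
.hunter_regions <- function(idx, means, w, chars, letter) {
  if (length(idx) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      score = numeric()))
  win <- IRanges::IRanges(start = idx, end = idx + w - 1L)
  reg <- IRanges::reduce(win, min.gapwidth = 0L)
  ov <- IRanges::findOverlaps(win, reg)
  grp <- S4Vectors::subjectHits(ov)
  best <- vapply(split(abs(means[idx]), grp), max, numeric(1))
  sgn <- if (letter == "G") 1 else -1
  starts <- integer(length(reg)); ends <- integer(length(reg))
  keep <- logical(length(reg))
  for (i in seq_along(reg)) {
    a <- IRanges::start(reg)[i]; b <- IRanges::end(reg)[i]
    inside <- which(chars[a:b] == letter)
    if (length(inside) == 0L) next     # cannot happen for |mean| >= s > 0
    keep[i] <- TRUE
    starts[i] <- a + inside[1L] - 1L
    ends[i] <- a + inside[length(inside)] - 1L
  }
  data.frame(start = starts[keep] - 1L, end = ends[keep],
             score = sgn * unname(best)[keep])
}

#' Merge overlapping hits
#'
#' Hits sharing at least one bp are replaced by their union span,
#' per contig and (by default) per strand.  When constituents come from
#' different methods the merged hit's method is `"merged"`; the score is
#' the maximum-magnitude constituent score; sequences are re-extracted
#' from `genome` when supplied, else dropped.
#'
#' @param hits Hit data.frame.
#' @param across_strands Merge regardless of strand; mixed-strand merges
#'   get strand `"."`.
#' @param genome Optional genome data.frame to refill `sequence`.
#' @return Merged hit data.frame.
#' @export
merge_hits <- function(hits, across_strands = FALSE, genome = NULL) {
  if (nrow(hits) == 0L) return(.empty_hits())
  key <- if (across_strands) hits$contig_id
         else paste(hits$contig_id, hits$strand)
  pieces <- lapply(split(seq_len(nrow(hits)), key), function(i) {
    h <- hits[i, , drop = FALSE]
    ir <- .as_iranges(h)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)  # abutting spans share
    ov <- IRanges::findOverlaps(ir, red)           # no bp: keep separate
    grp <- S4Vectors::subjectHits(ov)
    meth <- vapply(split(h$method, grp), function(m) {
      u <- unique(m); if (length(u) == 1L) u else "merged"
    }, character(1))
    strand <- vapply(split(h$strand, grp), function(s) {
      u <- unique(s); if (length(u) == 1L) u else "."
    }, character(1))
    sco <- vapply(split(h$score, grp), function(s) {
      s <- s[!is.na(s)]
      if (length(s) == 0L) NA_real_ else s[which.max(abs(s))]
    }, numeric(1))
    .hit_df(h$contig_id[1L], IRanges::start(red) - 1L, IRanges::end(red),
            unname(strand), unname(meth), unname(sco), NA_character_)
  })
  res <- do.call(rbind, pieces)
  if (!is.null(genome)) {
    seqs <- stats::setNames(genome$sequence, genome$contig_id)
    res$sequence <- substring(seqs[res$contig_id], res$start + 1L, res$end)
  }
  res <- res[order(res$contig_id, res$start, res$end, res$strand), ,
             drop = FALSE]
  row.names(res) <- NULL
  res
}

#' Scan a whole genome with one or both methods
#'
#' @param genome Genome data.frame from [parse_fasta()].
#' @param method `"regex"`, `"hunter"`, or `"both"`.
#' @param params [detect_params()].
#' @param merge Merge overlapping per-method calls per strand first.
#' @return Hit data.frame over all contigs.
#' @export
scan_genome <- function(genome, method = c("both", "regex", "hunter"),
                        params = detect_params(), merge = FALSE) {
  method <- match.arg(method)
  out <- list()
  for (i in seq_len(nrow(genome))) {
    rec <- genome[i, , drop = FALSE]
    if (method %in% c("both", "regex"))
      out[[paste0(i, "r")]] <- scan_regex(rec, params)
    if (method %in% c("both", "hunter"))
      out[[paste0(i, "h")]] <- call_hunter(rec, params)
  }
  res <- if (length(out)) do.call(rbind, out) else .empty_hits()
  row.names(res) <- NULL
  if (merge) res <- merge_hits(res, genome = genome)
  res
}
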