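# Independent brute-force oracles used to cross-check the package's
# interval and scanning algorithms.  These deliberately re-derive every
# quantity from first principles (recursive grammar matching, per-window
# recomputation, all-pairs overlap, per-base bitmaps) and share no code
# with the implementation paths they check.

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Greedy backtracking matcher for the consensus grammar, mirroring
# standard regex semantics (leftmost match, quantifiers prefer longest).
# Returns the 1-based inclusive end of the match starting at `pos`, or
# NA.  `chars` is the character vector of the sequence.
oracle_match_end <- function(chars, pos, p = detect_params()) {
  n <- length(chars)
  acgt <- c("A", "C", "G", "T")
  rec <- function(i, runs_left) {
    k <- 0L
    while (i + k <= n && chars[i + k] == "G") k <- k + 1L
    if (k < p$min_run) return(NA_integer_)
    if (runs_left == 1L) return(i + k - 1L)
    for (rl in seq.int(k, p$min_run)) {
      j <- i + rl
      for (ll in seq.int(p$loop_max, p$loop_min)) {
        jl <- j + ll
        if (jl > n + 1L || jl - 1L + p$min_run > n + 1L) next
        if (!all(chars[j:(jl - 1L)] %in% acgt)) next
        r <- rec(jl, runs_left - 1L)
        if (!is.na(r)) return(r)
      }
    }
    NA_integer_
  }
  rec(pos, p$n_runs)
}

# Non-overlapping left-to-right forward-strand scan by direct grammar
# matching; returns 0-based half-open spans.
oracle_regex_strand <- function(seq, p = detect_params()) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  starts <- integer(0)
  ends <- integer(0)
  i <- 1L
  while (i <= n) {
    e <- oracle_match_end(chars, i, p)
    if (!is.na(e)) {
      starts <- c(starts, i - 1L)
      ends <- c(ends, e)
      i <- e + 1L
    } else i <- i + 1L
  }
  data.frame(start = starts, end = ends)
}

# Both-strand oracle in forward-reference coordinates.
oracle_regex <- function(seq, p = detect_params()) {
  fwd <- oracle_regex_strand(seq, p)
  rc <- oracle_regex_strand(g4topo::revcomp(seq), p)
  L <- nchar(seq)
  rbind(
    if (nrow(fwd)) cbind(fwd, strand = "+"),
    if (nrow(rc)) data.frame(start = sort(L - rc$end),
                             end = sort(L - rc$start), strand = "-"))
}

# Recompute every window mean from scratch (no cumulative sums).
oracle_window_means <- function(scores, w) {
  n <- length(scores)
  vapply(seq_len(n - w + 1L),
         function(i) sum(scores[i:(i + w - 1L)]) / w, numeric(1))
}

# All-pairs fractional-overlap oracle: matched pairs under the
# "either sequence" rule.
oracle_frac_pairs <- function(a, b, min_frac) {
  pairs <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$contig_id[i] != b$contig_id[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov <= 0) next
    la <- a$end[i] - a$start[i]
    lb <- b$end[j] - b$start[j]
    if (ov >= min_frac * la || ov >= min_frac * lb)
      pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  if (length(pairs) == 0L)
    return(data.frame(a_idx = integer(), b_idx = integer()))
  m <- do.call(rbind, pairs)
  data.frame(a_idx = m[, 1L], b_idx = m[, 2L])
}

# Pairwise repeated-union merge oracle (O(n^2) passes until fixpoint).
oracle_merge_spans <- function(start, end) {
  s <- start
  e <- end
  repeat {
    n <- length(s)
    merged <- FALSE
    for (i in seq_len(max(n - 1L, 0L))) {
      for (j in (i + 1L):n) {
        if (s[i] < e[j] && s[j] < e[i]) {      # share >= 1 bp
          s[i] <- min(s[i], s[j])
          e[i] <- max(e[i], e[j])
          s <- s[-j]
          e <- e[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  ord <- order(s)
  data.frame(start = s[ord], end = e[ord])
}

# Per-base bitmap oracle for compartment overlap bp on a toy genome.
oracle_overlap_bp <- function(hits, features, genome_len) {
  inh <- logical(genome_len)
  for (i in seq_len(nrow(hits)))
    inh[(hits$start[i] + 1L):hits$end[i]] <- TRUE
  inf <- logical(genome_len)
  for (i in seq_len(nrow(features)))
    inf[(features$start[i] + 1L):features$end[i]] <- TRUE
  sum(inh & inf)
}

random_intervals <- function(n, contigs = c("c1", "c2"), span = 10000L,
                             max_len = 200L) {
  st <- sample.int(span, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(contig_id = sample(contigs, n, replace = TRUE),
             start = st, end = st + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             method = "regex", score = NA_real_,
             sequence = NA_character_, stringsAsFactors = FALSE)
}

make_hits <- function(contig_id, start, end, strand = "+",
                      method = "regex", score = NA_real_) {
  data.frame(contig_id = contig_id, start = as.integer(start),
             end = as.integer(end), strand = strand, method = method,
             score = score, sequence = NA_character_,
             stringsAsFactors = FALSE)
}
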