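#' Decompose a G4 sequence into G-runs and loops
#'
#' Maximal runs of at least `min_run` consecutive G are G-runs;
#' everything between consecutive G-runs is a loop.  Sequence before
#' the first run / after the last run (possible for windowed-score hits
#' after trimming) is recorded as flanks, not loops.  A sequence with
#' fewer than two G-runs is flagged non-canonical and has no loops.
#'
#' @param sequence Nonempty uppercase nucleotide string.
#' @param min_run Minimum run length (default 3; the strict "more than
#'   three" reading is `min_run = 4`).
#' @return List of class `g4_decomposition`: `g_run_lengths`,
#'   `loop_sequences`, `loop_lengths`, `flank_left`, `flank_right`,
#'   `total_length`, `gc_fraction`, `canonical`.
#' @export
decompose_g4 <- function(sequence, min_run = 3L) {
  stopifnot(nchar(sequence) > 0L)
  pat <- sprintf("G{%d,}", min_run)
  m <- gregexpr(pat, sequence)[[1L]]
  if (m[1L] == -1L) {
    runs <- integer(0)
    starts <- integer(0)
  } else {
    runs <- attr(m, "match.length")
    starts <- as.integer(m)
  }
  n <- length(runs)
  loops <- character(0)
  if (n >= 2L) {
    ls <- starts[-n] + runs[-n]
    le <- starts[-1L] - 1L
    loops <- substring(sequence, ls, le)
    loops[le < ls] <- ""
  }
  fl <- if (n > 0L && starts[1L] > 1L)
    substring(sequence, 1L, starts[1L] - 1L) else ""
  fr <- if (n > 0L && starts[n] + runs[n] - 1L < nchar(sequence))
    substring(sequence, starts[n] + runs[n], nchar(sequence)) else ""
  if (n == 0L) { fl <- sequence; fr <- "" }
  structure(list(
    g_run_lengths = as.integer(runs),
    loop_sequences = loops,
    loop_lengths = nchar(loops),
    flank_left = fl,
    flank_right = fr,
    total_length = nchar(sequence),
    gc_fraction = tryCatch(gc_fraction(sequence),
                           error = function(e) NA_real_),
    canonical = n >= 2L
  ), class = "g4_decomposition")
}

#' Reconstruct the input from a decomposition
#' @param d A `g4_decomposition`.
#' @return The original sequence.
#' @export
reconstruct_g4 <- function(d) {
  n <- length(d$g_run_lengths)
  core <- ""
  if (n > 0L) {
    parts <- character(2L * n - 1L)
    parts[seq(1L, 2L * n - 1L, by = 2L)] <-
      strrep("G", d$g_run_lengths)
    if (n > 1L) parts[seq(2L, 2L * n - 2L, by = 2L)] <- d$loop_sequences
    core <- paste(parts, collapse = "")
  }
  paste0(d$flank_left, core, d$flank_right)
}

#' Tabulate length distributions over a hit catalog
#'
#' @param hits Hit data.frame carrying `sequence`.
#' @param min_run Passed to [decompose_g4()].
#' @return List of data.frames `total_length`, `g_run_length`,
#'   `loop_length`, each with columns `value`, `count`.
#' @export
length_distributions <- function(hits, min_run = 3L) {
  tab <- function(x) {
    if (length(x) == 0L)
      return(data.frame(value = integer(), count = integer()))
    t <- table(x)
    data.frame(value = as.integer(names(t)), count = as.integer(t))
  }
  if (nrow(hits) == 0L)
    return(list(total_length = tab(integer(0)),
                g_run_length = tab(integer(0)),
                loop_length = tab(integer(0))))
  decs <- lapply(hits$sequence, decompose_g4, min_run = min_run)
  list(
    total_length = tab(vapply(decs, `[[`, integer(1), "total_length")),
    g_run_length = tab(unlist(lapply(decs, `[[`, "g_run_lengths"))),
    loop_length = tab(unlist(lapply(decs, `[[`, "loop_lengths")))
  )
}

#' GC fraction of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; ambiguity letters are excluded
#' from both numerator and denominator.
#'
#' @param sequence Nonempty nucleotide string.
#' @return Real in `[0, 1]`.
#' @export
gc_fraction <- function(sequence) {
  stopifnot(nchar(sequence) > 0L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  denom <- sum(chars %in% c("A", "C", "G", "T"))
  if (denom == 0L) stop("no unambiguous bases in sequence")
  sum(chars %in% c("G", "C")) / denom
}
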