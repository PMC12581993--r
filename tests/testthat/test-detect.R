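test_that("consensus scanner finds the minimal motif on both strands", {
  h <- scan_regex("GGGTGGGTGGGTGGG")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, 15L))
  expect_equal(h$strand, "+")
  expect_equal(h$sequence, "GGGTGGGTGGGTGGG")

  # three runs do not satisfy the four-run grammar
  expect_equal(nrow(scan_regex("GGGTGGGTGGG")), 0L)

  h <- scan_regex("CCCACCCACCCACCC")
  expect_equal(c(h$start, h$end, h$strand), c("0", "15", "-"))

  # N breaks both runs and loops
  expect_equal(nrow(scan_regex("GGGNGGGTGGGTGGG")), 0L)
})

test_that("consensus scanner matches the brute-force grammar oracle", {
  set.seed(101)
  for (i in 1:60) {
    s <- random_seq(2000, runif(1, 0.3, 0.7))
    got <- scan_regex(s)
    exp <- oracle_regex(s)
    got_key <- sort(paste(got$start, got$end, got$strand))
    exp_key <- if (is.null(exp) || nrow(exp) == 0L) character(0)
               else sort(paste(exp$start, exp$end, exp$strand))
    expect_identical(got_key, exp_key)
  }
})

test_that("per-base scores follow the capped run-length rule", {
  expect_equal(base_scores("GGTAACC"), c(2L, 2L, 0L, 0L, 0L, -2L, -2L))
  expect_equal(base_scores("GGGGG"), rep(4L, 5L))
  expect_equal(base_scores("ATAT"), rep(0L, 4L))
  expect_equal(base_scores("GGGNGG"), c(3L, 3L, 3L, 0L, 2L, 2L))
})

test_that("windowed caller emits trimmed regions with qualifying windows", {
  # 25 G in an A background: one saturating window, score 4
  s <- paste0(strrep("A", 40), strrep("G", 25), strrep("A", 40))
  h <- call_hunter(s)
  expect_equal(nrow(h), 1L)
  expect_equal(h$score, 4)
  expect_equal(h$strand, "+")
  expect_equal(substr(s, h$start + 1L, h$end), strrep("G", 25))

  # isolated single Gs: window mean 0.5 < 1.5, no call
  expect_equal(nrow(call_hunter(strrep("GT", 50))), 0L)

  # C-rich gives a "-" region with negative score
  h <- call_hunter(paste0(strrep("A", 40), strrep("C", 25), strrep("A", 40)))
  expect_equal(h$strand, "-")
  expect_equal(h$score, -4)

  # contig shorter than the window: empty result with a notice
  expect_message(h <- call_hunter(strrep("G", 10)), "shorter than window")
  expect_equal(nrow(h), 0L)
})

test_that("windowed caller agrees with per-window brute force", {
  set.seed(202)
  p <- detect_params()
  for (i in 1:20) {
    s <- random_seq(3000, runif(1, 0.35, 0.65))
    sc <- base_scores(s, p)
    om <- oracle_window_means(sc, p$window)
    n <- nchar(s)
    cs <- cumsum(c(0, sc))
    fast <- (cs[(p$window + 1L):(n + 1L)] - cs[1L:(n - p$window + 1L)]) /
      p$window
    expect_equal(fast, om, tolerance = 1e-12)
    # every emitted region contains at least one qualifying window start
    h <- call_hunter(s, p)
    qual <- which(abs(om) >= p$threshold) - 1L   # 0-based window starts
    for (j in seq_len(nrow(h))) {
      inside <- qual[qual >= h$start[j] - p$window &
                     qual <= h$end[j]]
      ok <- any(vapply(inside, function(w0) {
        wm <- om[w0 + 1L]
        (h$strand[j] == "+" && wm >= p$threshold) ||
          (h$strand[j] == "-" && wm <= -p$threshold)
      }, logical(1)))
      expect_true(ok)
      expect_gte(abs(h$score[j]), p$threshold)
    }
  }
})

test_that("both detectors are antisymmetric under reverse complement", {
  set.seed(303)
  for (i in 1:20) {
    s <- random_seq(2000, runif(1, 0.35, 0.65))
    L <- nchar(s)
    rc <- revcomp(s)
    for (f in list(scan_regex, call_hunter)) {
      a <- f(s)
      b <- f(rc)
      mirrored <- data.frame(start = L - b$end, end = L - b$start,
                             strand = ifelse(b$strand == "+", "-", "+"),
                             score = -b$score)
      key <- function(d) sort(paste(d$start, d$end, d$strand))
      expect_identical(key(a), key(mirrored))
      if (nrow(a) > 0L && !all(is.na(a$score))) {
        oa <- a[order(a$start, a$strand), ]
        ob <- mirrored[order(mirrored$start, mirrored$strand), ]
        expect_equal(oa$score, ob$score, tolerance = 1e-12)
      }
    }
  }
})

test_that("merging unions overlapping spans and is idempotent", {
  h <- make_hits("c", c(0L, 5L), c(10L, 15L))
  m <- merge_hits(h)
  expect_equal(c(m$start, m$end), c(0L, 15L))

  # abutting half-open spans share no bp and stay separate
  h <- make_hits("c", c(0L, 10L), c(10L, 20L))
  expect_equal(nrow(merge_hits(h)), 2L)

  # methods differing -> merged; strands kept apart by default
  h <- make_hits("c", c(0L, 5L, 3L), c(10L, 15L, 8L),
                 strand = c("+", "+", "-"),
                 method = c("regex", "hunter", "regex"))
  m <- merge_hits(h)
  expect_equal(sort(m$method), c("merged", "regex"))
  m2 <- merge_hits(h, across_strands = TRUE)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$strand, ".")

  set.seed(404)
  for (i in 1:20) {
    x <- random_intervals(50, contigs = "c1")
    x$strand <- "+"
    m <- merge_hits(x)
    o <- oracle_merge_spans(x$start, x$end)
    expect_equal(m$start, o$start)
    expect_equal(m$end, o$end)
    # idempotent, and covered bp never decreases
    expect_equal(merge_hits(m)[, c("start", "end")],
                 m[, c("start", "end")])
    cov_in <- sum(oracle_merge_spans(x$start, x$end)$end -
                  oracle_merge_spans(x$start, x$end)$start)
    expect_gte(sum(m$end - m$start), cov_in)
  }
})

test_that("every consensus hit satisfies the grammar on its own strand", {
  set.seed(505)
  p <- detect_params()
  s <- random_seq(50000, 0.6)
  h <- scan_regex(s)
  expect_gt(nrow(h), 0L)
  for (i in seq_len(nrow(h))) {
    sq <- if (h$strand[i] == "+") h$sequence[i] else revcomp(h$sequence[i])
    chars <- strsplit(sq, "", fixed = TRUE)[[1L]]
    expect_equal(oracle_match_end(chars, 1L, p), length(chars))
  }
})
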