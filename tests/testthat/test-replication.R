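test_that("circular distance satisfies the formula and its properties", {
  expect_equal(circ_distance(10, 90, 100), 20)
  expect_equal(circ_distance(0, 50, 100), 50)
  expect_equal(circ_distance(7, 7, 100), 0)
  expect_error(circ_distance(-1, 5, 100), "lie in")

  set.seed(11)
  p <- sample.int(1000L, 200L, replace = TRUE) - 1L
  q <- sample.int(1000L, 200L, replace = TRUE) - 1L
  expect_equal(circ_distance(p, q, 1000L), circ_distance(q, p, 1000L))
  expect_true(all(circ_distance(p, q, 1000L) <= 500))
})

test_that("signed offsets map to (-L/2, L/2] with the antipode positive", {
  ori <- origin_spec("c", 50, 100)
  expect_equal(signed_offset(60, ori), 10)
  expect_equal(signed_offset(40, ori), -10)
  expect_equal(signed_offset(0, ori), 50)
  expect_error(signed_offset(5, origin_spec("c", 50, 100, "linear")),
               "circular")
  # |offset| equals the circular distance from oriC
  set.seed(12)
  p <- sample.int(100L, 50L, replace = TRUE) - 1L
  expect_equal(abs(signed_offset(p, ori)), circ_distance(p, 50, 100))
})

test_that("circular binning assigns midpoints and spans correctly", {
  ori <- origin_spec("c", 5000, 10010)
  nb <- 11L   # bin width 910, centre bin 5 holds offset 0
  h <- make_hits("c", 4999L, 5002L)        # midpoint 5000 = oriC
  cp <- bin_circular(h, ori, nb)
  expect_equal(cp$counts_fwd[6L], 1L)
  expect_equal(sum(cp$counts_fwd), 1L)

  # a hit spanning two bin boundaries lands in all three touched bins
  bw <- 10010 / nb
  h <- make_hits("c", as.integer(5000 - bw), as.integer(5000 + bw + 1))
  cp <- bin_circular(h, ori, nb)
  expect_equal(sum(cp$counts_fwd > 0L), 3L)
  expect_true(all(cp$counts_fwd[5:7] == 1L))

  # strand-split tallies
  h <- rbind(make_hits("c", 100L, 120L, "+"),
             make_hits("c", 100L, 120L, "-"))
  cp <- bin_circular(h, ori, nb)
  expect_equal(sum(cp$counts_fwd), 1L)
  expect_equal(sum(cp$counts_rev), 1L)
})

test_that("uniform random hits bin uniformly (multinomial bound)", {
  set.seed(13)
  L <- 1001000L
  ori <- origin_spec("c", 500500, L)
  n <- 30000L
  st <- sample.int(L - 2L, n, replace = TRUE) - 1L
  h <- make_hits("c", st, st + 1L)
  cp <- bin_circular(h, ori, 1001L)
  expected <- n / 1001
  sdv <- sqrt(n * (1 / 1001) * (1 - 1 / 1001))
  expect_true(all(abs(cp$counts_fwd + cp$counts_rev - expected) <=
                  5 * sdv))
})

test_that("bin enrichment normalises per strand with mean one", {
  ori <- origin_spec("c", 500, 1001)
  cp <- structure(list(n_bins = 11L, chrom_len = 1001,
                       counts_fwd = rep(3L, 11L),
                       counts_rev = c(11L, rep(0L, 10L)),
                       enrichment_fwd = NULL, enrichment_rev = NULL,
                       gc_skew = NULL, n_genomes = 1L),
                  class = "g4_circular_profile")
  cp <- bin_enrichment(cp)
  expect_true(all(cp$enrichment_fwd == 1))
  expect_equal(cp$enrichment_rev[1L], 11)
  expect_equal(cp$enrichment_rev[2L], 0)
  expect_lt(abs(mean(cp$enrichment_fwd) - 1), 1e-9)
  expect_lt(abs(mean(cp$enrichment_rev) - 1), 1e-9)

  # zero-total strand reported as missing, not zero
  cp$counts_rev <- rep(0L, 11L)
  cp <- bin_enrichment(cp)
  expect_true(all(is.na(cp$enrichment_rev)))
})

test_that("GC skew follows (G-C)/(G+C) and skips G+C = 0 windows", {
  # toy windows of 6: "GGGGCC" -> 1/3, "AATTAA" skipped
  s <- paste0("GGGGCC", "AATTAA")
  ori <- origin_spec("c", 6, 12)
  sk <- gc_skew_binned(s, ori, window = 6L, n_bins = 3L)
  expect_equal(attr(sk, "n_skipped_windows"), 1L)
  expect_equal(sk[!is.na(sk)], 1 / 3, ignore_attr = TRUE)
})

test_that("planted replichore skew is recovered from the sequence", {
  sp <- synthetic_spec(genome_length = 200000L, topology = "circular",
                       skew_amp = 0.2, n_genes = 0L,
                       baseline_g4_rate = 0, seed = 21L)
  g <- generate_genome(sp)
  sk <- gc_skew_binned(g$genome[1L, , drop = FALSE], g$ori, 25L, 1001L)
  off <- (seq_len(1001L) - 1L + 0.5) * (200000 / 1001) - 100000
  right <- off > 0 & !is.na(sk)
  left <- off < 0 & !is.na(sk)
  expect_lt(abs(mean(sk[right]) - 0.2), 0.05)
  expect_lt(abs(mean(sk[left]) + 0.2), 0.05)
})

test_that("leading fraction follows the orientation convention", {
  ori <- origin_spec("c", 50, 100)
  expect_equal(leading_fraction(make_hits("c", 58L, 62L, "+"), ori), 1)
  h <- rbind(make_hits("c", 58L, 62L, "+"), make_hits("c", 58L, 62L, "-"))
  expect_equal(leading_fraction(h, ori), 0.5)
  expect_equal(leading_fraction(make_hits("c", 58L, 62L, "+"), ori,
                                invert = TRUE), 0)
  expect_error(leading_fraction(h[0L, ], ori), "no stranded hits")
})

test_that("unbiased uniform hits give leading fraction near one half", {
  set.seed(22)
  L <- 100000L
  ori <- origin_spec("c", 50000, L)
  n <- 2000L
  st <- sample.int(L - 30L, n, replace = TRUE) - 1L
  h <- make_hits("c", st, st + 20L,
                 strand = sample(c("+", "-"), n, replace = TRUE))
  lf <- leading_fraction(h, ori)
  se <- sqrt(0.25 / n)
  expect_lt(abs(lf - 0.5), 3 * se + 1e-9)
})

test_that("rotation leaves circular counts invariant; revcomp swaps strands", {
  set.seed(23)
  L <- 50000L
  st <- sample.int(L - 40L, 300L, replace = TRUE) - 1L
  h <- make_hits("c", st, st + 25L,
                 strand = sample(c("+", "-"), 300L, replace = TRUE))
  ori <- origin_spec("c", 20000, L)
  cp <- bin_circular(h, ori, 101L)
  for (rot in c(1234L, 45000L)) {
    nw <- (h$start + rot) %% L
    keep <- nw + 25L <= L          # drop the few spans that would wrap
    hr <- h[keep, , drop = FALSE]
    hr$start <- nw[keep]
    hr$end <- hr$start + 25L
    cp2 <- bin_circular(hr, origin_spec("c", (20000 + rot) %% L, L), 101L)
    cpref <- bin_circular(h[keep, , drop = FALSE], ori, 101L)
    expect_equal(cp2$counts_fwd, cpref$counts_fwd)
    expect_equal(cp2$counts_rev, cpref$counts_rev)
  }

  # reverse complement: strands swap, GC skew negates bin-wise (up to
  # window-tiling misalignment at the sequence ends)
  sq <- random_seq(L, 0.5)
  ori_rc <- origin_spec("c", L - 1 - 20000, L)
  sk <- gc_skew_binned(sq, ori, 25L, 101L)
  skr <- gc_skew_binned(revcomp(sq), ori_rc, 25L, 101L)
  ok <- !is.na(sk) & !is.na(rev(skr))
  expect_lt(max(abs(sk[ok] + rev(skr)[ok])), 0.2)

  hrc <- h
  hrc$start <- L - h$end
  hrc$end <- L - h$start
  hrc$strand <- ifelse(h$strand == "+", "-", "+")
  cprc <- bin_circular(hrc, ori_rc, 101L)
  expect_equal(sum(cprc$counts_fwd), sum(cp$counts_rev))
  expect_equal(sum(cprc$counts_rev), sum(cp$counts_fwd))
})

test_that("linear origin profiles count per strand and normalise", {
  origins <- make_hits("c", 4999L, 5002L)     # midpoint 5000
  h <- make_hits("c", 4995L, 5005L, "+")
  pr <- linear_origin_profile(h, origins, halfwin = 2000L)
  idx <- which(pr$offset %in% -5:4)
  expect_true(all(pr$counts_fwd[idx] == 1L))
  expect_equal(sum(pr$counts_fwd), 10L)
  expect_equal(pr$enrichment_fwd[idx][1L], 1 / mean(pr$counts_fwd))
  expect_true(all(is.na(pr$enrichment_rev)))
})

test_that("origin vicinity fraction counts windows with >= 1 hit", {
  origins <- rbind(make_hits("c", 1000L, 1001L),
                   make_hits("c", 9000L, 9001L))
  h <- make_hits("c", 1500L, 1520L)
  expect_equal(origins_with_hit_fraction(origins, h, 2000L), 0.5)
  expect_equal(origins_with_hit_fraction(origins, h[0L, ], 2000L), 0)
  # halfwin 0: only a hit covering the midpoint base counts
  expect_equal(origins_with_hit_fraction(origins,
                                         make_hits("c", 1000L, 1001L), 0L),
               0.5)
  expect_equal(origins_with_hit_fraction(origins,
                                         make_hits("c", 1001L, 1002L), 0L),
               0)
})
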