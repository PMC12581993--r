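make_gene <- function(start, end, strand, gid = "g1") {
  data.frame(contig_id = "c", start = as.integer(start),
             end = as.integer(end), strand = strand, kind = "gene",
             gene_id = gid, biotype = "unknown", stringsAsFactors = FALSE)
}

test_that("anchors follow transcriptional orientation", {
  g <- make_gene(100L, 200L, "+")
  expect_equal(collect_anchors(g, "TSS")$position, 100L)
  expect_equal(collect_anchors(g, "TES")$position, 199L)
  g <- make_gene(100L, 200L, "-")
  expect_equal(collect_anchors(g, "TSS")$position, 199L)
  expect_equal(collect_anchors(g, "TES")$position, 100L)

  intr <- data.frame(contig_id = "c", start = 10L, end = 20L,
                     strand = "+", kind = "intron", gene_id = "g1",
                     biotype = "unknown", stringsAsFactors = FALSE)
  expect_equal(collect_anchors(intr, "SS5")$position, 10L)
  expect_equal(collect_anchors(intr, "SS3")$position, 19L)
})

test_that("occupancy counts per-bp coverage in oriented offsets", {
  anch <- collect_anchors(make_gene(1000L, 2000L, "+"), "TSS")
  pr <- occupancy_profile(make_hits("c", 995L, 1005L), anch, 500L)
  idx <- which(pr$offsets %in% -5:4)
  expect_true(all(pr$counts_nontemplate[idx] == 1L))
  expect_equal(sum(pr$counts_nontemplate), 10L)
  expect_equal(sum(pr$counts_template), 0L)

  # minus-strand anchor: orientation flips and a "+" hit is template
  anch <- collect_anchors(make_gene(50L, 101L, "-"), "TSS")
  pr <- occupancy_profile(make_hits("c", 103L, 108L), anch, 500L)
  idx <- which(pr$offsets %in% -7:-3)
  expect_true(all(pr$counts_template[idx] == 1L))
  expect_equal(sum(pr$counts_template), 5L)
  expect_equal(sum(pr$counts_nontemplate), 0L)

  # no hits -> all-zero counts
  pr <- occupancy_profile(make_hits("c", 1L, 2L)[0L, ], anch, 500L)
  expect_equal(sum(pr$counts_total), 0L)
})

test_that("counts_total equals hit-bp falling inside windows", {
  set.seed(808)
  genes <- do.call(rbind, lapply(1:5, function(i)
    make_gene(i * 3000L, i * 3000L + 1000L,
              sample(c("+", "-"), 1L), sprintf("g%d", i))))
  hits <- random_intervals(60, contigs = "c", span = 20000L)
  hits$contig_id <- "c"
  anch <- collect_anchors(genes, "TSS")
  pr <- occupancy_profile(hits, anch, 500L)
  # brute-force per-base recount
  expected <- 0L
  for (i in seq_len(nrow(anch))) {
    for (j in seq_len(nrow(hits))) {
      for (b in seq.int(hits$start[j], hits$end[j] - 1L)) {
        o <- if (anch$strand[i] == "+") b - anch$position[i]
             else anch$position[i] - b
        if (o >= -500L && o < 500L) expected <- expected + 1L
      }
    }
  }
  expect_equal(sum(pr$counts_total), expected)
})

test_that("enrichment normalises to mean 1 and rejects empty profiles", {
  anch <- collect_anchors(make_gene(1000L, 2000L, "+"), "TSS")
  # uniform coverage across the window -> enrichment 1 everywhere
  pr <- occupancy_profile(make_hits("c", 400L, 1600L), anch, 500L)
  pr <- enrichment_profile(pr)
  expect_true(all(abs(pr$enrichment - 1) < 1e-12))

  # half covered -> 2 and 0
  pr <- occupancy_profile(make_hits("c", 500L, 1000L), anch, 500L)
  pr <- enrichment_profile(pr)
  expect_setequal(unique(pr$enrichment), c(2, 0))

  # algebraic identity at 1e-9
  set.seed(909)
  for (i in 1:10) {
    hits <- random_intervals(30, contigs = "c", span = 3000L)
    hits$contig_id <- "c"
    pr <- occupancy_profile(hits, anch, 500L)
    if (sum(pr$counts_total) == 0L) next
    pr <- enrichment_profile(pr)
    expect_lt(abs(mean(pr$enrichment) - 1), 1e-9)
  }

  empty <- occupancy_profile(make_hits("c", 1L, 2L)[0L, ], anch, 500L)
  expect_error(enrichment_profile(empty), "empty profile")
})

test_that("profiles are invariant under genome reflection", {
  # reflecting all genes to the opposite strand and reverse-complementing
  # the genome leaves the profile unchanged
  set.seed(111)
  L <- 20000L
  s <- random_seq(L, 0.55)
  genome <- data.frame(contig_id = "c", sequence = s, length = L,
                       topology = "linear", stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(1:4, function(i)
    make_gene(i * 4000L, i * 4000L + 1200L,
              sample(c("+", "-"), 1L), sprintf("g%d", i))))
  hits <- scan_regex(genome)
  pr1 <- occupancy_profile(hits, collect_anchors(genes, "TSS"), 300L)

  rg <- genome; rg$sequence <- revcomp(s)
  rgenes <- genes
  rgenes$start <- L - genes$end
  rgenes$end <- L - genes$start
  rgenes$strand <- ifelse(genes$strand == "+", "-", "+")
  rhits <- scan_regex(rg)
  pr2 <- occupancy_profile(rhits, collect_anchors(rgenes, "TSS"), 300L)
  expect_equal(pr1$counts_total, pr2$counts_total)
  expect_equal(pr1$counts_template, pr2$counts_template)
  expect_equal(pr1$counts_nontemplate, pr2$counts_nontemplate)
})

test_that("Monte-Carlo bands collapse for degenerate cohorts", {
  anch <- collect_anchors(make_gene(1000L, 2000L, "+"), "TSS")
  pr <- occupancy_profile(make_hits("c", 900L, 1100L), anch, 500L)

  # a single species: bands equal the point estimate exactly
  mc <- mc_confidence(list(pr), mc_params(n_reps = 200L, seed = 3L))
  expect_identical(mc$ci_low, mc$enrichment)
  expect_identical(mc$ci_high, mc$enrichment)

  # ten identical species: zero-width bands
  mc <- mc_confidence(rep(list(pr), 10L), mc_params(200L, seed = 3L))
  expect_identical(mc$ci_low, mc$ci_high)
  expect_equal(mc$ci_low, mc$enrichment)

  # reproducibility under the same seed
  set.seed(121)
  profs <- lapply(1:6, function(i) {
    hits <- random_intervals(20, contigs = "c", span = 3000L)
    hits$contig_id <- "c"
    occupancy_profile(hits, anch, 500L)
  })
  a <- mc_confidence(profs, mc_params(100L, seed = 9L))
  b <- mc_confidence(profs, mc_params(100L, seed = 9L))
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
})

test_that("MC bands shrink as the cohort grows", {
  set.seed(131)
  anch <- collect_anchors(make_gene(1000L, 2000L, "+"), "TSS")
  pool <- lapply(1:50, function(i) {
    hits <- random_intervals(25, contigs = "c", span = 3000L)
    hits$contig_id <- "c"
    occupancy_profile(hits, anch, 100L)
  })
  w <- function(n) {
    mc <- mc_confidence(pool[seq_len(n)], mc_params(300L, seed = 5L))
    mean(mc$ci_high - mc$ci_low)
  }
  expect_lt(w(50L), w(5L))
})

test_that("regional fold enrichment averages the requested offsets", {
  anch <- collect_anchors(make_gene(1000L, 2000L, "+"), "TSS")
  pr <- enrichment_profile(
    occupancy_profile(make_hits("c", 400L, 1600L), anch, 500L))
  expect_equal(fold_enrichment_region(pr, c(-500L, 0L)), 1)
  pr2 <- enrichment_profile(
    occupancy_profile(make_hits("c", 500L, 1000L), anch, 500L))
  expect_equal(fold_enrichment_region(pr2, c(-500L, 0L)), 2)
  expect_error(fold_enrichment_region(pr, 10000L), "empty offset range")
})
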