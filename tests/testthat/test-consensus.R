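parsed_row <- function(id, key, seq, quals) {
  tibble::tibble(id = id, matched = TRUE, fwd_tag = key, rev_tag = NA_character_,
                 key = key, amplicon_seq = seq, amplicon_qual = phred_encode(quals))
}

test_that("categorize splits matched reads into categories and SRCs", {
  parsed <- dplyr::bind_rows(
    parsed_row("r1", "AAAA", "ACGT", rep(30, 4)),
    parsed_row("r2", "AAAA", "ACGT", rep(30, 4)),
    parsed_row("r3", "BBBB", "ACGT", rep(30, 4))
  )
  bins <- categorize(parsed)
  expect_equal(unique(bins$categories$key), "AAAA")
  expect_equal(unique(bins$categories$depth), 2L)
  expect_equal(bins$srcs$key, "BBBB")
  # conservation
  expect_equal(sum(bins$categories$depth[!duplicated(bins$categories$key)]) +
                 nrow(bins$srcs), nrow(parsed))
})

test_that("categorize of empty input yields empty tables", {
  parsed <- parsed_row("r", "K", "A", 30)[0, ]
  bins <- categorize(parsed)
  expect_equal(nrow(bins$categories), 0)
  expect_equal(nrow(bins$srcs), 0)
})

test_that("uniquely tagged simulated molecules give one category each, no SRCs", {
  cfg <- sim_config(n_molecules = 100, seed = 13, pcr_error_rate = 0,
                    seq_error = list(profile = "uniform", rate = 0),
                    depth_dist = list(dist = "fixed", value = 3),
                    amplification_bias_sd = 0, n_templates = 4,
                    template_length = 50)
  sim <- simulate_mt_reads(cfg)
  parsed <- parse_reads(sim$reads, compile_matcher(cfg$spec))
  bins <- categorize(parsed)
  expect_equal(length(unique(bins$categories$key)), 100)
  expect_equal(nrow(bins$srcs), 0)
})

test_that("length clustering keeps the largest bin, ties to the longest", {
  cat3 <- dplyr::bind_rows(
    parsed_row("a", "K", strrep("A", 100), rep(30, 100)),
    parsed_row("b", "K", strrep("A", 100), rep(30, 100)),
    parsed_row("c", "K", strrep("A", 101), rep(30, 101))
  )
  lc <- length_cluster(cat3)
  expect_equal(nrow(lc$used), 2)
  expect_equal(lc$discarded, 1)
  expect_equal(unique(nchar(lc$used$amplicon_seq)), 100)

  tie <- cat3[c(1, 3), ]
  lc2 <- length_cluster(tie)
  expect_equal(nrow(lc2$used), 1)
  expect_equal(nchar(lc2$used$amplicon_seq), 101)

  same <- cat3[1:2, ]
  lc3 <- length_cluster(same)
  expect_equal(nrow(lc3$used), 2)
  expect_equal(lc3$discarded, 0)
})

test_that("stacking builds a depth x length matrix, verbatim, no gaps", {
  cat3 <- dplyr::bind_rows(
    parsed_row("a", "K", "ACGTA", c(10, 20, 30, 40, 50)),
    parsed_row("b", "K", "ACGTT", c(11, 21, 31, 41, 51)),
    parsed_row("c", "K", "TCGTA", c(12, 22, 32, 42, 52))
  )
  M <- stack_reads(cat3)
  expect_equal(dim(M$bases), c(3, 5))
  expect_equal(dim(M$quals), c(3, 5))
  expect_equal(M$bases[2, ], c("A", "C", "G", "T", "T"))
  expect_equal(M$quals[, 1], c(10L, 11L, 12L))
  # column j is the multiset of base j across reads
  for (j in 1:5) {
    expect_equal(sort(M$bases[, j]),
                 sort(substr(cat3$amplicon_seq, j, j)))
  }
  expect_error(stack_reads(dplyr::bind_rows(cat3, parsed_row("d", "K", "AC", c(1, 2)))),
               "unequal length")
})

test_that("column consensus follows mode, mean quality, tie-break and IUPAC rules", {
  # mode base with mean of its own qualities
  expect_equal(consensus_column(c("A", "A", "G"), c(30, 32, 10)),
               list(base = "A", qual = 31L))
  # count tie resolved by higher mean quality, keeping that base's mean
  expect_equal(consensus_column(c("A", "G"), c(30, 20)),
               list(base = "A", qual = 30L))
  # exact quality tie falls back to the covering IUPAC code
  expect_equal(consensus_column(c("A", "G"), c(30, 30)),
               list(base = "R", qual = 30L))
  # four-way tie covers all bases
  expect_equal(consensus_column(c("A", "C", "G", "T"), rep(20, 4)),
               list(base = "N", qual = 20L))
  # half-up rounding of the mean quality
  expect_equal(consensus_column(c("C", "C"), c(30, 31))$qual, 31L)
})

test_that("N observations are never mode candidates", {
  expect_equal(consensus_column(c("A", "N", "N"), c(10, 40, 40))$base, "A")
  expect_equal(consensus_column(c("A", "N", "N"), c(10, 40, 40))$qual, 10L)
  expect_equal(consensus_column(c("N", "N"), c(20, 30)),
               list(base = "N", qual = 25L))
})

test_that("build_conseq reproduces identical reads and honours depth-2 quality", {
  amp <- "ACGTACGTAC"
  cat5 <- dplyr::bind_rows(lapply(1:5, function(i) {
    parsed_row(sprintf("r%d", i), "K", amp, rep(35, 10))
  }))
  cs <- build_conseq(cat5)
  expect_equal(cs$seq, amp)
  expect_equal(phred_decode(cs$qual)[[1]], rep(35L, 10))
  expect_equal(cs$depth, 5L)
  expect_equal(cs$n_used, 5L)

  # depth-2 category differing at one base: the higher-quality base wins
  cat2 <- dplyr::bind_rows(
    parsed_row("r1", "K", "ACGTACGTAC", c(rep(35, 4), 35, rep(35, 5))),
    parsed_row("r2", "K", "ACGTTCGTAC", c(rep(35, 4), 20, rep(35, 5)))
  )
  cs2 <- build_conseq(cat2)
  expect_equal(substr(cs2$seq, 5, 5), "A")
  expect_equal(phred_decode(cs2$qual)[[1]][5], 35L)

  expect_error(build_conseq(cat2[1, ]), "depth >= 2")
})

test_that("consensus equals the brute-force oracle on random small matrices", {
  set.seed(99)
  for (i in 1:60) {
    cat <- random_category(sample(2:8, 1), sample(3:25, 1), n_prob = 0.05)
    lc <- length_cluster(cat)
    M <- stack_reads(lc$used)
    got <- build_conseq(cat)
    want <- oracle_consensus(M$bases, M$quals)
    expect_equal(got$seq, want$seq)
    expect_equal(phred_decode(got$qual)[[1]], want$qual)
  }
})

test_that("deep categories still out-call their reads under simulated errors", {
  cfg <- sim_config(n_molecules = 60, seed = 31, pcr_error_rate = 0,
                    seq_error = list(profile = "uniform", rate = 0.005),
                    depth_dist = list(dist = "fixed", value = 10),
                    amplification_bias_sd = 0, n_templates = 3,
                    template_length = 80)
  sim <- simulate_mt_reads(cfg)
  parsed <- parse_reads(sim$reads, compile_matcher(cfg$spec))
  bins <- categorize(parsed)
  cs <- call_consensus(bins$categories)
  per_base_identity <- evaluate_epb(cs, sim$truth)
  # per-base consensus accuracy > 0.999 at depth 10 and error 0.005
  expect_lt(sum(per_base_identity$mean_epb * per_base_identity$n) /
              sum(per_base_identity$n), 0.001)
})

test_that("digital normalization subsamples reproducibly and only above the cap", {
  cat <- random_category(50, 20)
  a <- subsample_category(cat, 20, seed = 123)
  b <- subsample_category(cat, 20, seed = 123)
  expect_equal(nrow(a), 20)
  expect_identical(a, b)
  expect_true(all(a$id %in% cat$id))
  expect_false(identical(a, subsample_category(cat, 20, seed = 124)))

  small <- random_category(5, 20)
  expect_identical(subsample_category(small, 20, seed = 1), small)
})

test_that("subsampling retains the majority base at hypergeometric rates", {
  # 8 of 10 reads carry the majority base; subsample 4 of 10; majority kept
  # unless >= 3 of the 4 come from the 2-read minority: impossible here to
  # lose outright, a 2-2 split needs both minority reads drawn
  maj <- parsed_row(sprintf("M%d", 1:8), "K", "A", 30)
  min_ <- parsed_row(sprintf("m%d", 1:2), "K", "C", 30)
  cat <- dplyr::bind_rows(maj, min_)
  p_tie <- stats::dhyper(2, 2, 8, 4) # both minority reads in the subsample
  ties <- 0L
  for (s in 1:400) {
    sub <- subsample_category(cat, 4, seed = s)
    n_min <- sum(sub$amplicon_seq == "C")
    expect_lte(n_min, 2)
    if (n_min == 2) ties <- ties + 1L
  }
  # observed tie rate within 3 SE of the exact hypergeometric probability
  se <- sqrt(p_tie * (1 - p_tie) / 400)
  expect_lt(abs(ties / 400 - p_tie), 3 * se + 1e-9)
})
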