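test_that("the zero-error limit reproduces templates exactly at every stage", {
  cfg <- sim_config(n_molecules = 80, seed = 17, pcr_error_rate = 0,
                    seq_error = list(profile = "uniform", rate = 0),
                    depth_dist = list(dist = "fixed", value = 3),
                    amplification_bias_sd = 0, n_templates = 4,
                    template_length = 60)
  sim <- simulate_mt_reads(cfg)
  parsed <- parse_reads(sim$reads, compile_matcher(cfg$spec))
  expect_true(all(parsed$matched))
  expect_equal(parsed$amplicon_seq,
               sim$truth$true_amplicon)
  bins <- categorize(parsed)
  cs <- call_consensus(bins$categories)
  key_truth <- dplyr::distinct(sim$truth, tag_key, true_amplicon)
  expect_equal(cs$seq, key_truth$true_amplicon[match(cs$key, key_truth$tag_key)])
  epb <- evaluate_epb(cs, sim$truth)
  expect_true(all(epb$mean_epb == 0))
})

test_that("seeded simulations are bit-reproducible and seeds differ", {
  cfg <- sim_config(n_molecules = 30, seed = 4,
                    seq_error = list(profile = "uniform", rate = 0.01))
  a <- simulate_mt_reads(cfg)
  b <- simulate_mt_reads(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  cfg2 <- cfg; cfg2$seed <- 5L
  expect_false(identical(simulate_mt_reads(cfg2)$reads, a$reads))
})

test_that("uniform sequencing error hits the configured rate", {
  cfg <- sim_config(n_molecules = 1000, seed = 8, pcr_error_rate = 0,
                    seq_error = list(profile = "uniform", rate = 0.005),
                    depth_dist = list(dist = "fixed", value = 1),
                    amplification_bias_sd = 0, n_templates = 2,
                    template_length = 150)
  sim <- simulate_mt_reads(cfg)
  parsed <- parse_reads(sim$reads, compile_matcher(cfg$spec))
  raw <- tibble::tibble(id = parsed$id, seq = parsed$amplicon_seq)[parsed$matched, ]
  epb <- evaluate_epb(raw, sim$truth)
  n_bases <- sum(epb$n) * 150
  expect_gte(n_bases, 1e5)
  p <- 0.005
  se <- sqrt(p * (1 - p) / n_bases)
  expect_lt(abs(epb$mean_epb[1] - p), 3 * se)
})

test_that("qualities are calibrated to the error probabilities used", {
  cfg <- sim_config(n_molecules = 5, seed = 1,
                    seq_error = list(profile = "uniform", rate = 0.001))
  sim <- simulate_mt_reads(cfg)
  expect_true(all(phred_decode(sim$reads$qual[1])[[1]] == 30L))
  cfg2 <- sim_config(n_molecules = 5, seed = 1, template_length = 100,
                     seq_error = list(profile = "quality_curve",
                                      q_start = 38, q_end = 28))
  sim2 <- simulate_mt_reads(cfg2)
  q <- phred_decode(sim2$reads$qual[1])[[1]]
  expect_equal(q[1], 38L)
  expect_equal(q[length(q)], 28L)
  expect_true(all(diff(q) <= 0))
})

test_that("a first-cycle PCR mutation reaches about half of a molecule's reads", {
  cfg <- sim_config(n_molecules = 1, seed = 19, pcr_error_rate = 0.05,
                    n_cycles = 1L,
                    seq_error = list(profile = "uniform", rate = 0),
                    depth_dist = list(dist = "fixed", value = 400),
                    amplification_bias_sd = 0, n_templates = 1,
                    template_length = 80)
  sim <- simulate_mt_reads(cfg)
  # with rate 0.05 over a ~135 nt fragment a founder mutation is
  # essentially certain; no other error source is active
  variants <- table(sim$reads$seq)
  expect_equal(length(variants), 2L)
  frac <- min(variants) / sum(variants)
  se <- sqrt(0.25 / 400)
  expect_lt(abs(frac - 0.5), 4 * se)
})

test_that("amplification bias correlates efficiency weight with realized depth", {
  cfg <- sim_config(n_molecules = 600, seed = 23, amplification_bias_sd = 0.5,
                    n_templates = 3, template_length = 40,
                    seq_error = list(profile = "uniform", rate = 0))
  sim <- simulate_mt_reads(cfg)
  ct <- stats::cor.test(sim$molecules$amp_weight, sim$molecules$depth,
                        method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 1e-3)
})

test_that("planted collisions put two templates behind the configured key fraction", {
  cfg <- sim_config(n_molecules = 200, seed = 29, collision_rate = 0.05,
                    n_templates = 10, template_length = 40,
                    seq_error = list(profile = "uniform", rate = 0))
  sim <- simulate_mt_reads(cfg)
  per_key <- dplyr::summarise(dplyr::group_by(sim$molecules, key),
                              n_templates = dplyr::n_distinct(template_id))
  expect_equal(sum(per_key$n_templates == 2), 10)
  expect_error(
    simulate_mt_reads(sim_config(n_molecules = 10, collision_rate = 0.5,
                                 templates = "ACGTACGTACGT")),
    "two distinct templates"
  )
})

test_that("a too-small tag space without collisions is rejected", {
  spec <- structure_spec(fwd_mt_len = 2L, fwd_primer = "ACGTAC",
                         rev_primer = "TTGGCC", layout = "merged_pair")
  cfg <- sim_config(n_molecules = 100, spec = spec, template_length = 30)
  expect_error(simulate_mt_reads(cfg), "tag space")
})

test_that("errors per base counts IUPAC-covered calls as correct", {
  truth <- tibble::tibble(read_id = "r1", tag_key = "K", template_id = 1L,
                          true_amplicon = strrep("A", 100), molecule_id = 1L)
  same <- tibble::tibble(key = "K", seq = strrep("A", 100), depth = 2L)
  expect_equal(evaluate_epb(same, truth)$mean_epb, 0)

  one_off <- same
  substr(one_off$seq, 10, 10) <- "C"
  expect_equal(evaluate_epb(one_off, truth)$mean_epb, 0.01)

  ambig <- same
  substr(ambig$seq, 10, 10) <- "R" # covers A: not an error
  expect_equal(evaluate_epb(ambig, truth)$mean_epb, 0)
  # brute-force set membership cross-check of the expansion rule
  for (code in c("R", "Y", "K", "M", "B", "N")) {
    rec <- same
    substr(rec$seq, 1, 1) <- code
    want <- if ("A" %in% iupac_to_class(code)) 0 else 0.01
    expect_equal(evaluate_epb(rec, truth)$mean_epb, want)
  }

  unknown <- tibble::tibble(key = "NOPE", seq = strrep("A", 100), depth = 2L)
  out <- evaluate_epb(unknown, truth)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_unknown"), 1L)
})
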