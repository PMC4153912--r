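toy_run_input <- function() {
  spec <- toy_spec()
  amp1 <- strrep("AGCT", 8)
  amp2 <- strrep("GGAA", 8)
  reads <- dplyr::bind_rows(
    structured_read("a1", "AAAA", "CCCC", amp1, spec),
    structured_read("a2", "AAAA", "CCCC", amp1, spec),
    structured_read("a3", "AAAA", "CCCC", amp1, spec),
    structured_read("b1", "GGGG", "TTTT", amp2, spec),
    structured_read("b2", "GGGG", "TTTT", amp2, spec),
    structured_read("b3", "GGGG", "TTTT", amp2, spec)
  )
  list(spec = spec, reads = reads, amps = c(amp1, amp2))
}

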