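# Independent brute-force consensus oracle. Deliberately written from the
# rules alone (table/loop based), sharing no code with the package's
# consensus path.

oracle_iupac <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W", "GT" = "K", "AC" = "M",
  "CGT" = "B", "AGT" = "D", "ACT" = "H", "ACG" = "V", "ACGT" = "N"
)

oracle_consensus_column <- function(bases, quals) {
  keep <- bases %in% c("A", "C", "G", "T")
  if (!any(keep)) {
    return(list(base = "N", qual = min(93L, as.integer(floor(mean(quals) + 0.5)))))
  }
  b <- bases[keep]
  q <- quals[keep]
  tab <- table(b)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) > 1) {
    mq <- sapply(winners, function(w) mean(q[b == w]))
    winners <- winners[abs(mq - max(mq)) < 1e-9]
  }
  if (length(winners) == 1) {
    base <- winners
    qual <- floor(mean(q[b == base]) + 0.5)
  } else {
    base <- oracle_iupac[[paste(sort(winners), collapse = "")]]
    qual <- floor(mean(q[b %in% winners]) + 0.5)
  }
  list(base = base, qual = min(93L, as.integer(qual)))
}

oracle_consensus <- function(base_mat, qual_mat) {
  out_b <- character(ncol(base_mat))
  out_q <- integer(ncol(base_mat))
  for (j in seq_len(ncol(base_mat))) {
    r <- oracle_consensus_column(base_mat[, j], qual_mat[, j])
    out_b[j] <- r$base
    out_q[j] <- r$qual
  }
  list(seq = paste(out_b, collapse = ""), qual = out_q)
}

# random equal-length category as a parsed-read tibble
random_category <- function(depth, len, key = "TESTKEY", n_prob = 0) {
  alphabet <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(depth), function(i) {
    ch <- sample(alphabet, len, replace = TRUE)
    if (n_prob > 0) {
      nn <- runif(len) < n_prob
      ch[nn] <- "N"
    }
    paste(ch, collapse = "")
  }, character(1))
  quals <- vapply(seq_len(depth), function(i) {
    phred_encode(sample(0:60, len, replace = TRUE))
  }, character(1))
  tibble::tibble(
    id = sprintf("r%d", seq_len(depth)), matched = TRUE,
    fwd_tag = key, rev_tag = NA_character_, key = key,
    amplicon_seq = seqs, amplicon_qual = quals
  )
}

# build a structured whole-fragment read around an amplicon
structured_read <- function(id, fwd_tag, rev_tag, amplicon, spec, qual_char = "I") {
  seq <- paste0(fwd_tag, spec$fwd_linker, spec$fwd_primer, amplicon,
                reverse_complement(spec$rev_primer),
                reverse_complement(spec$rev_linker),
                reverse_complement(rev_tag))
  tibble::tibble(id = id, comment = NA_character_, seq = seq,
                 qual = strrep(qual_char, nchar(seq)), mate = "single")
}

# simple fixed-tag spec used across structure tests (no degeneracies)
toy_spec <- function(layout = "merged_pair") {
  structure_spec(fwd_mt_len = 4L, fwd_primer = "ACGTAC",
                 rev_primer = "TTGGCC", rev_mt_len = 4L, layout = layout)
}
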