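#' Parameters for overlapping paired-end merging
#'
#' FLASH-style defaults: overlaps of at least 10 nt are considered and the
#' candidate with the smallest mismatch ratio wins (ties go to the longer
#' overlap); pairs whose best ratio exceeds `max_mismatch_ratio` are not
#' merged.
#'
#' @param min_overlap Minimum overlap length in nt (`>= 1`).
#' @param max_mismatch_ratio Maximum fraction of mismatching positions
#'   tolerated in the chosen overlap, in `[0, 1]`.
#' @param max_overlap Largest overlap length scanned (`Inf` for unlimited).
#' @return A `merge_params` list.
#' @export
merge_params <- function(min_overlap = 10L, max_mismatch_ratio = 0.25, max_overlap = Inf) {
  stopifnot(min_overlap >= 1L, max_mismatch_ratio >= 0, max_mismatch_ratio <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_ratio = max_mismatch_ratio,
                 max_overlap = max_overlap),
            class = "merge_params")
}

# merge one pair given char/qual vectors of fwd and rc'd rev; returns NULL on
# no-merge, else list(seq, qual, overlap)
merge_one <- function(fb, fq, rb, rq, params) {
  lf <- length(fb); lr <- length(rb)
  omax <- min(lf, lr, params$max_overlap)
  if (omax < params$min_overlap) return(NULL)
  best_o <- -1L
  best_ratio <- Inf
  best_mm <- NULL
  for (o in seq.int(params$min_overlap, omax)) {
    ft <- (lf - o + 1L):lf
    mm <- fb[ft] != rb[1:o]
    ratio <- sum(mm) / o
    # strict < keeps the first minimum; scanning short->long, a tie at equal
    # ratio must prefer the longer overlap, so use <=
    if (ratio <= best_ratio) {
      best_ratio <- ratio
      best_o <- o
      best_mm <- mm
    }
  }
  if (best_ratio > params$max_mismatch_ratio) return(NULL)
  o <- best_o
  ft <- (lf - o + 1L):lf
  ob <- fb[ft]; oq <- pmax(fq[ft], rq[1:o])
  if (any(best_mm)) {
    i <- which(best_mm)
    qf <- fq[ft][i]; qr <- rq[1:o][i]
    take_rev <- qr > qf
    ob[i][take_rev] <- rb[1:o][i][take_rev]
    # conflicting evidence: quality is the score difference, floored at 2;
    # an exact quality tie keeps the forward base at quality 2
    oq[i] <- pmax(abs(qf - qr), 2L)
  }
  seq_chars <- c(fb[seq_len(lf - o)], ob, rb[o + seq_len(lr - o)])
  qual_ints <- c(fq[seq_len(lf - o)], oq, rq[o + seq_len(lr - o)])
  list(seq = paste(seq_chars, collapse = ""),
       qual = phred_encode(pmin(qual_ints, 93L)),
       overlap = o)
}

#' Merge overlapping paired-end reads
#'
#' The reverse mate is reverse-complemented (with quality reversal) and slid
#' against the forward read. Among overlaps of length at least
#' `params$min_overlap` the one minimising the mismatch ratio is chosen, ties
#' going to the longer overlap. Within the overlap, agreeing positions take
#' quality `max(q_f, q_r)`; disagreeing positions take the higher-quality
#' base with quality `|q_f - q_r|` floored at 2 (forward base at quality 2 on
#' an exact tie). Pairs that cannot be merged are a normal outcome, flagged
#' `merged = FALSE`.
#'
#' @param fwd,rev Read tibbles of equal row count, row i of `rev` being the
#'   mate of row i of `fwd`.
#' @param params A [merge_params()].
#' @return A tibble with one row per pair: `id`, `merged`, `seq`, `qual`,
#'   `overlap` (sequence columns `NA` for unmerged pairs). Merged length is
#'   always `len(fwd) + len(rev) - overlap`.
#' @export
merge_pairs <- function(fwd, rev, params = merge_params()) {
  stopifnot(nrow(fwd) == nrow(rev))
  n <- nrow(fwd)
  out <- tibble::tibble(id = fwd$id, merged = FALSE,
                        seq = NA_character_, qual = NA_character_,
                        overlap = NA_integer_)
  if (n == 0L) return(out)
  rc_seq <- reverse_complement(rev$seq)
  rc_qual <- str_reverse(rev$qual)
  fb_all <- strsplit(fwd$seq, "", fixed = TRUE)
  rb_all <- strsplit(rc_seq, "", fixed = TRUE)
  fq_all <- phred_decode(fwd$qual)
  rq_all <- phred_decode(rc_qual)
  for (i in seq_len(n)) {
    res <- merge_one(fb_all[[i]], fq_all[[i]], rb_all[[i]], rq_all[[i]], params)
    if (!is.null(res)) {
      out$merged[i] <- TRUE
      out$seq[i] <- res$seq
      out$qual[i] <- res$qual
      out$overlap[i] <- res$overlap
    }
  }
  out
}
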