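#' Phred-scaled confidence score of a consensus sequence
#'
#' For column j let `f_j` be the fraction of rows whose base equals the
#' consensus base and `qbar_j` the mean Phred quality of those agreeing
#' observations; the c-score is `mean_j(f_j * qbar_j)`. Under perfect
#' agreement it equals the mean consensus quality; disagreement — including
#' the split signal of a tag accidentally shared by two template molecules
#' (the "birthday paradox") — pulls it down. Columns whose consensus is an
#' ambiguity code have no literally agreeing rows and contribute 0.
#'
#' This definition is this package's own Phred-scaled construction; it is
#' calibrated so that the conventional removal threshold of 35 is meaningful
#' for high-quality (Q35-40) sequencing runs.
#'
#' @param M `alignment_matrix` from [stack_reads()].
#' @param conseq Consensus sequence string built from `M` (a one-row conseq
#'   tibble is also accepted).
#' @return The c-score, a number in `[0, 93]`.
#' @export
c_score <- function(M, conseq) {
  if (is.data.frame(conseq)) conseq <- conseq$seq[1]
  cons <- strsplit(conseq, "", fixed = TRUE)[[1]]
  if (length(cons) != ncol(M$bases)) {
    stop("consensus length does not match matrix dimensions", call. = FALSE)
  }
  if (length(cons) == 0L) return(0)
  contrib <- vapply(seq_along(cons), function(j) {
    agree <- M$bases[, j] == cons[j]
    if (!any(agree)) return(0)
    mean(agree) * mean(M$quals[agree, j])
  }, numeric(1))
  mean(contrib)
}

#' Quality-control thresholds for consensus sequences and SRCs
#'
#' @param min_depth Minimum category depth kept (default 2).
#' @param min_conseq_mean_qual Minimum mean consensus Phred quality.
#' @param min_src_mean_qual Minimum mean Phred quality for a kept SRC.
#' @param c_score_min Consensus sequences with c-score less than *or equal
#'   to* this bound are removed (default 35).
#' @param include_srcs Keep single-read categories that pass the SRC quality
#'   threshold? Default `FALSE` (SRCs retain all technical errors).
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_depth = 2L, min_conseq_mean_qual = 20,
                          min_src_mean_qual = 20, c_score_min = 35,
                          include_srcs = FALSE) {
  stopifnot(min_depth >= 0, min_conseq_mean_qual >= 0,
            min_src_mean_qual >= 0, c_score_min >= 0)
  structure(list(min_depth = as.integer(min_depth),
                 min_conseq_mean_qual = min_conseq_mean_qual,
                 min_src_mean_qual = min_src_mean_qual,
                 c_score_min = c_score_min,
                 include_srcs = isTRUE(include_srcs)),
            class = "filter_params")
}

# SRC rows reshaped to the conseq column layout (depth 1, no c-score)
srcs_as_records <- function(srcs) {
  if (nrow(srcs) == 0L) {
    return(tibble::tibble(key = character(), depth = integer(), n_used = integer(),
                          discarded = integer(), seq = character(), qual = character(),
                          mean_qual = numeric(), c_score = numeric(), type = character()))
  }
  tibble::tibble(
    key = srcs$key, depth = 1L, n_used = 1L, discarded = 0L,
    seq = srcs$amplicon_seq, qual = srcs$amplicon_qual,
    mean_qual = mean_qual(srcs$amplicon_qual),
    c_score = NA_real_, type = "src"
  )
}

#' Filter consensus sequences and SRCs by depth, quality and c-score
#'
#' Each record is kept or removed with a single reason: `low_depth` (depth
#' below `min_depth`; also SRCs when `include_srcs` is off), `low_mean_qual`,
#' or `low_c_score` (c-score `<= c_score_min`). SRCs are never c-score
#' filtered (no c-score exists at depth 1). Every input appears exactly once
#' across kept and removed.
#'
#' @param conseqs Conseq tibble from [call_consensus()].
#' @param srcs SRC tibble from [categorize()] (may have 0 rows).
#' @param params A [filter_params()].
#' @return List with `kept` and `removed` tibbles; `removed` carries a
#'   `reason` column; both carry a `type` column (`"conseq"` or `"src"`).
#' @export
apply_filters <- function(conseqs, srcs = NULL, params = filter_params()) {
  cq <- dplyr::mutate(conseqs, type = "conseq")
  cq <- dplyr::mutate(
    cq,
    reason = dplyr::case_when(
      .data$depth < params$min_depth ~ "low_depth",
      .data$mean_qual < params$min_conseq_mean_qual ~ "low_mean_qual",
      .data$c_score <= params$c_score_min ~ "low_c_score",
      TRUE ~ NA_character_
    )
  )
  sr <- srcs_as_records(if (is.null(srcs)) conseqs[0, ] else srcs)
  if (nrow(sr)) {
    sr$reason <- if (!params$include_srcs) {
      "low_depth"
    } else {
      ifelse(sr$mean_qual < params$min_src_mean_qual, "low_mean_qual", NA_character_)
    }
  } else {
    sr$reason <- character()
  }
  all <- dplyr::bind_rows(cq, sr)
  list(
    kept = dplyr::select(dplyr::filter(all, is.na(.data$reason)), -"reason"),
    removed = dplyr::filter(all, !is.na(.data$reason))
  )
}
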