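#' Run the molecule-tag consensus pipeline end to end
#'
#' Orchestrates (optional) paired-end merging, structure parsing, tag
#' binning, digital normalization, consensus calling and QC filtering, with
#' full read accounting: every raw read is either merge-failed, unmatched, or
#' categorizable, and categorizable reads are exactly the category depths
#' plus the SRCs.
#'
#' @param input Read tibble or FASTQ path. For `mode = "paired_merge"` the
#'   forward mates; otherwise the only input.
#' @param input2 Reverse-mate tibble or FASTQ path (paired modes only).
#' @param spec A [structure_spec()]. For `paired_merge`, a whole-fragment
#'   layout spec (`merged_pair`); for `paired_separate`, any spec — its
#'   forward/reverse halves are matched against the respective mates.
#' @param mode `"single"` (one file, layout taken from `spec`),
#'   `"paired_merge"` (overlap-merge mates, then treat as merged reads) or
#'   `"paired_separate"` (non-overlapping mates; forward and reverse amplicon
#'   regions are consensused independently per tag key).
#' @param merge_p A [merge_params()].
#' @param filter_p A [filter_params()].
#' @param max_depth Optional digital-normalization depth cap.
#' @param seed Integer seed (subsampling); a seeded run is byte-reproducible.
#' @param out_dir Optional directory; when given, ConSeq/SRC/filtered FASTQ,
#'   the per-category TSV, a summary TSV and a run log are written there.
#' @return An `mt_run` object: list with `conseqs` (kept), `removed`, `srcs`,
#'   `categories`, `summary` (named list of counts), `depth_histogram`, and
#'   for `paired_separate` a second set of reverse-side tables under `rev`.
#' @export
run_pipeline <- function(input, input2 = NULL, spec,
                         mode = c("single", "paired_merge", "paired_separate"),
                         merge_p = merge_params(), filter_p = filter_params(),
                         max_depth = NULL, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  reads <- if (is.character(input)) read_fastq(input, mate = if (mode == "single") "single" else "fwd") else input
  reads2 <- if (!is.null(input2)) {
    if (is.character(input2)) read_fastq(input2, mate = "rev") else input2
  } else NULL
  if (mode != "single" && is.null(reads2)) {
    stop("paired modes need a second input", call. = FALSE)
  }
  if (mode == "single" && !is.null(reads2)) {
    stop("mode 'single' takes one input", call. = FALSE)
  }

  n_raw <- nrow(reads) + if (is.null(reads2)) 0L else nrow(reads2)
  n_merge_failed <- 0L

  # accounting units: one single-end read, one merged pair, or one mate pair;
  # reads_per_unit converts units back to raw reads
  reads_per_unit <- if (mode == "single") 1L else 2L

  if (mode == "paired_merge") {
    if (nrow(reads) != nrow(reads2)) stop("mate files differ in read count", call. = FALSE)
    mg <- merge_pairs(reads, reads2, merge_p)
    n_merge_failed <- sum(!mg$merged)
    reads <- mg[mg$merged, c("id", "seq", "qual")]
  }

  if (mode == "paired_separate") {
    res <- run_separate_pair(reads, reads2, spec, filter_p, max_depth, seed)
  } else {
    parsed <- parse_reads(reads, compile_matcher(spec))
    bins <- categorize(parsed)
    conseqs <- call_consensus(bins$categories, max_depth = max_depth, seed = seed)
    filt <- apply_filters(conseqs, bins$srcs, filter_p)
    res <- list(parsed = parsed, bins = bins, conseqs = conseqs, filt = filt,
                n_unmatched = sum(!parsed$matched),
                n_categorizable = sum(parsed$matched))
  }

  depth_hist <- if (nrow(res$bins$categories) || nrow(res$bins$srcs)) {
    dplyr::bind_rows(
      dplyr::distinct(res$bins$categories, .data$key, .data$depth),
      dplyr::distinct(res$bins$srcs, .data$key, .data$depth)
    ) |>
      dplyr::count(.data$depth, name = "n_categories") |>
      dplyr::arrange(.data$depth)
  } else {
    tibble::tibble(depth = integer(), n_categories = integer())
  }

  removed_by_reason <- if (nrow(res$filt$removed)) {
    tab <- table(res$filt$removed$reason)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer()
  }
  kept_conseqs <- dplyr::filter(res$filt$kept, .data$type == "conseq")
  summary <- list(
    n_raw = n_raw,
    reads_per_unit = reads_per_unit,
    n_merge_failed = n_merge_failed,
    n_unmatched = res$n_unmatched,
    n_categorizable = res$n_categorizable,
    n_categories = length(unique(res$bins$categories$key)),
    n_srcs = nrow(res$bins$srcs),
    n_conseqs = nrow(res$conseqs),
    n_conseqs_kept = nrow(kept_conseqs),
    n_kept_total = nrow(res$filt$kept),
    n_removed = nrow(res$filt$removed),
    n_removed_by_reason = removed_by_reason
  )

  run <- structure(list(
    conseqs = res$filt$kept, removed = res$filt$removed,
    all_conseqs = res$conseqs, srcs = res$bins$srcs,
    categories = res$bins$categories, parsed = res$parsed,
    summary = summary, depth_histogram = depth_hist,
    rev = res$rev, mode = mode, seed = seed
  ), class = "mt_run")

  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

# non-overlapping pair path: consensus fwd and rev amplicon regions
# independently per joint tag key
run_separate_pair <- function(r1, r2, spec, filter_p, max_depth, seed) {
  # one unit = one mate pair
  spec_f <- spec; spec_f$layout <- "fwd_of_pair"
  spec_r <- spec; spec_r$layout <- "rev_of_pair"
  p1 <- parse_reads(r1, compile_matcher(spec_f))
  p2 <- parse_reads(r2, compile_matcher(spec_r))
  ord2 <- match(p1$id, p2$id)
  p2 <- p2[ord2, , drop = FALSE]
  ok <- p1$matched & !is.na(ord2) & p2$matched
  # joint key across mates; reverse mate's tag read in reverse-strand
  # orientation already
  joint_key <- tag_key(p1$fwd_tag, p2$rev_tag)
  fwd_side <- tibble::tibble(
    id = p1$id, matched = ok, fwd_tag = p1$fwd_tag, rev_tag = p2$rev_tag,
    key = ifelse(ok, joint_key, NA_character_),
    amplicon_seq = p1$amplicon_seq, amplicon_qual = p1$amplicon_qual
  )
  rev_side <- tibble::tibble(
    id = p2$id, matched = ok, fwd_tag = p1$fwd_tag, rev_tag = p2$rev_tag,
    key = ifelse(ok, joint_key, NA_character_),
    amplicon_seq = p2$amplicon_seq, amplicon_qual = p2$amplicon_qual
  )
  bins_f <- categorize(fwd_side)
  bins_r <- categorize(rev_side)
  conseqs_f <- call_consensus(bins_f$categories, max_depth = max_depth, seed = seed)
  conseqs_r <- call_consensus(bins_r$categories, max_depth = max_depth, seed = seed)
  filt_f <- apply_filters(conseqs_f, bins_f$srcs, filter_p)
  filt_r <- apply_filters(conseqs_r, bins_r$srcs, filter_p)
  list(
    parsed = fwd_side, bins = bins_f, conseqs = conseqs_f, filt = filt_f,
    n_unmatched = sum(!ok),
    n_categorizable = sum(ok),
    rev = list(parsed = rev_side, bins = bins_r, conseqs = conseqs_r, filt = filt_r)
  )
}

conseq_fastq_tbl <- function(tbl) {
  tibble::tibble(
    id = tbl$key,
    comment = sprintf("key=%s depth=%d n_used=%d c_score=%s",
                      tbl$key, tbl$depth, tbl$n_used,
                      ifelse(is.na(tbl$c_score), "NA", sprintf("%.4f", tbl$c_score))),
    seq = tbl$seq, qual = tbl$qual
  )
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kept_conseqs <- dplyr::filter(run$conseqs, .data$type == "conseq")
  kept_srcs <- dplyr::filter(run$conseqs, .data$type == "src")
  write_fastq(conseq_fastq_tbl(kept_conseqs), file.path(out_dir, "conseqs.fastq"))
  src_tbl <- if (nrow(run$srcs)) {
    tibble::tibble(id = run$srcs$key,
                   comment = sprintf("key=%s depth=1", run$srcs$key),
                   seq = run$srcs$amplicon_seq, qual = run$srcs$amplicon_qual)
  } else {
    tibble::tibble(id = character(), comment = character(),
                   seq = character(), qual = character())
  }
  write_fastq(src_tbl, file.path(out_dir, "srcs.fastq"))
  removed <- run$removed
  write_fastq(conseq_fastq_tbl(removed), file.path(out_dir, "filtered.fastq"))

  cat_tbl <- dplyr::bind_rows(
    dplyr::mutate(run$conseqs, kept = TRUE, reason = NA_character_),
    dplyr::mutate(run$removed, kept = FALSE)
  ) |>
    dplyr::select("key", "type", "depth", "n_used", "discarded",
                  "mean_qual", "c_score", "kept", "reason") |>
    dplyr::arrange(.data$key)
  readr::write_tsv(cat_tbl, file.path(out_dir, "categories.tsv"))

  s <- run$summary
  summary_tbl <- tibble::tibble(
    metric = c("n_raw", "reads_per_unit", "n_merge_failed", "n_unmatched", "n_categorizable",
               "n_categories", "n_srcs", "n_conseqs", "n_conseqs_kept",
               "n_kept_total", "n_removed",
               paste0("removed_", names(s$n_removed_by_reason))),
    value = c(s$n_raw, s$reads_per_unit, s$n_merge_failed, s$n_unmatched, s$n_categorizable,
              s$n_categories, s$n_srcs, s$n_conseqs, s$n_conseqs_kept,
              s$n_kept_total, s$n_removed,
              unname(s$n_removed_by_reason))
  )
  readr::write_tsv(summary_tbl, file.path(out_dir, "summary.tsv"))

  log_lines <- c(
    "molecule-tag consensus run",
    sprintf("mode: %s  seed: %d", run$mode, run$seed),
    sprintf("raw reads: %d", s$n_raw),
    sprintf("merge-failed: %d  unmatched: %d  categorizable: %d",
            s$n_merge_failed, s$n_unmatched, s$n_categorizable),
    sprintf("categories (depth>=2): %d  SRCs: %d", s$n_categories, s$n_srcs),
    sprintf("conseqs kept: %d of %d  removed: %d",
            s$n_conseqs_kept, s$n_conseqs, s$n_removed)
  )
  readr::write_lines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.mt_run <- function(x, ...) {
  s <- x$summary
  cat("<mt_run>", x$mode, "mode\n")
  cat(sprintf("  raw reads:       %d\n", s$n_raw))
  cat(sprintf("  categorizable:   %d (unmatched %d, merge-failed %d)\n",
              s$n_categorizable, s$n_unmatched, s$n_merge_failed))
  cat(sprintf("  MT categories:   %d (+ %d SRCs)\n", s$n_categories, s$n_srcs))
  cat(sprintf("  conseqs kept:    %d of %d\n", s$n_conseqs_kept, s$n_conseqs))
  invisible(x)
}

#' Tidy per-category table of a pipeline run
#'
#' @param x An `mt_run`.
#' @param ... Unused.
#' @return Tibble with one row per consensus/SRC record: key, type, depth,
#'   quality and filtering outcome.
#' @export
tidy.mt_run <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$conseqs, kept = TRUE, reason = NA_character_),
    dplyr::mutate(x$removed, kept = FALSE)
  ) |>
    dplyr::select("key", "type", "depth", "n_used", "discarded",
                  "mean_qual", "c_score", "kept", "reason") |>
    dplyr::arrange(.data$key)
}

#' One-row run summary
#'
#' @param x An `mt_run`.
#' @param ... Unused.
#' @return One-row tibble of the run's counts.
#' @export
glance.mt_run <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_raw = s$n_raw, n_merge_failed = s$n_merge_failed,
    n_unmatched = s$n_unmatched, n_categorizable = s$n_categorizable,
    n_categories = s$n_categories, n_srcs = s$n_srcs,
    n_conseqs = s$n_conseqs, n_conseqs_kept = s$n_conseqs_kept,
    n_removed = s$n_removed
  )
}
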