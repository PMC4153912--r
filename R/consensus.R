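#' Bin parsed reads into molecule-tag categories
#'
#' Every matched read lands in exactly one category, keyed by its tag key.
#' Categories seen in a single read carry no consensus information and are
#' returned separately as single-read categories (SRCs).
#'
#' @param parsed Parsed-read tibble from [parse_reads()]; unmatched rows are
#'   dropped with a warning-free filter (they are accounted for upstream).
#' @return A list with `categories` (tibble of reads belonging to keys of
#'   depth >= 2, with a `depth` column) and `srcs` (tibble of depth-1 reads).
#'   The depth sum plus the SRC count equals the number of matched reads.
#' @export
categorize <- function(parsed) {
  matched <- dplyr::filter(parsed, .data$matched)
  if (nrow(matched) == 0L) {
    return(list(categories = dplyr::mutate(matched, depth = integer()),
                srcs = dplyr::mutate(matched, depth = integer())))
  }
  matched <- dplyr::add_count(matched, .data$key, name = "depth")
  list(
    categories = dplyr::filter(matched, .data$depth >= 2L),
    srcs = dplyr::filter(matched, .data$depth == 1L)
  )
}

#' Keep the dominant length cluster of a category
#'
#' Reads of one tag category almost always share a length; when they do not,
#' reads are binned by exact amplicon length and only the largest bin is
#' stacked. A tie between largest bins is resolved deterministically in
#' favour of the greatest length.
#'
#' @param cat Tibble of one category's reads (column `amplicon_seq`).
#' @return List with `used` (the winning bin's rows) and `discarded` (count
#'   of reads dropped).
#' @export
length_cluster <- function(cat) {
  len <- nchar(cat$amplicon_seq)
  tab <- table(len)
  sizes <- as.integer(tab)
  lens <- as.integer(names(tab))
  win <- lens[sizes == max(sizes)]
  win_len <- max(win)
  keep <- len == win_len
  list(used = cat[keep, , drop = FALSE], discarded = sum(!keep))
}

#' Stack equal-length reads into an alignment matrix
#'
#' Rows are reads, columns positions; bases and qualities are taken verbatim
#' (no gaps). All reads must share one length — [length_cluster()] guarantees
#' this upstream.
#'
#' @param used Tibble of reads (columns `id`, `amplicon_seq`,
#'   `amplicon_qual`), all the same length.
#' @return An `alignment_matrix`: list with `bases` (character matrix),
#'   `quals` (integer matrix) and `member_ids`.
#' @export
stack_reads <- function(used) {
  lens <- nchar(used$amplicon_seq)
  if (length(unique(lens)) > 1L) {
    stop("cannot stack reads of unequal length; run length_cluster() first", call. = FALSE)
  }
  bases <- do.call(rbind, strsplit(used$amplicon_seq, "", fixed = TRUE))
  quals <- do.call(rbind, phred_decode(used$amplicon_qual))
  if (is.null(bases)) bases <- matrix(character(), 0L, 0L)
  if (is.null(quals)) quals <- matrix(integer(), 0L, 0L)
  structure(list(bases = bases, quals = quals, member_ids = used$id),
            class = "alignment_matrix")
}

BASES4 <- c("A", "C", "G", "T")

#' Call the consensus base of one alignment column
#'
#' The mode base wins; its quality is the rounded mean quality of the
#' observations carrying it. A count tie goes to the tied base with the
#' highest mean quality; an exact quality tie falls back to the IUPAC code
#' covering the tied bases, with quality the rounded mean over all their
#' observations. `N` observations carry no base information and are excluded
#' from counting (an all-`N` column yields `N`).
#'
#' @param bases Character vector of one column's bases.
#' @param quals Integer vector of matching Phred qualities.
#' @return List with `base` (single character, possibly an IUPAC ambiguity
#'   code) and `qual` (integer, capped at 93).
#' @export
consensus_column <- function(bases, quals) {
  stopifnot(length(bases) == length(quals), length(bases) >= 1L)
  informative <- bases != "N"
  if (!any(informative)) {
    return(list(base = "N", qual = as.integer(min(93, round_half_up(mean(quals))))))
  }
  b <- bases[informative]
  q <- quals[informative]
  idx <- match(b, BASES4)
  counts <- tabulate(idx, 4L)
  top <- which(counts == max(counts))
  if (length(top) == 1L) {
    sel <- idx == top
    return(list(base = BASES4[top],
                qual = as.integer(min(93, round_half_up(mean(q[sel]))))))
  }
  mq <- vapply(top, function(k) mean(q[idx == k]), numeric(1))
  best <- top[abs(mq - max(mq)) < 1e-9]
  if (length(best) == 1L) {
    sel <- idx == best
    return(list(base = BASES4[best],
                qual = as.integer(min(93, round_half_up(mean(q[sel]))))))
  }
  sel <- idx %in% best
  list(base = iupac_code_for(BASES4[best]),
       qual = as.integer(min(93, round_half_up(mean(q[sel])))))
}

# consensus over all columns of an alignment matrix -> list(seq, qual_int)
consensus_of_matrix <- function(M) {
  L <- ncol(M$bases)
  if (L == 0L) return(list(seq = "", qual = integer()))
  out_b <- character(L)
  out_q <- integer(L)
  for (j in seq_len(L)) {
    cc <- consensus_column(M$bases[, j], M$quals[, j])
    out_b[j] <- cc$base
    out_q[j] <- cc$qual
  }
  list(seq = paste(out_b, collapse = ""), qual = out_q)
}

#' Build the consensus sequence of one molecule-tag category
#'
#' Applies [length_cluster()], [stack_reads()] and [consensus_column()]
#' column by column, then scores the result with [c_score()]. Categories of
#' depth 1 take the SRC path and are rejected here.
#'
#' @param cat Tibble of one category's reads (>= 2 rows).
#' @return One-row tibble: `key`, `depth`, `n_used`, `discarded`, `seq`,
#'   `qual` (Phred+33 string), `mean_qual`, `c_score`.
#' @export
build_conseq <- function(cat) {
  if (nrow(cat) < 2L) {
    stop("consensus needs depth >= 2; depth-1 categories are SRCs", call. = FALSE)
  }
  lc <- length_cluster(cat)
  M <- stack_reads(lc$used)
  cons <- consensus_of_matrix(M)
  cs <- c_score(M, cons$seq)
  tibble::tibble(
    key = cat$key[1],
    depth = nrow(cat),
    n_used = nrow(lc$used),
    discarded = lc$discarded,
    seq = cons$seq,
    qual = phred_encode(cons$qual),
    mean_qual = mean(as.numeric(cons$qual)),
    c_score = cs
  )
}

#' Cap a category's depth by seeded uniform subsampling
#'
#' Digital normalization: categories deeper than `max_depth` are reduced to a
#' reproducible uniform subsample, bounding consensus runtime with minimal
#' accuracy cost.
#'
#' @param cat Tibble of one category's reads.
#' @param max_depth Depth cap (`>= 2`).
#' @param seed Integer seed making the subsample reproducible.
#' @return The category tibble, subsampled if it exceeded `max_depth`.
#' @export
subsample_category <- function(cat, max_depth, seed) {
  stopifnot(max_depth >= 2L)
  if (nrow(cat) <= max_depth) return(cat)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  cat[sort(sample.int(nrow(cat), max_depth)), , drop = FALSE]
}

#' Call consensus sequences for every category
#'
#' @param categories Category tibble from [categorize()] (reads of all keys
#'   with depth >= 2).
#' @param max_depth Optional digital-normalization cap passed to
#'   [subsample_category()].
#' @param seed Seed used to derive per-category subsampling seeds.
#' @return Tibble of consensus sequences, one row per key, in key order
#'   (deterministic).
#' @export
call_consensus <- function(categories, max_depth = NULL, seed = 1L) {
  if (nrow(categories) == 0L) {
    return(tibble::tibble(key = character(), depth = integer(), n_used = integer(),
                          discarded = integer(), seq = character(), qual = character(),
                          mean_qual = numeric(), c_score = numeric()))
  }
  keys <- sort(unique(categories$key))
  split_cats <- split(categories, factor(categories$key, levels = keys))
  purrr::imap_dfr(split_cats, function(cat, key) {
    if (!is.null(max_depth)) {
      k <- match(key, keys)
      cat <- subsample_category(cat, max_depth, seed = (as.numeric(seed) + k) %% 2147483647)
    }
    build_conseq(cat)
  })
}
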