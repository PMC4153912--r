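#' Describe the structure of a molecule-tagged read
#'
#' A read produced by a molecule-tagging protocol is, 5' to 3':
#' `[fwd tag][fwd linker][fwd primer][amplicon][rc(rev primer)][rc(rev linker)][rc(rev tag)]`
#' with the 3' structure present only when the read spans the whole fragment
#' (single-end or merged paired-end reads). The reverse primer and linker are
#' given as written 5'->3' on the reverse strand, the way they appear on an
#' order sheet.
#'
#' @param fwd_mt_len,rev_mt_len Molecule-tag lengths in nt (`>= 0`; at least
#'   one must be positive).
#' @param fwd_primer,rev_primer Primer sequences, IUPAC codes allowed.
#' @param fwd_linker,rev_linker Optional linker/spacer sequences between tag
#'   and primer, IUPAC codes allowed; default empty.
#' @param layout One of `"merged_pair"`, `"single_end"`, `"fwd_of_pair"`,
#'   `"rev_of_pair"`. The first two expect both 5' and 3' structure on the
#'   read; `fwd_of_pair` expects only the 5' structure; `rev_of_pair` matches
#'   the reverse-strand structure at the read's 5' end.
#' @return A `structure_spec` object.
#' @export
structure_spec <- function(fwd_mt_len = 0L, fwd_linker = "", fwd_primer = "",
                           rev_primer = "", rev_linker = "", rev_mt_len = 0L,
                           layout = c("merged_pair", "single_end", "fwd_of_pair", "rev_of_pair")) {
  layout <- match.arg(layout)
  fwd_mt_len <- as.integer(fwd_mt_len)
  rev_mt_len <- as.integer(rev_mt_len)
  stopifnot(fwd_mt_len >= 0L, rev_mt_len >= 0L)
  if (fwd_mt_len == 0L && rev_mt_len == 0L) {
    stop("at least one molecule-tag length must be positive", call. = FALSE)
  }
  for (s in c(fwd_linker, fwd_primer, rev_primer, rev_linker)) {
    if (nchar(s) && grepl("[^ACGTRYSWKMBVDHN]", toupper(s))) {
      stop("invalid IUPAC character in structure sequence: ", s, call. = FALSE)
    }
  }
  needs_fwd <- layout %in% c("merged_pair", "single_end", "fwd_of_pair")
  needs_rev <- layout %in% c("merged_pair", "single_end", "rev_of_pair")
  if (needs_fwd && !nchar(fwd_primer)) stop("fwd_primer must be non-empty for layout ", layout, call. = FALSE)
  if (needs_rev && !nchar(rev_primer)) stop("rev_primer must be non-empty for layout ", layout, call. = FALSE)
  structure(
    list(fwd_mt_len = fwd_mt_len, fwd_linker = toupper(fwd_linker),
         fwd_primer = toupper(fwd_primer), rev_primer = toupper(rev_primer),
         rev_linker = toupper(rev_linker), rev_mt_len = rev_mt_len,
         layout = layout),
    class = "structure_spec"
  )
}

#' @export
print.structure_spec <- function(x, ...) {
  cat("<structure_spec> layout:", x$layout, "\n")
  cat("  5':", sprintf("MT(%d) + %s + %s", x$fwd_mt_len,
                       if (nchar(x$fwd_linker)) x$fwd_linker else "-",
                       if (nchar(x$fwd_primer)) x$fwd_primer else "-"), "\n")
  cat("  3':", sprintf("%s + %s + MT(%d) (reverse strand)",
                       if (nchar(x$rev_primer)) x$rev_primer else "-",
                       if (nchar(x$rev_linker)) x$rev_linker else "-", x$rev_mt_len), "\n")
  invisible(x)
}

# tag region pattern: tags are random, so any read base (incl. N) is accepted
tag_pattern <- function(len, name) {
  if (len == 0L) return("")
  sprintf("(?<%s>[ACGTN]{%d})", name, len)
}

#' Compile a structure spec into a read matcher
#'
#' Builds an anchored regular expression with named capture groups for the
#' tag(s) and the amplicon. Matching is exact and IUPAC-aware: a degenerate
#' primer position matches any base in its expansion, but no mismatches are
#' tolerated.
#'
#' @param spec A [structure_spec()].
#' @return A `structure_matcher` object (the compiled pattern plus the spec).
#' @export
compile_matcher <- function(spec) {
  stopifnot(inherits(spec, "structure_spec"))
  fwd5 <- paste0(
    tag_pattern(spec$fwd_mt_len, "fwdtag"),
    if (nchar(spec$fwd_linker)) iupac_regex(spec$fwd_linker) else "",
    if (nchar(spec$fwd_primer)) iupac_regex(spec$fwd_primer) else ""
  )
  rev3 <- paste0(
    if (nchar(spec$rev_primer)) iupac_regex(reverse_complement(spec$rev_primer)) else "",
    if (nchar(spec$rev_linker)) iupac_regex(reverse_complement(spec$rev_linker)) else "",
    tag_pattern(spec$rev_mt_len, "revtag")
  )
  pattern <- switch(
    spec$layout,
    merged_pair = ,
    single_end = paste0("^", fwd5, "(?<amp>[ACGTN]*?)", rev3, "[ACGTN]*$"),
    fwd_of_pair = paste0("^", fwd5, "(?<amp>[ACGTN]*)$"),
    rev_of_pair = paste0(
      "^",
      tag_pattern(spec$rev_mt_len, "revtag"),
      if (nchar(spec$rev_linker)) iupac_regex(spec$rev_linker) else "",
      if (nchar(spec$rev_primer)) iupac_regex(spec$rev_primer) else "",
      "(?<amp>[ACGTN]*)$"
    )
  )
  structure(list(pattern = pattern, spec = spec), class = "structure_matcher")
}

#' Decompose reads into tag, primer and amplicon regions
#'
#' Applies a compiled matcher to every read. Non-matching reads are a normal
#' outcome (`matched = FALSE`); region qualities are exact slices of the
#' source read's quality string. For whole-fragment layouts the reverse tag is
#' reported in reverse-strand orientation so that keys agree across layouts.
#'
#' @param reads Read tibble from [read_fastq()] (columns `id`, `seq`, `qual`).
#' @param matcher A [compile_matcher()] result (a bare [structure_spec()] is
#'   compiled on the fly).
#' @return A tibble with one row per input read: `id`, `matched`, `fwd_tag`,
#'   `rev_tag`, `key` (see [tag_key()]), `amplicon_seq`, `amplicon_qual`.
#' @export
parse_reads <- function(reads, matcher) {
  if (inherits(matcher, "structure_spec")) matcher <- compile_matcher(matcher)
  stopifnot(inherits(matcher, "structure_matcher"))
  spec <- matcher$spec
  n <- nrow(reads)
  out <- tibble::tibble(
    id = reads$id, matched = FALSE,
    fwd_tag = NA_character_, rev_tag = NA_character_, key = NA_character_,
    amplicon_seq = NA_character_, amplicon_qual = NA_character_
  )
  if (n == 0L) return(out)

  m <- regexpr(matcher$pattern, reads$seq, perl = TRUE)
  hit <- m != -1L
  out$matched <- hit
  if (!any(hit)) return(out)

  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  grab <- function(x, name, idx) {
    if (!name %in% colnames(cs)) return(rep(NA_character_, length(idx)))
    s <- cs[idx, name]
    l <- cl[idx, name]
    substr(x[idx], s, s + l - 1L)
  }
  idx <- which(hit)
  if (spec$fwd_mt_len > 0L) out$fwd_tag[idx] <- grab(reads$seq, "fwdtag", idx)
  if (spec$rev_mt_len > 0L) {
    rt <- grab(reads$seq, "revtag", idx)
    # reverse-strand orientation for whole-fragment layouts
    if (spec$layout %in% c("merged_pair", "single_end")) rt <- reverse_complement(rt)
    out$rev_tag[idx] <- rt
  }
  out$amplicon_seq[idx] <- grab(reads$seq, "amp", idx)
  out$amplicon_qual[idx] <- grab(reads$qual, "amp", idx)
  out$key[idx] <- tag_key(out$fwd_tag[idx], out$rev_tag[idx])
  out
}

#' Build the tag key identifying a molecule-tag category
#'
#' The key is the forward tag, the reverse tag, or `fwd + "+" + rev` when
#' both tags exist.
#'
#' @param fwd_tag,rev_tag Character vectors (either may be `NA` where the
#'   structure has no such tag).
#' @return Character vector of keys.
#' @export
tag_key <- function(fwd_tag, rev_tag = NA_character_) {
  dplyr::case_when(
    !is.na(fwd_tag) & !is.na(rev_tag) ~ paste0(fwd_tag, "+", rev_tag),
    !is.na(fwd_tag) ~ fwd_tag,
    !is.na(rev_tag) ~ rev_tag,
    TRUE ~ NA_character_
  )
}
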