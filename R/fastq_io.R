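#' Read a FASTQ file into a read tibble
#'
#' Parses standard 4-line FASTQ (Sanger/Phred+33 qualities). Sequences are
#' uppercased; qualities are kept as the encoded string (decode on demand with
#' [phred_decode()]).
#'
#' @param path Path to a FASTQ file.
#' @param mate One of `"single"`, `"fwd"`, `"rev"`; recorded in the `mate`
#'   column.
#' @param lenient If `TRUE`, bases outside the accepted alphabet are mapped
#'   to `N` instead of raising an error.
#' @param allow_iupac If `TRUE`, accept the full IUPAC alphabet (needed to
#'   read consensus FASTQ, whose ambiguity calls are IUPAC codes); by default
#'   only `A/C/G/T/N` raw-read bases are accepted.
#' @return A tibble with columns `id` (first header token), `comment`
#'   (remainder of the header, `NA` if none), `seq`, `qual` (Phred+33 string)
#'   and `mate`, one row per read, in file order.
#' @export
read_fastq <- function(path, mate = c("single", "fwd", "rev"), lenient = FALSE,
                       allow_iupac = FALSE) {
  mate <- match.arg(mate)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: number of lines not a multiple of 4 in ", path, call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(tibble::tibble(id = character(), comment = character(),
                          seq = character(), qual = character(), mate = character()))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]

  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    stop("malformed FASTQ record ", bad_hdr[1], ": header does not start with '@'", call. = FALSE)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop("malformed FASTQ record ", bad_plus[1], ": separator line does not start with '+'", call. = FALSE)
  }
  bad_len <- which(nchar(seq) != nchar(qual))
  if (length(bad_len)) {
    stop("malformed FASTQ record ", bad_len[1], ": sequence and quality lengths differ", call. = FALSE)
  }
  alphabet <- if (allow_iupac) "ACGTRYSWKMBVDHN" else "ACGTN"
  bad_re <- paste0("[^", alphabet, "]")
  bad_base <- grepl(bad_re, seq)
  if (any(bad_base)) {
    if (lenient) {
      seq[bad_base] <- gsub(bad_re, "N", seq[bad_base])
    } else {
      stop("non-", alphabet, " base in record ", which(bad_base)[1],
           " (use lenient = TRUE to map to N)", call. = FALSE)
    }
  }
  bad_q <- grepl("[^!-~]", qual)
  if (any(bad_q)) {
    stop("quality characters outside Phred+33 range in record ", which(bad_q)[1], call. = FALSE)
  }

  hdr <- sub("^@", "", hdr)
  id <- sub("\\s.*$", "", hdr)
  comment <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), NA_character_)
  if (any(id == "")) {
    stop("malformed FASTQ record ", which(id == "")[1], ": empty read id", call. = FALSE)
  }
  tibble::tibble(id = id, comment = comment, seq = seq, qual = qual, mate = mate)
}

#' Write a read tibble to FASTQ
#'
#' Round-trips with [read_fastq()]: writing then reading recovers the same
#' `id`, `seq` and `qual` columns.
#'
#' @param reads Tibble with columns `id`, `seq`, `qual` and optionally
#'   `comment` (written after the id, space-separated).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) == 0L) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  if (any(grepl("[^!-~]", reads$qual))) {
    stop("quality outside the encodable Phred+33 range", call. = FALSE)
  }
  hdr <- paste0("@", reads$id)
  if ("comment" %in% names(reads)) {
    has_c <- !is.na(reads$comment) & reads$comment != ""
    hdr[has_c] <- paste(hdr[has_c], reads$comment[has_c])
  }
  out <- character(4L * nrow(reads))
  out[seq(1L, by = 4L, length.out = nrow(reads))] <- hdr
  out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$seq
  out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = nrow(reads))] <- reads$qual
  readr::write_lines(out, path)
  invisible(path)
}
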