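#' Decode Phred+33 quality strings to integer scores
#'
#' Quality scores travel through the package as Sanger-encoded (Phred+33)
#' ASCII strings, the representation they have on disk in FASTQ. This decodes
#' one or more such strings into integer vectors.
#'
#' @param qual Character vector of quality strings.
#' @return A list of integer vectors (one per input string), each value in
#'   `[0, 93]`.
#' @examples
#' phred_decode("IIII") # Phred 40 at every position
#' @export
phred_decode <- function(qual) {
  stopifnot(is.character(qual))
  lapply(qual, function(q) {
    if (is.na(q)) return(NA_integer_)
    v <- utf8ToInt(q) - 33L
    if (length(v) && (min(v) < 0L || max(v) > 93L)) {
      stop("quality character outside the Sanger (Phred+33) range", call. = FALSE)
    }
    v
  })
}

#' Encode integer Phred scores as a Phred+33 quality string
#'
#' @param scores Integer vector of Phred scores in `[0, 93]`.
#' @return A single quality string.
#' @examples
#' phred_encode(c(40L, 40L, 2L))
#' @export
phred_encode <- function(scores) {
  scores <- as.integer(scores)
  if (anyNA(scores) || (length(scores) && (min(scores) < 0L || max(scores) > 93L))) {
    stop("Phred scores must be integers in [0, 93]", call. = FALSE)
  }
  if (!length(scores)) return("")
  intToUtf8(scores + 33L)
}

# round-half-up; base round() is round-half-even, which would make mean
# qualities like 30.5 depend on parity
round_half_up <- function(x) floor(x + 0.5)

# mean Phred quality of one quality string (NA-safe for unmatched reads)
mean_qual <- function(qual) {
  vapply(phred_decode(qual), function(v) mean(as.numeric(v)), numeric(1))
}
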