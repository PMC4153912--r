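# IUPAC nucleotide code tables. Degenerate primers and ambiguous consensus
# bases both use this alphabet.
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# reverse lookup: sorted expansion -> code
IUPAC_CODE_OF <- local({
  keys <- vapply(IUPAC_CLASSES, function(x) paste(sort(x), collapse = ""), character(1))
  stats::setNames(names(IUPAC_CLASSES), keys)
})

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code A single IUPAC DNA character (one of the 15 codes).
#' @return Character vector of the plain bases the code covers.
#' @examples
#' iupac_to_class("R") # A, G
#' iupac_to_class("N") # A, C, G, T
#' @export
iupac_to_class <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  cls <- IUPAC_CLASSES[[toupper(code)]]
  if (is.null(cls)) stop("unknown IUPAC code: ", code, call. = FALSE)
  cls
}

# code covering a set of plain bases (e.g. c("A","G") -> "R")
iupac_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC_CODE_OF[[key]]
  if (is.null(code)) stop("not a valid base set: ", key, call. = FALSE)
  code
}

#' Reverse-complement DNA sequences
#'
#' Complementation is defined on the full IUPAC alphabet, so degenerate
#' primers reverse-complement correctly.
#'
#' @param seq Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT") # self-complementary
#' reverse_complement("AAR")  # "YTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl(paste0("[^", paste(names(IUPAC_COMPLEMENT), collapse = ""), "]"), seq)
  if (any(bad, na.rm = TRUE)) {
    stop("invalid IUPAC character in sequence", call. = FALSE)
  }
  comp <- chartr("ACGTRYSWKMBVDHN", "TGCAYRSWMKVBHDN", seq)
  vapply(comp, function(s) {
    if (is.na(s)) return(NA_character_)
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# reverse a string (used for quality strings alongside reverse_complement)
str_reverse <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# regex character class matching one IUPAC pattern character against a plain
# ACGT(N-free) read base
iupac_regex <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    cls <- iupac_to_class(ch)
    if (length(cls) == 1L) cls else paste0("[", paste(cls, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# does IUPAC code `code` cover plain base `base`? Vectorised via lookup matrix.
IUPAC_COVERS <- local({
  codes <- names(IUPAC_CLASSES)
  m <- matrix(FALSE, length(codes), 4, dimnames = list(codes, c("A", "C", "G", "T")))
  for (cd in codes) m[cd, IUPAC_CLASSES[[cd]]] <- TRUE
  m
})
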