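## Fixed alphabet of the concatenated pangenome text.
## Order: "#" (final terminator, global minimum) < "$" (document separator)
## < A < C < G < N < T.  Integer codes are 1-based for direct R indexing.
ALPHABET <- c("#", "$", "A", "C", "G", "N", "T")
N_SYMBOLS <- length(ALPHABET)

.code_lookup <- local({
  x <- rep(NA_integer_, 256)
  x[utf8ToInt("#") + 1L] <- 1L
  x[utf8ToInt("$") + 1L] <- 2L
  x[utf8ToInt("A") + 1L] <- 3L
  x[utf8ToInt("C") + 1L] <- 4L
  x[utf8ToInt("G") + 1L] <- 5L
  x[utf8ToInt("N") + 1L] <- 6L
  x[utf8ToInt("T") + 1L] <- 7L
  x[utf8ToInt("a") + 1L] <- 3L
  x[utf8ToInt("c") + 1L] <- 4L
  x[utf8ToInt("g") + 1L] <- 5L
  x[utf8ToInt("n") + 1L] <- 6L
  x[utf8ToInt("t") + 1L] <- 7L
  x
})

#' Encode a DNA/text string as integer symbol codes
#'
#' Maps characters of the index alphabet (`#`, `$`, `A`, `C`, `G`, `N`, `T`,
#' case-insensitive for bases) to integer codes whose order is the
#' lexicographic order used throughout the index. Characters outside the
#' alphabet map to `NA`, which never matches anything.
#'
#' @param s A single character string.
#' @return Integer vector of codes, one per character.
#' @export
dna_encode <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  .code_lookup[utf8ToInt(s) + 1L]
}

#' Decode integer symbol codes back to a string
#' @param codes Integer vector of symbol codes (1..7).
#' @return A single character string.
#' @export
dna_decode <- function(codes) {
  paste(ALPHABET[codes], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' `N` stays `N`; characters outside `ACGTN` are left unchanged (they will
#' never match the index anyway).
#'
#' @param s A single character string.
#' @return The reverse complement string.
#' @export
revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}
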