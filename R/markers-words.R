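## 64-bit marker words.
##
## A marker records (chromosome, reference offset, allele id) packed into a
## 64-bit word: 12 bits chromosome | 48 bits offset | 4 bits allele, with the
## allele in the lowest bits so that unsigned word order sorts by
## (chromosome, offset).  R has no native 64-bit integer, so the word is
## carried as a fixed-width hexadecimal string "0x" + 16 hex digits; string
## comparison of the fixed-width digits equals unsigned comparison of the
## word, and encode/decode are exact for the full field widths.

MAX_CHROM <- 2^12
MAX_OFFSET <- 2^48
MAX_ALLELE <- 2^4

#' Pack (chromosome, reference offset, allele) into a 64-bit marker word
#'
#' Field widths are 12 bits for the chromosome index (order of appearance in
#' the VCF header, 0-based), 48 bits for the 0-based offset within the
#' chromosome, and 4 bits for the allele id (0 = reference allele, 1..15 =
#' alternate allele index). The word is returned as a `"0x"`-prefixed
#' 16-hex-digit string; comparing these strings lexicographically is
#' equivalent to comparing the words as unsigned 64-bit integers.
#'
#' @param chrom_id Integer vector, `0 <= chrom_id < 2^12`.
#' @param ref_offset Numeric vector of 0-based offsets, `< 2^48`.
#' @param allele_id Integer vector, `0 <= allele_id < 16`.
#' @return Character vector of marker words.
#' @examples
#' encode_marker(0, 0, 0)
#' decode_marker(encode_marker(1, 12345, 2))
#' @export
encode_marker <- function(chrom_id, ref_offset, allele_id) {
  chrom_id <- as.numeric(chrom_id)
  ref_offset <- as.numeric(ref_offset)
  allele_id <- as.numeric(allele_id)
  if (any(chrom_id < 0 | chrom_id >= MAX_CHROM) ||
      any(ref_offset < 0 | ref_offset >= MAX_OFFSET) ||
      any(allele_id < 0 | allele_id >= MAX_ALLELE)) {
    stop("marker field overflow: need chrom_id < 2^12, ref_offset < 2^48, allele_id < 16")
  }
  ## 48-bit offset split into two 24-bit halves so sprintf("%x") stays within
  ## 32-bit integer range.
  off_hi <- ref_offset %/% 2^24
  off_lo <- ref_offset %% 2^24
  sprintf("0x%03x%06x%06x%01x", as.integer(chrom_id), as.integer(off_hi),
          as.integer(off_lo), as.integer(allele_id))
}

#' Unpack a 64-bit marker word
#'
#' @param word Character vector of marker words as produced by
#'   [encode_marker()] (with or without the `"0x"` prefix).
#' @return A tibble with columns `chrom_id`, `ref_offset`, `allele_id`.
#' @export
decode_marker <- function(word) {
  hex <- sub("^0x", "", word)
  stopifnot(all(nchar(hex) == 16L))
  chrom_id <- strtoi(substr(hex, 1L, 3L), base = 16L)
  off_hi <- strtoi(substr(hex, 4L, 9L), base = 16L)
  off_lo <- strtoi(substr(hex, 10L, 15L), base = 16L)
  allele_id <- strtoi(substr(hex, 16L, 16L), base = 16L)
  tibble::tibble(
    chrom_id = chrom_id,
    ref_offset = off_hi * 2^24 + off_lo,
    allele_id = allele_id
  )
}
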