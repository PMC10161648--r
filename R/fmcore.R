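## Suffix array, BWT and FM-index over the concatenated text, with backward
## search, LF and FL primitives.  The full suffix array is retained as the
## locate oracle at this scale (no run-sampled SA).

.as_codes <- function(text) {
  if (inherits(text, "concat_text")) return(text$codes)
  if (is.character(text) && length(text) == 1L) {
    codes <- dna_encode(text)
    if (anyNA(codes)) stop("text contains characters outside the index alphabet")
    return(codes)
  }
  if (is.numeric(text)) return(as.integer(text))
  stop("text must be a concat_text, a string, or integer codes")
}

#' Build the suffix array of a text
#'
#' Prefix-doubling construction over base R's radix sort: ranks of suffixes by
#' their first \eqn{2^k} characters are refined until all distinct. The text
#' must end with a unique, lexicographically smallest symbol so suffix order
#' is total. Output is the exact lexicographic suffix order (checked against a
#' naive sort oracle in the test suite).
#'
#' @param text A `concat_text`, a character string over the index alphabet, or
#'   an integer code vector.
#' @return Integer vector `sa` of 0-based suffix start offsets,
#'   `suffix(sa[i]) < suffix(sa[i+1])`.
#' @examples
#' build_suffix_array("ACAC$")  # 4 2 0 3 1
#' @export
build_suffix_array <- function(text) {
  v <- .as_codes(text)
  n <- length(v)
  stopifnot(n >= 1L)
  rank <- v
  k <- 1L
  if (n == 1L) return(0L)
  repeat {
    rank2 <- c(rank[-seq_len(min(k, n))], rep.int(0L, min(k, n)))
    o <- order(rank, rank2, method = "radix")
    r1 <- rank[o]; r2 <- rank2[o]
    changed <- c(TRUE, r1[-1L] != r1[-n] | r2[-1L] != r2[-n])
    newr <- cumsum(changed)
    rank <- integer(n)
    rank[o] <- newr
    if (newr[n] == n) return(o - 1L)
    k <- k * 2L
  }
}

#' Build the FM-index bundle over a text
#'
#' Computes the BWT `L` (`L[i] = T[sa[i]-1]`, wrapping at 0), the C-counts
#' (for each symbol, the number of text characters strictly smaller), rank
#' support (per-symbol cumulative counts over `L`), select support (per-symbol
#' occurrence positions, for FL steps), the number of same-character BWT runs
#' `r`, and retains the full suffix array as the locate oracle.
#'
#' @param text As in [build_suffix_array()].
#' @param sa Suffix array from [build_suffix_array()]; built if `NULL`.
#' @param n_docs Number of documents in the text (taken from a `concat_text`
#'   automatically; defaults to the number of separator symbols).
#' @return An object of class `fm_index`.
#' @export
build_fm_index <- function(text, sa = NULL, n_docs = NULL) {
  codes <- .as_codes(text)
  n <- length(codes)
  if (is.null(sa)) sa <- build_suffix_array(codes)
  stopifnot(length(sa) == n)
  if (is.null(n_docs)) {
    n_docs <- if (inherits(text, "concat_text")) text$n_docs
              else sum(codes <= 2L)
  }
  prev <- ifelse(sa == 0L, n, sa)          # 1-based index of T[sa[i]-1]
  bwt <- codes[prev]
  counts <- tabulate(codes, nbins = N_SYMBOLS)
  C <- c(0L, cumsum(counts))[seq_len(N_SYMBOLS)]   # C[s] = #chars < s
  ## rank: OCC[i + 1, s] = occurrences of s in bwt[1..i] (i 0-based prefix len)
  OCC <- matrix(0L, nrow = n + 1L, ncol = N_SYMBOLS)
  for (s in seq_len(N_SYMBOLS)) {
    if (counts[s] > 0L) OCC[-1L, s] <- cumsum(bwt == s)
  }
  sel <- lapply(seq_len(N_SYMBOLS), function(s) which(bwt == s))  # 1-based
  run_starts <- which(c(TRUE, bwt[-1L] != bwt[-n]))               # 1-based
  structure(list(
    codes = codes, n = n, sa = sa, bwt = bwt,
    counts = counts, C = C, OCC = OCC, sel = sel,
    run_starts = run_starts, r = length(run_starts),
    n_docs = n_docs
  ), class = "fm_index")
}

#' @export
print.fm_index <- function(x, ...) {
  cat(sprintf("<fm_index> |T| = %d, r = %d BWT runs, %d document(s)\n",
              x$n, x$r, x$n_docs))
  invisible(x)
}

#' Suffix-array range
#'
#' Inclusive 0-based bounds into suffix-array order; `lo > hi` denotes the
#' empty range.
#'
#' @param lo,hi Inclusive bounds.
#' @return An integer vector `c(lo, hi)` of class `sa_range`.
#' @export
sa_range <- function(lo, hi) {
  structure(c(lo = as.integer(lo), hi = as.integer(hi)), class = "sa_range")
}

#' All-inclusive suffix-array range of an index
#' @param index An `fm_index`.
#' @return The range covering every suffix.
#' @export
full_range <- function(index) sa_range(0L, index$n - 1L)

#' Is a suffix-array range empty?
#' @param range An `sa_range`.
#' @return Logical.
#' @export
is_empty_range <- function(range) range[1] > range[2]

#' One backward-search step
#'
#' Given the SA range of suffixes prefixed by a pattern `Q`, returns the
#' maximal range of suffixes prefixed by `cQ`: `lo' = C[c] + rank_c(lo)`,
#' `hi' = C[c] + rank_c(hi + 1) - 1`. A symbol outside the alphabet (e.g. a
#' read `N`) yields the empty range rather than an error.
#'
#' @param index An `fm_index`.
#' @param range An `sa_range` (or `c(lo, hi)`).
#' @param c A single character, or its integer code.
#' @return An `sa_range`; empty when `cQ` does not occur.
#' @export
backward_step <- function(index, range, c) {
  code <- if (is.character(c)) .code_lookup[utf8ToInt(c) + 1L] else as.integer(c)
  if (is.na(code) || code < 1L || code > N_SYMBOLS || range[1] > range[2]) {
    return(sa_range(0L, -1L))
  }
  lo <- index$C[code] + index$OCC[range[1] + 1L, code]
  hi <- index$C[code] + index$OCC[range[2] + 2L, code] - 1L
  sa_range(lo, hi)
}

#' Count (and locate in SA order) the occurrences of a pattern
#'
#' Full backward search of `q`, right to left.
#'
#' @param index An `fm_index`.
#' @param q Pattern string (non-empty) over `{A,C,G,T,N}` (separators allowed).
#' @return A list with `occ` (exact occurrence count) and `range` (the final
#'   `sa_range`, empty if `occ == 0`).
#' @export
count_occurrences <- function(index, q) {
  codes <- dna_encode(q)
  stopifnot(length(codes) >= 1L)
  range <- full_range(index)
  for (i in rev(seq_along(codes))) {
    range <- backward_step(index, range, codes[i])
    if (range[1] > range[2]) break
  }
  occ <- if (range[1] > range[2]) 0L else unname(range[2] - range[1] + 1L)
  list(occ = occ, range = range)
}

#' One LF step
#'
#' Maps BWT row `i` to the row of the preceding text position:
#' `lf(i) = C[L[i]] + rank_{L[i]}(i)`, so `sa[lf(i)] = sa[i] - 1 (mod |T|)`.
#'
#' @param index An `fm_index`.
#' @param i Row index, 0-based.
#' @return The mapped row, 0-based.
#' @export
lf_step <- function(index, i) {
  stopifnot(i >= 0L, i < index$n)
  s <- index$bwt[i + 1L]
  index$C[s] + index$OCC[i + 1L, s]
}

#' One FL step (inverse of LF)
#'
#' Maps row `i'` to the row of the following text position using a select
#' query on the BWT: `fl(i') = select_{F[i']}(i' - C[F[i']])`.
#'
#' @param index An `fm_index`.
#' @param i Row index, 0-based.
#' @return The mapped row, 0-based; `fl_step(lf_step(i)) == i`.
#' @export
fl_step <- function(index, i) {
  stopifnot(i >= 0L, i < index$n)
  s <- findInterval(i, index$C)            # F[i']: symbol whose C-interval holds i'
  index$sel[[s]][i - index$C[s] + 1L] - 1L
}
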