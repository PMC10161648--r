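## Marker array MA (markers permuted into suffix-rank order) and augmented
## "smeared" marker array MA^w, plus the fully-sensitive FL marker-query
## oracle.

## Per-position document start, from doc_bounds (for smear clipping).
.doc_start_of <- function(text) {
  rep.int(text$doc_bounds$start, text$doc_bounds$end - text$doc_bounds$start)
}

## Shared builder: smear each marker w positions leftward (clipped at its
## document's start so a window never crosses a separator), group payloads by
## text position ordered by increasing marked offset, permute into SA order,
## and run-length encode.
.build_marker_multimap <- function(markers, sa, w, text) {
  n <- length(sa)
  keyvec <- character(n)
  paye <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(markers) > 0L) {
    doc_start <- .doc_start_of(text)
    reach <- pmin(w, markers$gpos - doc_start[markers$gpos + 1L])
    off <- sequence(reach + 1L, from = 0L)
    p <- rep.int(markers$gpos, reach + 1L) - off
    g <- rep.int(markers$gpos, reach + 1L)
    word <- rep.int(markers$word, reach + 1L)
    ord <- order(p, g, word, method = "radix")
    p <- p[ord]; word <- word[ord]
    pay <- split(word, p)
    keyvec[as.integer(names(pay)) + 1L] <-
      vapply(pay, paste, character(1), collapse = "\x1f")
    list2env(pay, envir = paye)
  }
  keys_sa <- keyvec[sa + 1L]
  sa_local <- sa
  payload_at <- function(i) paye[[as.character(sa_local[i])]]
  .sparse_from_keys(keys_sa, payload_at)
}

#' Build the marker array MA
#'
#' `MA[i] = M[sa[i]]`: the dense marker map permuted into suffix-rank order,
#' with runs of identical markers merged by the sparse encoder.
#'
#' @param markers Dense marker map: a tibble with columns `gpos` (0-based
#'   global text offset) and `word`, as from [extract_markers()].
#' @param sa Suffix array of the same text (0-based).
#' @param text The `concat_text` the markers were extracted over.
#' @return An object of class `marker_array` wrapping a `sparse_multimap`
#'   over SA order.
#' @export
build_marker_array <- function(markers, sa, text) {
  sm <- .build_marker_multimap(markers, sa, 0L, text)
  structure(list(sparse = sm, n = sm$n), class = "marker_array")
}

#' Build the augmented (smeared) marker array MA^w
#'
#' `MA^w[i]` lists the markers at text positions `sa[i] .. sa[i] + w`,
#' clipped at the document's separator, ordered by increasing text offset
#' (so the queried position's own marker, if any, comes first). Marks are
#' thereby extended ("smeared") `w` positions to the left, which lets a
#' backward search consult the array only every `w` steps.
#'
#' @param markers,sa,text As in [build_marker_array()].
#' @param w Window size in positions (`w >= 0`; `w = 0` degenerates to MA).
#' @return An object of class `aug_marker_array` with elements `sparse`
#'   (a `sparse_multimap`), `w` and `n`.
#' @export
build_augmented_marker_array <- function(markers, sa, w, text) {
  stopifnot(w >= 0L)
  sm <- .build_marker_multimap(markers, sa, as.integer(w), text)
  structure(list(sparse = sm, w = as.integer(w), n = sm$n),
            class = "aug_marker_array")
}

#' @export
print.marker_array <- function(x, ...) {
  cat(sprintf("<marker_array> %d ranks, %d run(s)\n", x$n, sum(x$sparse$S)))
  invisible(x)
}

#' @export
print.aug_marker_array <- function(x, ...) {
  cat(sprintf("<aug_marker_array> w = %d, %d ranks, %d run(s), %d payload(s)\n",
              x$w, x$n, sum(x$sparse$S), x$sparse$nx))
  invisible(x)
}

#' Access a marker array at one SA rank
#' @param ma A `marker_array` or `aug_marker_array`.
#' @param i 0-based SA rank.
#' @return Character vector of marker words (empty when unmarked).
#' @export
ma_access <- function(ma, i) sparse_access(ma$sparse, i)

#' Hash map from text offset to marker words
#'
#' Builds an environment keyed by global text offset (as character) holding
#' the marker word(s) at that offset — the random-access form of the dense
#' marker map used by [fl_marker_query()].
#'
#' @param markers Tibble with `gpos` and `word` columns.
#' @return An environment.
#' @export
marker_map <- function(markers) {
  paye <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(markers) > 0L) {
    m <- markers[order(markers$gpos, markers$word), ]
    list2env(split(m$word, m$gpos), envir = paye)
  }
  paye
}

#' Fully-sensitive FL marker query
#'
#' Returns every marker overlapped by every occurrence of `q` in the text:
#' backward search gives the SA range of `q`; from each row, a sequence of
#' `|q| - 1` FL steps walks rightward over the occurrence, and the dense
#' marker map is consulted at each visited text offset. Cost is
#' `O(|q| * occ)` FL steps — this is the exact oracle that the heuristic
#' scan's evidence must be contained in.
#'
#' @param index An `fm_index` (with its retained suffix array).
#' @param M Dense marker map: tibble with `gpos`/`word`, or a prebuilt
#'   [marker_map()] environment.
#' @param q Query string; if absent from the text the result is empty.
#' @return Tibble with columns `text_offset` and `word`, one row per distinct
#'   (offset, marker) pair.
#' @export
fl_marker_query <- function(index, M, q) {
  env <- if (is.environment(M)) M else marker_map(M)
  res <- count_occurrences(index, q)
  empty <- tibble::tibble(text_offset = integer(0), word = character(0))
  if (res$occ == 0L) return(empty)
  m <- nchar(q)
  offs <- integer(0); words <- character(0)
  for (x in res$range[1]:res$range[2]) {
    t0 <- index$sa[x + 1L]
    r <- x
    for (j in seq_len(m) - 1L) {
      if (j > 0L) r <- fl_step(index, r)
      hit <- get0(as.character(t0 + j), envir = env, ifnotfound = NULL)
      if (!is.null(hit)) {
        offs <- c(offs, rep.int(t0 + j, length(hit)))
        words <- c(words, hit)
      }
    }
  }
  dplyr::distinct(tibble::tibble(text_offset = offs, word = words))
}
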