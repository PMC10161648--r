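## Sparse S/E/X/B encoding of a mostly-empty array of payload lists.
##
## The non-empty elements of an array A fall into maximal runs of identical
## (and non-empty) elements.  S marks run starts, E marks run ends, X holds
## the payloads of each run (flattened, one slice per run), and B marks the
## first payload of each run within X.  A[i] is non-empty iff
## S.rank1(i+1) > E.rank1(i); its run index is E.rank1(i).

.new_sparse_multimap <- function(S, E, X, B) {
  stopifnot(length(S) == length(E), length(X) == length(B),
            sum(S) == sum(E), sum(S) == sum(B))
  structure(list(
    S = S, E = E, X = X, B = B,
    n = length(S), nx = length(X),
    Scum = c(0L, cumsum(S)),    # Scum[j + 1] = rank1(j) = ones strictly before j (0-based)
    Ecum = c(0L, cumsum(E)),
    Bpos = which(B)             # 1-based start of each run's payload slice in X
  ), class = "sparse_multimap")
}

#' @export
print.sparse_multimap <- function(x, ...) {
  cat(sprintf("<sparse_multimap> |A| = %d, %d run(s), %d payload(s)\n",
              x$n, sum(x$S), x$nx))
  invisible(x)
}

## Core constructor from a key vector (one key per array position; "" marks
## an empty element; equal adjacent keys merge into one run) and an accessor
## returning the payload vector at a 1-based position.
.sparse_from_keys <- function(keys, payload_at) {
  n <- length(keys)
  S <- logical(n); E <- logical(n)
  X <- character(0); B <- logical(0)
  if (n > 0L) {
    rl <- rle(keys)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    nonempty <- rl$values != ""
    S[starts[nonempty]] <- TRUE
    E[ends[nonempty]] <- TRUE
    if (any(nonempty)) {
      plist <- lapply(starts[nonempty], payload_at)
      lens <- lengths(plist)
      X <- as.character(unlist(plist))
      B <- logical(length(X))
      B[cumsum(lens) - lens + 1L] <- TRUE
    }
  }
  .new_sparse_multimap(S, E, X, B)
}

#' Sparse-encode an array of payload lists
#'
#' Encodes an array whose elements are empty (`NULL` or zero-length) or
#' character vectors of payloads into the S/E/X/B structure. Two adjacent
#' non-empty elements belong to the same run only when their payload lists
#' are equal element-wise.
#'
#' @param dense A list; empty elements are `NULL`/`character(0)`.
#' @return A `sparse_multimap`.
#' @examples
#' sm <- sparse_encode(list(NULL, "m1", "m1", NULL, "m2"))
#' sm$S  # FALSE TRUE FALSE FALSE TRUE
#' @export
sparse_encode <- function(dense) {
  keys <- vapply(dense, function(p) {
    if (is.null(p) || length(p) == 0L) "" else paste(p, collapse = "\x1f")
  }, character(1))
  .sparse_from_keys(keys, function(i) as.character(dense[[i]]))
}

#' Access one element of a sparse multimap
#'
#' Membership is decided by `S.rank1(i+1) > E.rank1(i)`; the payload slice of
#' the containing run is `X` delimited by `B`, starting at payload index
#' `E.rank1(i)`.
#'
#' @param sm A `sparse_multimap`.
#' @param i 0-based position, `0 <= i < |A|`.
#' @return Character vector of payloads (length 0 when the element is empty).
#' @export
sparse_access <- function(sm, i) {
  if (i < 0L || i >= sm$n) stop("sparse_access: index out of range")
  if (sm$Scum[i + 2L] <= sm$Ecum[i + 1L]) return(character(0))
  run <- sm$Ecum[i + 1L] + 1L             # 1-based run index
  from <- sm$Bpos[run]
  to <- if (run < length(sm$Bpos)) sm$Bpos[run + 1L] - 1L else sm$nx
  sm$X[from:to]
}

## Vectorized access over many 0-based positions: returns a list with
## parallel vectors `pos` and `word` (one row per payload found).
.sparse_access_many <- function(sm, pos) {
  ok <- sm$Scum[pos + 2L] > sm$Ecum[pos + 1L]
  pos <- pos[ok]
  if (!length(pos)) return(list(pos = integer(0), word = character(0)))
  run <- sm$Ecum[pos + 1L] + 1L
  from <- sm$Bpos[run]
  to <- ifelse(run < length(sm$Bpos), sm$Bpos[pmin(run + 1L, length(sm$Bpos))] - 1L, sm$nx)
  lens <- to - from + 1L
  idx <- sequence(lens, from = from)
  list(pos = rep.int(pos, lens), word = sm$X[idx])
}

#' Decode a sparse multimap back to its dense array
#' @param sm A `sparse_multimap`.
#' @return A list of length `|A|`; empty elements are `character(0)`.
#' @export
sparse_decode <- function(sm) {
  out <- rep(list(character(0)), sm$n)
  starts <- which(sm$S); ends <- which(sm$E)
  for (k in seq_along(starts)) {
    from <- sm$Bpos[k]
    to <- if (k < length(sm$Bpos)) sm$Bpos[k + 1L] - 1L else sm$nx
    payload <- sm$X[from:to]
    for (i in starts[k]:ends[k]) out[[i]] <- payload
  }
  out
}

## Dense key vector (paste of payloads, "" when empty) — cheap whole-array
## comparison form used by the definition oracles.
.sparse_keys <- function(sm) {
  keys <- character(sm$n)
  starts <- which(sm$S); ends <- which(sm$E)
  if (length(starts)) {
    froms <- sm$Bpos
    tos <- c(sm$Bpos[-1L] - 1L, sm$nx)
    runkeys <- vapply(seq_along(starts), function(k)
      paste(sm$X[froms[k]:tos[k]], collapse = "\x1f"), character(1))
    lens <- ends - starts + 1L
    keys[sequence(lens, from = starts)] <- rep.int(runkeys, lens)
  }
  keys
}

#' Serialized size of a sparse multimap, in bytes
#'
#' The size of the on-disk encoding: the `S` and `E` bitvectors packed 8
#' positions per byte, the `B` bitvector packed likewise over the payloads,
#' and 8 bytes per 64-bit payload word in `X`.
#'
#' @param sm A `sparse_multimap`.
#' @return Number of bytes.
#' @export
sparse_size_bytes <- function(sm) {
  2 * ceiling(sm$n / 8) + ceiling(sm$nx / 8) + 8 * sm$nx
}
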