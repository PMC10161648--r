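## Heuristic read scanning against the augmented marker array, evidence
## tallying, and haploid/diploid genotype calling.
##
## A read is scanned right to left with backward search.  When the range
## empties, it is reset to the all-inclusive range and matching restarts at
## the next character; a maximal run of successful steps is an "extension".
## The marker array is consulted on a fixed schedule: at matched lengths
## w+1, 2w+1, 3w+1, ... and once more when the extension ends with at least
## w+1 matched characters — offsets chosen so the w+1-position smear window
## always lies inside the matched substring — and only while the range size
## is at most N_h (the number of indexed documents), larger ranges being
## ambiguous multi-locus matches.  Evidence from an extension is discarded
## wholesale if two alleles conflict at one site, if its sites span more
## than one chromosome, or if the extension matched fewer than
## `min_seed_len` characters.

## One scanning pass over a set of same-strand read sequences.
## Reads are advanced in lockstep (one character per iteration per read) so
## the rank arithmetic stays vectorized.
.scan_pass <- function(index, seqs) {
  fm <- index$fm
  nr <- length(seqs)
  n <- fm$n
  w <- index$w
  Nh <- index$n_h
  sm <- index$maw$sparse
  OCC <- fm$OCC; C <- fm$C

  lens <- nchar(seqs)
  maxlen <- max(lens, 1L)
  seq_mat <- matrix(NA_integer_, nrow = nr, ncol = maxlen)
  for (i in seq_len(nr)) {
    if (lens[i] > 0L) seq_mat[i, seq_len(lens[i])] <- dna_encode(seqs[i])
  }

  p <- lens                       # next char (1-based from the left; consumed right to left)
  lo <- rep.int(0L, nr); hi <- rep.int(n - 1L, nr)
  m <- integer(nr); ext <- rep.int(1L, nr); lastq <- integer(nr)

  ev <- list(read = list(), ext = list(), word = list(),
             q_len = list(), right = list())
  ex <- list(read = list(), ext = list(), len = list(), right = list())
  nev <- 0L; nex <- 0L

  collect <- function(rs) {
    ## marker-array query for reads rs over their current ranges
    lens_r <- hi[rs] - lo[rs] + 1L
    rows <- sequence(lens_r, from = lo[rs])
    rd <- rep.int(rs, lens_r)
    res <- .sparse_access_many2(sm, rows)
    if (length(res$i)) {
      rr <- rd[res$i]
      nev <<- nev + 1L
      ev$read[[nev]] <<- rr
      ev$ext[[nev]] <<- ext[rr]
      ev$word[[nev]] <<- res$word
      ev$q_len[[nev]] <<- m[rr]
      ev$right[[nev]] <<- p[rr] + m[rr]
    }
  }
  close_ext <- function(rs) {
    live <- rs[m[rs] > 0L]
    if (!length(live)) return(invisible())
    term <- live[m[live] >= w + 1L & m[live] > lastq[live] &
                 (hi[live] - lo[live] + 1L) <= Nh]
    if (length(term)) collect(term)
    nex <<- nex + 1L
    ex$read[[nex]] <<- live
    ex$ext[[nex]] <<- ext[live]
    ex$len[[nex]] <<- m[live]
    ex$right[[nex]] <<- p[live] + m[live]
  }

  while (any(act <- p > 0L)) {
    idx <- which(act)
    pos <- p[idx]
    cc <- seq_mat[cbind(idx, pos)]
    valid <- !is.na(cc) & cc >= 3L & cc != 6L     # A/C/G/T; read N never matches
    cc2 <- ifelse(valid, cc, 3L)
    lo2 <- C[cc2] + OCC[cbind(lo[idx] + 1L, cc2)]
    hi2 <- C[cc2] + OCC[cbind(hi[idx] + 2L, cc2)] - 1L
    ok <- valid & lo2 <= hi2

    s <- idx[ok]
    if (length(s)) {
      lo[s] <- lo2[ok]; hi[s] <- hi2[ok]
      m[s] <- m[s] + 1L
      p[s] <- p[s] - 1L
      qs <- s[m[s] > w & (m[s] - 1L) %% w == 0L & (hi[s] - lo[s] + 1L) <= Nh]
      if (length(qs)) { collect(qs); lastq[qs] <- m[qs] }
      done <- s[p[s] == 0L]
      if (length(done)) close_ext(done)
    }

    f <- idx[!ok]
    if (length(f)) {
      close_ext(f)
      p[f] <- p[f] - 1L              # failing character is consumed unmatched
      lo[f] <- 0L; hi[f] <- n - 1L
      m[f] <- 0L; ext[f] <- ext[f] + 1L; lastq[f] <- 0L
    }
  }

  evidence <- tibble::tibble(
    read = unlist(ev$read) %||% integer(0),
    ext = unlist(ev$ext) %||% integer(0),
    word = unlist(ev$word) %||% character(0),
    q_len = unlist(ev$q_len) %||% integer(0),
    ext_right = unlist(ev$right) %||% integer(0)
  )
  exts <- tibble::tibble(
    read = unlist(ex$read) %||% integer(0),
    ext = unlist(ex$ext) %||% integer(0),
    len = unlist(ex$len) %||% integer(0),
    right = unlist(ex$right) %||% integer(0)
  )
  list(evidence = evidence, exts = exts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Like .sparse_access_many but also reports which queried position each
## payload came from (index into `pos`).
.sparse_access_many2 <- function(sm, pos) {
  ok <- sm$Scum[pos + 2L] > sm$Ecum[pos + 1L]
  ii <- which(ok)
  if (!length(ii)) return(list(i = integer(0), word = character(0)))
  run <- sm$Ecum[pos[ii] + 1L] + 1L
  from <- sm$Bpos[run]
  to <- ifelse(run < length(sm$Bpos), sm$Bpos[pmin(run + 1L, length(sm$Bpos))] - 1L, sm$nx)
  lens <- to - from + 1L
  list(i = rep.int(ii, lens), word = sm$X[sequence(lens, from = from)])
}

## Apply the extension-level discard rules to one pass's raw evidence.
.filter_evidence <- function(evidence, exts, min_seed_len) {
  if (nrow(evidence) == 0L) {
    return(tibble::tibble(read = integer(0), ext = integer(0),
                          word = character(0), q_len = integer(0),
                          ext_right = integer(0), ext_len = integer(0),
                          chrom_id = integer(0), ref_off = integer(0),
                          allele = integer(0)))
  }
  dec <- decode_marker(evidence$word)
  evidence$chrom_id <- dec$chrom_id
  evidence$ref_off <- as.integer(dec$ref_offset)
  evidence$allele <- dec$allele_id
  evidence <- dplyr::distinct(evidence, .data$read, .data$ext, .data$word,
                              .keep_all = TRUE)
  evidence <- dplyr::left_join(evidence,
                               dplyr::select(exts, "read", "ext", ext_len = "len"),
                               by = c("read", "ext"))
  bad <- evidence |>
    dplyr::group_by(.data$read, .data$ext) |>
    dplyr::summarise(
      conflict = dplyr::n_distinct(paste(.data$chrom_id, .data$ref_off, .data$allele)) >
                 dplyr::n_distinct(paste(.data$chrom_id, .data$ref_off)),
      multi_chrom = dplyr::n_distinct(.data$chrom_id) > 1L,
      .groups = "drop")
  evidence |>
    dplyr::left_join(bad, by = c("read", "ext")) |>
    dplyr::filter(.data$ext_len >= min_seed_len, !.data$conflict, !.data$multi_chrom) |>
    dplyr::select(-"conflict", -"multi_chrom")
}

#' Scan reads against a marker index and collect allele evidence
#'
#' Runs the heuristic backward-search scan over every read. For each read a
#' random initial strand is chosen (deterministically from `strand_seed` and
#' the read's ordinal); if no extension on that strand matches at least
#' `min_seed_len` characters, the opposite strand is scanned and its
#' surviving evidence is used instead. Evidence that fails any extension-level
#' rule (allele conflict at a site, sites on more than one chromosome,
#' extension shorter than `min_seed_len`) is discarded.
#'
#' @param reads Character vector of read sequences, or a data frame with a
#'   `seq` column (and optionally `read_id`).
#' @param index A `marker_index`.
#' @param min_seed_len Minimum matched length (bp) for an extension's
#'   evidence to count (default 80).
#' @param strand_seed Seed for the per-read initial-strand choice.
#' @return A tibble of surviving evidence: `read_id`, `strand` (strand the
#'   evidence came from), `ext`, `chrom_id`, `ref_off`, `allele`, `word`,
#'   `q_len` (matched length when the marker was collected), `ext_right`
#'   (rightmost read position of the extension on that strand), `ext_len`.
#' @export
genotype_reads <- function(reads, index, min_seed_len = 80L, strand_seed = 1L) {
  if (is.data.frame(reads)) {
    seqs <- toupper(reads$seq)
    ids <- if ("read_id" %in% names(reads)) reads$read_id else seq_along(seqs)
  } else {
    seqs <- toupper(as.character(reads))
    ids <- seq_along(seqs)
  }
  nr <- length(seqs)
  empty <- tibble::tibble(read_id = ids[0], strand = character(0),
                          ext = integer(0), chrom_id = integer(0),
                          ref_off = integer(0), allele = integer(0),
                          word = character(0), q_len = integer(0),
                          ext_right = integer(0), ext_len = integer(0))
  if (nr == 0L) return(empty)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed); on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  first <- withr_seed(strand_seed, sample(c("+", "-"), nr, replace = TRUE))

  pass1 <- .scan_pass(index, ifelse(first == "+", seqs, rc))
  ev1 <- .filter_evidence(pass1$evidence, pass1$exts, min_seed_len)
  qual1 <- unique(pass1$exts$read[pass1$exts$len >= min_seed_len])
  second <- setdiff(seq_len(nr), qual1)

  out <- list()
  if (nrow(ev1)) {
    keep1 <- ev1[ev1$read %in% qual1, ]
    keep1$strand <- first[keep1$read]
    out[[1]] <- keep1
  }
  if (length(second)) {
    opp <- ifelse(first[second] == "+", "-", "+")
    pass2 <- .scan_pass(index, ifelse(opp == "+", seqs[second], rc[second]))
    ev2 <- .filter_evidence(pass2$evidence, pass2$exts, min_seed_len)
    if (nrow(ev2)) {
      ev2$strand <- opp[ev2$read]
      ev2$read <- second[ev2$read]
      out[[length(out) + 1L]] <- ev2
    }
  }
  if (!length(out)) return(empty)
  res <- dplyr::bind_rows(out)
  res$read_id <- ids[res$read]
  res[order(res$read), c("read_id", "strand", "ext", "chrom_id", "ref_off",
                         "allele", "word", "q_len", "ext_right", "ext_len")]
}

#' Scan a single read
#'
#' Convenience wrapper around [genotype_reads()] for one read. A read shorter
#' than `min_seed_len` cannot qualify and yields an empty result.
#'
#' @inheritParams genotype_reads
#' @param read A single read sequence.
#' @return As [genotype_reads()].
#' @export
genotype_read <- function(read, index, min_seed_len = 80L, strand_seed = 1L) {
  genotype_reads(read, index, min_seed_len = min_seed_len,
                 strand_seed = strand_seed)
}

#' Tally per-site allele evidence over all reads
#'
#' Deduplicates to at most one observation per read per site (evidence from
#' several windows or extensions of one read is not independent), then counts
#' per site: `k` total allele observations, `l` reference-allele
#' observations, and the modal alternate allele.
#'
#' @param evidence Evidence tibble from [genotype_reads()].
#' @return Tibble with `chrom_id`, `ref_off`, `k`, `l`, `alt_allele` (modal
#'   non-reference allele id, `NA` when none observed), `alt_count`.
#' @export
tally_evidence <- function(evidence) {
  if (nrow(evidence) == 0L) {
    return(tibble::tibble(chrom_id = integer(0), ref_off = integer(0),
                          k = integer(0), l = integer(0),
                          alt_allele = integer(0), alt_count = integer(0)))
  }
  obs <- dplyr::distinct(evidence, .data$read_id, .data$chrom_id,
                         .data$ref_off, .keep_all = TRUE)
  obs |>
    dplyr::group_by(.data$chrom_id, .data$ref_off) |>
    dplyr::summarise(
      k = dplyr::n(),
      l = sum(.data$allele == 0L),
      alt_allele = {
        a <- .data$allele[.data$allele > 0L]
        if (length(a)) {
          tb <- sort(table(a), decreasing = TRUE)
          as.integer(names(tb)[1])
        } else NA_integer_
      },
      alt_count = {
        a <- .data$allele[.data$allele > 0L]
        if (length(a)) max(tabulate(a)) else 0L
      },
      .groups = "drop")
}

#' Diploid genotype likelihood
#'
#' For a site with `k` observed alleles of which `l` are the reference
#' allele, a global sequencing error rate `epsilon`, and `g` copies of the
#' reference allele in the diploid genotype,
#' \deqn{L(g) = (1/2)^k \, [(2-g)\epsilon + g(1-\epsilon)]^l \,
#'       [(2-g)(1-\epsilon) + g\epsilon]^{k-l}.}
#' This is the standard ploidy-2 genotype likelihood with a single global
#' error rate.
#'
#' @param g Copies of the reference allele, in `{0, 1, 2}`.
#' @param k Total allele observations at the site.
#' @param l Reference-allele observations, `0 <= l <= k`.
#' @param epsilon Error rate in `(0, 1)`.
#' @return The likelihood, in `[0, 1]`. Vectorized over all arguments.
#' @examples
#' genotype_likelihood(2, 10, 10, 0.01)  # 0.99^10
#' @export
genotype_likelihood <- function(g, k, l, epsilon = 0.01) {
  if (any(!(g %in% c(0, 1, 2)))) stop("g must be in {0, 1, 2}")
  if (any(l < 0 | l > k)) stop("need 0 <= l <= k")
  if (any(epsilon <= 0 | epsilon >= 1)) stop("need 0 < epsilon < 1")
  0.5^k * ((2 - g) * epsilon + g * (1 - epsilon))^l *
    ((2 - g) * (1 - epsilon) + g * epsilon)^(k - l)
}

#' Call diploid genotypes from site tallies
#'
#' Per site, computes `L(0)`, `L(1)`, `L(2)` and calls
#' `g = argmax L(g)`, breaking ties toward more reference copies (larger
#' `g`). Sites present in `sites` but absent from the tallies (no evidence,
#' `k = 0`) are called homozygous reference, consistent with the tie rule.
#'
#' @param tallies Tibble from [tally_evidence()].
#' @param epsilon Global error rate (default 0.01).
#' @param sites Optional site table (tibble with `chrom_id` and `mark_off`
#'   or `ref_off`) used to complete the call set.
#' @return Tibble of class `markergt_calls`: `chrom_id`, `ref_off`, `k`,
#'   `l`, `g`, `L0`, `L1`, `L2`, `alt_allele`.
#' @export
call_diploid <- function(tallies, epsilon = 0.01, sites = NULL) {
  t2 <- .complete_sites(tallies, sites)
  L0 <- genotype_likelihood(0, t2$k, t2$l, epsilon)
  L1 <- genotype_likelihood(1, t2$k, t2$l, epsilon)
  L2 <- genotype_likelihood(2, t2$k, t2$l, epsilon)
  g <- ifelse(L2 >= L1 & L2 >= L0, 2L, ifelse(L1 >= L0, 1L, 0L))
  out <- tibble::tibble(chrom_id = t2$chrom_id, ref_off = t2$ref_off,
                        k = t2$k, l = t2$l, g = g,
                        L0 = L0, L1 = L1, L2 = L2,
                        alt_allele = t2$alt_allele)
  class(out) <- c("markergt_calls", class(out))
  attr(out, "ploidy") <- 2L
  attr(out, "epsilon") <- epsilon
  out
}

#' Call haploid genotypes by majority vote
#'
#' Calls the most frequently observed allele at each site; when the
#' reference and alternate alleles have equal evidence (including no
#' evidence at all), the reference allele is called.
#'
#' @inheritParams call_diploid
#' @return Tibble of class `markergt_calls`: `chrom_id`, `ref_off`, `k`,
#'   `l`, `allele` (0 = reference).
#' @export
call_haploid <- function(tallies, sites = NULL) {
  t2 <- .complete_sites(tallies, sites)
  allele <- ifelse(t2$alt_count > t2$l & !is.na(t2$alt_allele),
                   t2$alt_allele, 0L)
  out <- tibble::tibble(chrom_id = t2$chrom_id, ref_off = t2$ref_off,
                        k = t2$k, l = t2$l, allele = as.integer(allele))
  class(out) <- c("markergt_calls", class(out))
  attr(out, "ploidy") <- 1L
  out
}

.complete_sites <- function(tallies, sites) {
  if (is.null(sites)) {
    t2 <- tallies
  } else {
    key <- tibble::tibble(
      chrom_id = sites$chrom_id,
      ref_off = if ("mark_off" %in% names(sites)) sites$mark_off else sites$ref_off)
    t2 <- dplyr::left_join(key, tallies, by = c("chrom_id", "ref_off"))
    t2$k[is.na(t2$k)] <- 0L
    t2$l[is.na(t2$l)] <- 0L
  }
  if (!"alt_count" %in% names(t2)) t2$alt_count <- t2$k - t2$l
  t2$alt_count[is.na(t2$alt_count)] <- 0L
  t2[order(t2$chrom_id, t2$ref_off), ]
}
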