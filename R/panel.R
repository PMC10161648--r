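## Haplotype panel: reference FASTA + phased VCF -> materialized documents,
## provenance, and the dense marker map over the concatenated text.

#' Parse a phased haplotype panel from VCF + FASTA
#'
#' Reads a reference FASTA and a phased VCF (haploid GT or phased diploid
#' `a|b` GT) and returns a haplotype panel: the reference sequences (document
#' \eqn{T_0}), the variant records, and the per-haplotype allele assignments
#' for the alternative documents \eqn{T_1..T_n}.
#'
#' Records are checked against the reference: a REF allele that does not match
#' the FASTA, a record overlapping an earlier kept record, a record with more
#' than 15 alternate alleles (the 4-bit allele field), or a length-changing
#' allele without a shared left-anchor base is skipped and tallied (see the
#' `skipped` element of the result). Variants whose minor-allele frequency
#' among the panelists (the \eqn{n} haplotypes; \eqn{T_0} is excluded from the
#' denominator) is not strictly greater than `min_af` are filtered out.
#'
#' @param vcf_source Path to a VCF 4.x file (optionally gzip-compressed).
#' @param fasta_source Path to the reference FASTA (every VCF chromosome must
#'   be present; chromosome order is taken from the FASTA).
#' @param min_af Minimum minor-allele frequency in `[0, 1]`; variants with
#'   MAF `> min_af` are kept.
#' @return An object of class `haplotype_panel`: a list with `chrom_names`,
#'   `ref_seqs`, `variants` (tibble: `chrom_id` 0-based, `ref_pos` 0-based,
#'   `ref`, `alts` list-column), `gt` (integer matrix, variants x haplotypes),
#'   `n_haplotypes`, `hap_names`, `min_af` and `skipped` (named tally).
#' @export
parse_panel <- function(vcf_source, fasta_source, min_af = 0) {
  fasta <- Biostrings::readDNAStringSet(fasta_source)
  ref_seqs <- toupper(as.character(fasta))
  chrom_names <- names(ref_seqs)
  chrom_names <- sub("\\s.*$", "", chrom_names)
  names(ref_seqs) <- chrom_names

  vcf <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fix <- vcf@fix
  nrec <- nrow(fix)

  skipped <- c(ref_mismatch = 0L, overlap = 0L, too_many_alts = 0L,
               unanchored = 0L, low_af = 0L)

  if (nrec == 0L) {
    return(.new_panel(chrom_names, ref_seqs,
                      variants = .empty_variants(), gt = matrix(0L, 0L, 0L),
                      hap_names = character(0), min_af = min_af, skipped = skipped))
  }

  chrom <- unname(fix[, "CHROM"])
  if (!all(chrom %in% chrom_names)) {
    stop("VCF chromosome(s) missing from FASTA: ",
         paste(unique(setdiff(chrom, chrom_names)), collapse = ", "))
  }
  pos <- unname(as.integer(fix[, "POS"]))
  ref <- unname(toupper(fix[, "REF"]))
  alt <- unname(toupper(fix[, "ALT"]))

  gt_str <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_str))) gt_str <- matrix(gt_str, nrow = nrec)
  if (any(is.na(gt_str)) || any(grepl("[/.]", gt_str))) {
    stop("panel VCF must have phased (\"|\") or haploid GT with no missing calls")
  }
  ## expand samples into haplotype columns
  sample_names <- colnames(gt_str)
  if (is.null(sample_names)) sample_names <- paste0("S", seq_len(ncol(gt_str)))
  hap_cols <- list(); hap_names <- character(0)
  for (j in seq_len(ncol(gt_str))) {
    pieces <- strsplit(gt_str[, j], "|", fixed = TRUE)
    plen <- lengths(pieces)
    if (length(unique(plen)) != 1L) {
      stop("inconsistent ploidy within sample ", sample_names[j])
    }
    mat <- matrix(as.integer(unlist(pieces)), nrow = nrec, byrow = TRUE)
    for (h in seq_len(plen[1])) {
      hap_cols[[length(hap_cols) + 1L]] <- mat[, h]
      hap_names <- c(hap_names, if (plen[1] == 1L) sample_names[j]
                     else paste0(sample_names[j], "_", h))
    }
  }
  gt <- do.call(cbind, hap_cols)
  n_hap <- ncol(gt)

  chrom_id <- match(chrom, chrom_names) - 1L
  ord <- order(chrom_id, pos)
  chrom_id <- chrom_id[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
  gt <- gt[ord, , drop = FALSE]

  alts <- strsplit(alt, ",", fixed = TRUE)
  keep <- logical(length(pos))
  last_end <- integer(length(chrom_names))  # 1-based exclusive end of last kept record
  for (i in seq_along(pos)) {
    ci <- chrom_id[i] + 1L
    lr <- nchar(ref[i])
    fasta_ref <- substr(ref_seqs[[ci]], pos[i], pos[i] + lr - 1L)
    if (!isTRUE(fasta_ref == ref[i])) {
      skipped["ref_mismatch"] <- skipped["ref_mismatch"] + 1L
      next
    }
    if (length(alts[[i]]) > 15L) {
      skipped["too_many_alts"] <- skipped["too_many_alts"] + 1L
      next
    }
    if (pos[i] < last_end[ci]) {
      skipped["overlap"] <- skipped["overlap"] + 1L
      next
    }
    la <- nchar(alts[[i]])
    anchored <- la == lr | substr(alts[[i]], 1L, 1L) == substr(ref[i], 1L, 1L)
    if (!all(anchored)) {
      skipped["unanchored"] <- skipped["unanchored"] + 1L
      next
    }
    if (any(gt[i, ] > length(alts[[i]]))) {
      stop("GT allele index exceeds ALT count at ", chrom[i], ":", pos[i])
    }
    ## minor-allele frequency among the n_hap panelists (T_0 excluded)
    freqs <- tabulate(gt[i, ] + 1L, nbins = length(alts[[i]]) + 1L) / n_hap
    maf <- sort(freqs, decreasing = TRUE)[2]
    if (!(maf > min_af)) {
      skipped["low_af"] <- skipped["low_af"] + 1L
      next
    }
    keep[i] <- TRUE
    last_end[ci] <- pos[i] + lr
  }

  n_skip <- sum(skipped[c("ref_mismatch", "overlap", "too_many_alts", "unanchored")])
  if (n_skip > 0L) {
    warning(sprintf("skipped %d VCF record(s): %s", n_skip,
                    paste(names(skipped), skipped, sep = "=", collapse = ", ")))
  }

  variants <- tibble::tibble(
    chrom_id = chrom_id[keep],
    ref_pos = pos[keep] - 1L,       # 0-based
    ref = ref[keep],
    alts = alts[keep]
  )
  .new_panel(chrom_names, ref_seqs, variants, gt[keep, , drop = FALSE],
             hap_names, min_af, skipped)
}

#' Construct a haplotype panel in code
#'
#' Builds a `haplotype_panel` directly from sequences and variant records,
#' bypassing file parsing and the allele-frequency filter. Useful for small
#' fixtures and for simulator output.
#'
#' @param ref_seqs Named character vector of reference chromosome sequences.
#' @param variants Tibble with `chrom_id` (0-based), `ref_pos` (0-based),
#'   `ref`, and either `alts` (list-column) or `alt` (character, biallelic).
#' @param gt Integer matrix (variants x haplotypes) of allele indices.
#' @param hap_names Optional haplotype names.
#' @return A `haplotype_panel`.
#' @export
haplotype_panel <- function(ref_seqs, variants, gt, hap_names = NULL) {
  if (!"alts" %in% names(variants) && "alt" %in% names(variants)) {
    variants$alts <- as.list(variants$alt)
    variants$alt <- NULL
  }
  if (is.null(dim(gt))) gt <- matrix(as.integer(gt), nrow = nrow(variants))
  stopifnot(nrow(gt) == nrow(variants))
  if (is.null(hap_names)) hap_names <- paste0("H", seq_len(ncol(gt)))
  variants <- variants[order(variants$chrom_id, variants$ref_pos), , drop = FALSE]
  .new_panel(names(ref_seqs), toupper(ref_seqs),
             tibble::as_tibble(variants[, c("chrom_id", "ref_pos", "ref", "alts")]),
             gt, hap_names, min_af = 0,
             skipped = c(ref_mismatch = 0L, overlap = 0L, too_many_alts = 0L,
                         unanchored = 0L, low_af = 0L))
}

.empty_variants <- function() {
  tibble::tibble(chrom_id = integer(0), ref_pos = integer(0),
                 ref = character(0), alts = list())
}

.new_panel <- function(chrom_names, ref_seqs, variants, gt, hap_names, min_af, skipped) {
  structure(list(
    chrom_names = chrom_names,
    ref_seqs = ref_seqs,
    variants = variants,
    gt = gt,
    n_haplotypes = ncol(gt),
    hap_names = hap_names,
    min_af = min_af,
    skipped = skipped
  ), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d chromosome(s), %d haplotype(s), %d variant(s), min_af > %g\n",
              length(x$chrom_names), x$n_haplotypes, nrow(x$variants), x$min_af))
  invisible(x)
}

#' Restrict a panel to a subset of haplotypes
#'
#' Keeps the given haplotype columns and re-applies the panel's minor-allele
#' frequency filter over the subset, dropping variants that are no longer
#' polymorphic (MAF not above `min_af`) among the remaining panelists. Used to
#' hold donor haplotypes out of an index build.
#'
#' @param panel A `haplotype_panel`.
#' @param haps Integer indices (1-based) of haplotypes to keep.
#' @param min_af MAF threshold; defaults to the panel's own.
#' @return A `haplotype_panel` over the retained haplotypes.
#' @export
subset_panel <- function(panel, haps, min_af = panel$min_af) {
  stopifnot(inherits(panel, "haplotype_panel"),
            all(haps >= 1L & haps <= panel$n_haplotypes))
  gt <- panel$gt[, haps, drop = FALSE]
  n_hap <- ncol(gt)
  keep <- vapply(seq_len(nrow(gt)), function(i) {
    freqs <- tabulate(gt[i, ] + 1L, nbins = length(panel$variants$alts[[i]]) + 1L) / n_hap
    sort(freqs, decreasing = TRUE)[2] > min_af
  }, logical(1))
  if (nrow(gt) == 0L) keep <- logical(0)
  .new_panel(panel$chrom_names, panel$ref_seqs,
             panel$variants[keep, , drop = FALSE], gt[keep, , drop = FALSE],
             panel$hap_names[haps], min_af, panel$skipped)
}

## Longest common prefix length of two strings.
.common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- substring(a, 1:n, 1:n); bv <- substring(b, 1:n, 1:n)
  d <- which(av != bv)
  if (length(d)) d[1] - 1L else n
}

## Apply selected alleles to one reference chromosome.  Returns the edited
## sequence and, per edited position, the reference column it projects to:
## same-length substitutions project base-by-base; bases at or beyond an
## indel's divergence point project to the left-flank (anchor) column.
.apply_haplotype <- function(ref_seq, pos0, ref_allele, alt_seq, cp) {
  n <- nchar(ref_seq)
  k <- length(pos0)
  segs <- vector("list", 2L * k + 1L)
  provs <- vector("list", 2L * k + 1L)
  cur <- 0L; j <- 1L
  for (v in seq_len(k)) {
    p <- pos0[v]; lr <- nchar(ref_allele[v]); la <- nchar(alt_seq[v])
    if (p > cur) {
      segs[[j]] <- substr(ref_seq, cur + 1L, p)
      provs[[j]] <- seq.int(cur, p - 1L)
      j <- j + 1L
    }
    segs[[j]] <- alt_seq[v]
    provs[[j]] <- if (la == lr) seq.int(p, p + la - 1L)
                  else p + pmin(seq_len(la) - 1L, cp[v] - 1L)
    j <- j + 1L
    cur <- p + lr
  }
  if (cur < n) {
    segs[[j]] <- substr(ref_seq, cur + 1L, n)
    provs[[j]] <- seq.int(cur, n - 1L)
    j <- j + 1L
  }
  seqs <- unlist(segs[seq_len(j - 1L)])
  list(seq = paste(seqs, collapse = ""), prov = as.integer(unlist(provs[seq_len(j - 1L)])))
}

#' Materialize the concatenated pangenome text
#'
#' Builds the documents \eqn{T_0, T_1, ..., T_n}: \eqn{T_0} is the unedited
#' reference (all chromosomes concatenated in FASTA order) and each \eqn{T_i}
#' applies exactly the alleles selected by haplotype \eqn{i}'s genotypes.
#' Every document is terminated by the separator `$` except the last, which is
#' terminated by `#`, the global lexicographic minimum. Provenance maps every
#' non-separator position to `(document, chromosome, projected reference
#' offset)`; positions inside insertions project to the marked left-flank
#' column.
#'
#' @param panel A `haplotype_panel`.
#' @return An object of class `concat_text` with elements `codes` (integer
#'   symbol codes), `n`, `n_docs`, `doc_bounds` (tibble `doc`, `start`, `end`,
#'   0-based half-open, separator included), `doc_id` (per position),
#'   `prov_chrom`, `prov_off` (NA at separators), and `chrom_names`.
#' @export
materialize_text <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  v <- panel$variants
  n_hap <- panel$n_haplotypes
  n_docs <- n_hap + 1L
  ## precompute per-variant common prefix length per alt
  cps <- lapply(seq_len(nrow(v)), function(i)
    vapply(v$alts[[i]], function(a) .common_prefix(v$ref[i], a), integer(1)))

  codes_l <- vector("list", n_docs)
  doc_id_l <- vector("list", n_docs)
  chrom_l <- vector("list", n_docs)
  off_l <- vector("list", n_docs)
  starts <- integer(n_docs); ends <- integer(n_docs)
  cursor <- 0L
  for (d in seq_len(n_docs) - 1L) {     # doc index 0..n_hap
    seq_parts <- character(0); off_parts <- list(); chrom_parts <- list()
    for (ci in seq_along(panel$chrom_names)) {
      ref_seq <- panel$ref_seqs[[ci]]
      sel <- if (d == 0L || nrow(v) == 0L) integer(0)
             else which(v$chrom_id == ci - 1L & panel$gt[, d] > 0L)
      if (length(sel)) {
        alt_seq <- vapply(sel, function(i) v$alts[[i]][panel$gt[i, d]], character(1))
        cp <- vapply(sel, function(i) cps[[i]][panel$gt[i, d]], integer(1))
        res <- .apply_haplotype(ref_seq, v$ref_pos[sel], v$ref[sel], alt_seq, cp)
      } else {
        res <- list(seq = ref_seq, prov = seq.int(0L, nchar(ref_seq) - 1L))
      }
      if (nchar(res$seq) == 0L) stop("allele application produced an empty document")
      seq_parts <- c(seq_parts, res$seq)
      off_parts[[ci]] <- res$prov
      chrom_parts[[ci]] <- rep.int(ci - 1L, length(res$prov))
    }
    sep <- if (d == n_hap) "#" else "$"
    doc_str <- paste0(paste(seq_parts, collapse = ""), sep)
    codes <- dna_encode(doc_str)
    if (anyNA(codes)) stop("document contains characters outside {A,C,G,T,N}")
    len <- length(codes)
    codes_l[[d + 1L]] <- codes
    doc_id_l[[d + 1L]] <- rep.int(d, len)
    chrom_l[[d + 1L]] <- c(unlist(chrom_parts), NA_integer_)
    off_l[[d + 1L]] <- c(unlist(off_parts), NA_integer_)
    starts[d + 1L] <- cursor
    ends[d + 1L] <- cursor + len
    cursor <- cursor + len
  }
  structure(list(
    codes = unlist(codes_l),
    n = cursor,
    n_docs = n_docs,
    doc_bounds = tibble::tibble(doc = seq_len(n_docs) - 1L, start = starts, end = ends),
    doc_id = unlist(doc_id_l),
    prov_chrom = unlist(chrom_l),
    prov_off = unlist(off_l),
    chrom_names = panel$chrom_names
  ), class = "concat_text")
}

#' @export
print.concat_text <- function(x, ...) {
  cat(sprintf("<concat_text> %d positions, %d document(s), %d chromosome(s)\n",
              x$n, x$n_docs, length(x$chrom_names)))
  invisible(x)
}

## Per-variant marked reference offset and per-alt edit classification.
.variant_meta <- function(variants) {
  n <- nrow(variants)
  mark_off <- integer(n)
  kinds <- vector("list", n)
  for (i in seq_len(n)) {
    ref <- variants$ref[i]; lr <- nchar(ref); p <- variants$ref_pos[i]
    alts <- variants$alts[[i]]
    cand <- integer(length(alts)); kk <- character(length(alts))
    for (a in seq_along(alts)) {
      la <- nchar(alts[a])
      if (la == lr) {
        d <- .common_prefix(ref, alts[a])       # first substituted base
        cand[a] <- p + d
        kk[a] <- "sub"
      } else {
        cp <- .common_prefix(ref, alts[a])      # anchored: cp >= 1
        cand[a] <- p + cp - 1L                  # base immediately left of the indel
        kk[a] <- if (la > lr) "ins" else "del"
      }
    }
    mark_off[i] <- min(cand)
    kinds[[i]] <- kk
  }
  list(mark_off = mark_off, kinds = kinds)
}

#' Extract the dense marker map and edit table
#'
#' For every surviving variant and every document (including the all-reference
#' \eqn{T_0}), marks exactly one text position: the first substituted base for
#' a substitution (or run of consecutive substitutions, collapsed into a
#' single edit), or the base immediately left of the indel for an insertion or
#' deletion. Reference copies carry allele id 0; a document carrying alternate
#' allele \eqn{a} carries allele id \eqn{a}. Markers are 64-bit words per
#' [encode_marker()].
#'
#' @param panel A `haplotype_panel`.
#' @param text The `concat_text` produced from `panel` by [materialize_text()].
#' @return A list with `markers` (tibble: `gpos` 0-based global text offset,
#'   `word`, `chrom_id`, `ref_off`, `allele`, `doc`), `edit_table` (tibble:
#'   `edit_id` > 0, one per (variant, alternate allele); id 0 is the reserved
#'   null operation and is never stored), `sites` (tibble of distinct marked
#'   loci with `chrom_id`, `mark_off`, `ref_pos`, `ref`, `alt`, `class`), and
#'   `total_sites`.
#' @export
extract_markers <- function(panel, text) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(text, "concat_text"))
  v <- panel$variants
  n_var <- nrow(v)
  n_docs <- text$n_docs
  if (n_var == 0L) {
    return(list(
      markers = tibble::tibble(gpos = integer(0), word = character(0),
                               chrom_id = integer(0), ref_off = integer(0),
                               allele = integer(0), doc = integer(0)),
      edit_table = tibble::tibble(edit_id = integer(0), chrom_id = integer(0),
                                  ref_pos = integer(0), alt_index = integer(0),
                                  kind = character(0), alt_seq = character(0),
                                  ref_span = integer(0)),
      sites = tibble::tibble(chrom_id = integer(0), mark_off = integer(0),
                             ref_pos = integer(0), ref = character(0),
                             alt = character(0), class = character(0)),
      total_sites = 0L
    ))
  }
  meta <- .variant_meta(v)

  ## edit table: one dense id per (variant, alternate allele)
  n_alts <- lengths(v$alts)
  edit_table <- tibble::tibble(
    edit_id = seq_len(sum(n_alts)),
    chrom_id = rep(v$chrom_id, n_alts),
    ref_pos = rep(v$ref_pos, n_alts),
    alt_index = unlist(lapply(n_alts, seq_len)),
    kind = unlist(meta$kinds),
    alt_seq = unlist(v$alts),
    ref_span = rep(nchar(v$ref), n_alts)
  )

  ## locate each variant's marked base in every document via provenance
  out <- vector("list", n_docs)
  for (d in seq_len(n_docs) - 1L) {
    idx <- which(text$doc_id == d & !is.na(text$prov_off))
    doc_chrom <- text$prov_chrom[idx]
    doc_off <- text$prov_off[idx]
    mult <- max(c(doc_off, meta$mark_off), 0L) + 1
    key_doc <- doc_chrom * mult + doc_off
    key_var <- v$chrom_id * mult + meta$mark_off
    loc <- match(key_var, key_doc)           # first position projecting there
    if (anyNA(loc)) stop("marked base missing from document ", d)
    allele <- if (d == 0L) rep.int(0L, n_var) else panel$gt[, d]
    out[[d + 1L]] <- tibble::tibble(
      gpos = idx[loc] - 1L,
      chrom_id = v$chrom_id,
      ref_off = meta$mark_off,
      allele = as.integer(allele),
      doc = d
    )
  }
  markers <- dplyr::bind_rows(out)
  markers$word <- encode_marker(markers$chrom_id, markers$ref_off, markers$allele)
  markers <- markers[order(markers$gpos, markers$word),
                     c("gpos", "word", "chrom_id", "ref_off", "allele", "doc")]

  sites <- tibble::tibble(
    chrom_id = v$chrom_id,
    mark_off = meta$mark_off,
    ref_pos = v$ref_pos,
    ref = v$ref,
    alt = vapply(v$alts, paste, character(1), collapse = ","),
    class = classify_variants(v$ref, v$alts)
  )
  list(markers = markers, edit_table = edit_table, sites = sites,
       total_sites = nrow(sites))
}

#' Classify variants as SNV, Indel (<= 50 bp) or SV (> 50 bp)
#'
#' A variant whose reference and alternate alleles have equal length is an
#' `SNV` (multi-base substitution runs included); a length difference of at
#' most 50 bp is an `Indel`; anything longer is an `SV`.
#'
#' @param ref Character vector of reference alleles.
#' @param alts List of character vectors of alternate alleles (or a character
#'   vector for biallelic sites).
#' @return Character vector of classes.
#' @export
classify_variants <- function(ref, alts) {
  if (!is.list(alts)) alts <- as.list(alts)
  vapply(seq_along(ref), function(i) {
    d <- max(abs(nchar(alts[[i]]) - nchar(ref[i])))
    if (d == 0) "SNV" else if (d <= 50) "Indel" else "SV"
  }, character(1))
}
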