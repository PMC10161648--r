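## Top-level index build over a panel, and directory (de)serialization.

#' Build a marker-array genotyping index
#'
#' Runs the full build: materialize the concatenated text from the panel,
#' construct the suffix array and FM-index, extract the dense marker map and
#' edit table, and build the augmented marker array \eqn{MA^w}. The number of
#' haplotypes \eqn{N_h} used by the scan's ambiguity filter counts all
#' documents, including the all-reference \eqn{T_0}.
#'
#' @param panel A `haplotype_panel` (from [parse_panel()] or built in code),
#'   or a list with `vcf` and `fasta` paths.
#' @param w Smearing window size (positions); the scan consults the marker
#'   array once every `w` backward-search steps.
#' @param min_af Minor-allele frequency threshold used when `panel` is given
#'   as file paths.
#' @param keep_dense Keep the dense marker map and provenance in the object
#'   (needed by the oracle queries; cheap at desk scale).
#' @return An object of class `marker_index`.
#' @export
build_marker_index <- function(panel, w = 19L, min_af = 0, keep_dense = TRUE) {
  if (!inherits(panel, "haplotype_panel")) {
    panel <- parse_panel(panel$vcf, panel$fasta, min_af = min_af)
  }
  text <- materialize_text(panel)
  sa <- build_suffix_array(text)
  fm <- build_fm_index(text, sa)
  mx <- extract_markers(panel, text)
  maw <- build_augmented_marker_array(mx$markers, sa, w, text)
  structure(list(
    fm = fm,
    maw = maw,
    w = as.integer(w),
    min_af = min_af,
    n_h = text$n_docs,
    sites = mx$sites,
    edit_table = mx$edit_table,
    chrom_names = text$chrom_names,
    doc_bounds = text$doc_bounds,
    markers = if (keep_dense) mx$markers else NULL,
    text = if (keep_dense) text else NULL
  ), class = "marker_index")
}

#' @export
print.marker_index <- function(x, ...) {
  cat(sprintf(
    "<marker_index> |T| = %d, %d document(s), w = %d, %d marked site(s), min_af > %g\n",
    x$fm$n, x$n_h, x$w, nrow(x$sites), x$min_af))
  invisible(x)
}

.pack_bits <- function(b) packBits(c(b, rep(FALSE, (-length(b)) %% 8)), type = "raw")
.unpack_bits <- function(r, n) as.logical(rawToBits(r))[seq_len(n)]

.word_to_raw <- function(words) {
  hex <- sub("^0x", "", words)
  bytes <- vapply(seq_len(8), function(k)
    as.raw(strtoi(substr(hex, 2L * k - 1L, 2L * k), base = 16L)), raw(length(hex)))
  if (length(hex) == 1L) as.raw(bytes) else as.raw(t(bytes))
}

.raw_to_word <- function(r) {
  stopifnot(length(r) %% 8 == 0)
  m <- matrix(as.integer(r), ncol = 8, byrow = TRUE)
  apply(m, 1, function(b) paste0("0x", paste(sprintf("%02x", b), collapse = "")))
}

#' Serialize a marker index to a directory
#'
#' Writes versioned binary artifacts (BWT and text as one byte per symbol
#' code, suffix array as little-endian int32, marker-array bitvectors packed
#' 8 per byte, payload words as 8-byte big-endian) plus a JSON manifest with
#' the alphabet, lengths, `w`, `min_af` and document bounds, and TSV tables
#' for sites, edits and the dense marker map. Round-trips bit-exactly through
#' [read_marker_index()].
#'
#' @param index A `marker_index`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_marker_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fm <- index$fm
  manifest <- list(
    format_version = 1L,
    alphabet = ALPHABET,
    n = fm$n,
    n_docs = index$n_h,
    w = index$w,
    min_af = index$min_af,
    n_payloads = index$maw$sparse$nx,
    chrom_names = index$chrom_names,
    doc_start = index$doc_bounds$start,
    doc_end = index$doc_bounds$end
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeBin(as.raw(fm$codes), file.path(dir, "text.bin"))
  writeBin(as.raw(fm$bwt), file.path(dir, "bwt.bin"))
  writeBin(fm$sa, file.path(dir, "sa.bin"), size = 4L, endian = "little")
  sm <- index$maw$sparse
  writeBin(.pack_bits(sm$S), file.path(dir, "ma_S.bin"))
  writeBin(.pack_bits(sm$E), file.path(dir, "ma_E.bin"))
  writeBin(.pack_bits(sm$B), file.path(dir, "ma_B.bin"))
  writeBin(.word_to_raw(sm$X), file.path(dir, "ma_X.bin"))
  utils::write.table(index$sites, file.path(dir, "sites.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(index$edit_table, file.path(dir, "edits.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(index$markers)) {
    utils::write.table(index$markers[, c("gpos", "word")],
                       file.path(dir, "markers.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a marker index from a directory written by [write_marker_index()]
#'
#' @param dir Index directory.
#' @return A `marker_index` supporting all queries (FM-index structures are
#'   rebuilt from the stored text/SA; the sparse marker array is restored
#'   bit-exactly).
#' @export
read_marker_index <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  n <- manifest$n
  codes <- as.integer(readBin(file.path(dir, "text.bin"), "raw", n = n))
  sa <- readBin(file.path(dir, "sa.bin"), "integer", n = n, size = 4L,
                endian = "little")
  fm <- build_fm_index(codes, sa, n_docs = manifest$n_docs)
  stopifnot(identical(as.integer(readBin(file.path(dir, "bwt.bin"), "raw", n = n)),
                      fm$bwt))
  nx <- manifest$n_payloads
  S <- .unpack_bits(readBin(file.path(dir, "ma_S.bin"), "raw", n = ceiling(n / 8)), n)
  E <- .unpack_bits(readBin(file.path(dir, "ma_E.bin"), "raw", n = ceiling(n / 8)), n)
  B <- .unpack_bits(readBin(file.path(dir, "ma_B.bin"), "raw", n = ceiling(nx / 8)), nx)
  X <- if (nx > 0) .raw_to_word(readBin(file.path(dir, "ma_X.bin"), "raw", n = 8 * nx))
       else character(0)
  sm <- .new_sparse_multimap(S, E, X, B)
  maw <- structure(list(sparse = sm, w = as.integer(manifest$w), n = sm$n),
                   class = "aug_marker_array")
  sites <- tibble::as_tibble(utils::read.table(
    file.path(dir, "sites.tsv"), header = TRUE, sep = "\t",
    colClasses = c("integer", "integer", "integer", "character", "character", "character")))
  edit_table <- tibble::as_tibble(utils::read.table(
    file.path(dir, "edits.tsv"), header = TRUE, sep = "\t",
    colClasses = c("integer", "integer", "integer", "integer", "character",
                   "character", "integer")))
  markers <- NULL
  if (file.exists(file.path(dir, "markers.tsv"))) {
    markers <- tibble::as_tibble(utils::read.table(
      file.path(dir, "markers.tsv"), header = TRUE, sep = "\t",
      colClasses = c("integer", "character")))
    markers <- dplyr::bind_cols(
      markers,
      decode_marker(markers$word)[, c("chrom_id", "ref_offset", "allele_id")] |>
        stats::setNames(c("chrom_id", "ref_off", "allele"))
    )
  }
  structure(list(
    fm = fm,
    maw = maw,
    w = as.integer(manifest$w),
    min_af = manifest$min_af,
    n_h = manifest$n_docs,
    sites = sites,
    edit_table = edit_table,
    chrom_names = manifest$chrom_names,
    doc_bounds = tibble::tibble(doc = seq_along(manifest$doc_start) - 1L,
                                start = manifest$doc_start,
                                end = manifest$doc_end),
    markers = markers,
    text = NULL
  ), class = "marker_index")
}
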