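## Precision/recall evaluation of genotype calls against a truth set, and
## VCF output / input for call sets.

#' Evaluate genotype calls against a truth set
#'
#' Three evaluation levels are supported. `"haploid"`: the positive class is
#' sites truly carrying an alternate allele; a call matching the true
#' alternate is a TP, an alternate call at a truly-reference site is an FP,
#' a missed true alternate is an FN. `"alt_allele"`: every diploid genotype
#' is scored as a pair of allele calls — an ALT call is a TP if the true
#' genotype contains at least one ALT (else FP); a REF call is a TN if the
#' truth contains at least one REF (else FN). `"het_site"`: heterozygous
#' calls versus truly heterozygous sites. Results are stratified by variant
#' class (`SNV`; `Indel`, length difference of at most 50 bp; `SV`, longer;
#' and `All`).
#'
#' @param calls A `markergt_calls` tibble (haploid calls need `allele`,
#'   diploid calls need `g`).
#' @param truth Tibble keyed by `chrom_id` + `ref_off` (or `mark_off`), with
#'   `truth_allele` (haploid) or `truth_g` (reference-copy count, diploid),
#'   and a `class` column (or `ref`/`alt` columns to derive it). Must cover
#'   every called site.
#' @param level One of `"haploid"`, `"alt_allele"`, `"het_site"`.
#' @param strata Variant classes to report (default all four).
#' @return Tibble of class `markergt_eval`: `stratum`, `level`, `tp`, `fp`,
#'   `fn`, `tn`, `precision`, `recall`, `f1`.
#' @export
evaluate_calls <- function(calls, truth,
                           level = c("haploid", "alt_allele", "het_site"),
                           strata = c("All", "SNV", "Indel", "SV")) {
  level <- match.arg(level)
  truth <- tibble::as_tibble(truth)
  if (!"ref_off" %in% names(truth) && "mark_off" %in% names(truth)) {
    truth$ref_off <- truth$mark_off
  }
  if (!"class" %in% names(truth)) {
    if (all(c("ref", "alt") %in% names(truth))) {
      truth$class <- classify_variants(truth$ref, strsplit(truth$alt, ",", fixed = TRUE))
    } else {
      truth$class <- "SNV"
    }
  }
  tcols <- intersect(c("truth_allele", "truth_g", "class"), names(truth))
  j <- dplyr::left_join(tibble::as_tibble(calls),
                        truth[, c("chrom_id", "ref_off", tcols)],
                        by = c("chrom_id", "ref_off"))
  if (anyNA(j$class)) stop("call site(s) missing from the truth set")

  count_level <- function(d) {
    if (level == "haploid") {
      stopifnot(all(c("allele", "truth_allele") %in% names(d)))
      tp <- sum(d$allele != 0L & d$truth_allele != 0L & d$allele == d$truth_allele)
      fp <- sum(d$allele != 0L & d$truth_allele == 0L)
      fn <- sum(d$truth_allele != 0L & d$allele != d$truth_allele)
      tn <- sum(d$allele == 0L & d$truth_allele == 0L)
    } else if (level == "alt_allele") {
      stopifnot(all(c("g", "truth_g") %in% names(d)))
      tp <- sum((2L - d$g) * (d$truth_g <= 1L))
      fp <- sum((2L - d$g) * (d$truth_g == 2L))
      tn <- sum(d$g * (d$truth_g >= 1L))
      fn <- sum(d$g * (d$truth_g == 0L))
    } else {
      stopifnot(all(c("g", "truth_g") %in% names(d)))
      tp <- sum(d$g == 1L & d$truth_g == 1L)
      fp <- sum(d$g == 1L & d$truth_g != 1L)
      fn <- sum(d$truth_g == 1L & d$g != 1L)
      tn <- sum(d$g != 1L & d$truth_g != 1L)
    }
    c(tp = tp, fp = fp, fn = fn, tn = tn)
  }

  rows <- lapply(strata, function(s) {
    d <- if (s == "All") j else j[j$class == s, ]
    cn <- count_level(d)
    prec <- if (cn["tp"] + cn["fp"] > 0) cn["tp"] / (cn["tp"] + cn["fp"]) else NA_real_
    rec <- if (cn["tp"] + cn["fn"] > 0) cn["tp"] / (cn["tp"] + cn["fn"]) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    tibble::tibble(stratum = s, level = level,
                   tp = unname(cn["tp"]), fp = unname(cn["fp"]),
                   fn = unname(cn["fn"]), tn = unname(cn["tn"]),
                   precision = unname(prec), recall = unname(rec),
                   f1 = unname(f1))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("markergt_eval", class(out))
  out
}

#' Write diploid genotype calls as VCF 4.2
#'
#' One record per called site with `GT` (diploid, `0/0`, `0/a`, `a/a` for
#' `g` = 2, 1, 0 where `a` is the called alternate index) and `GL`
#' (log10-scaled likelihoods in genotype order `0/0, 0/1, 1/1`). Positions
#' are 1-based.
#'
#' @param calls A diploid `markergt_calls` tibble.
#' @param index A `marker_index` (provides site REF/ALT and chromosome
#'   names), or any list with `sites` and `chrom_names`.
#' @param path Output file.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, index, path, sample_name = "DONOR") {
  sites <- index$sites
  j <- dplyr::inner_join(tibble::as_tibble(calls),
                         sites[, c("chrom_id", "mark_off", "ref_pos", "ref", "alt")],
                         by = c("chrom_id", "ref_off" = "mark_off"))
  j <- j[order(j$chrom_id, j$ref_pos), ]
  diploid <- "g" %in% names(j)
  if (diploid) {
    a <- ifelse(is.na(j$alt_allele), 1L, j$alt_allele)
    gt <- ifelse(j$g == 2L, "0/0",
          ifelse(j$g == 1L, paste0("0/", a), paste0(a, "/", a)))
    gl <- sprintf("%.4f,%.4f,%.4f",
                  pmax(log10(pmax(j$L2, 1e-300)), -999),
                  pmax(log10(pmax(j$L1, 1e-300)), -999),
                  pmax(log10(pmax(j$L0, 1e-300)), -999))
    fmt <- "GT:GL"
    sample_field <- paste(gt, gl, sep = ":")
  } else {
    fmt <- "GT"
    sample_field <- as.character(j$allele)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=markergt",
    paste0("##contig=<ID=", index$chrom_names, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (diploid)
      '##FORMAT=<ID=GL,Number=G,Type=Float,Description="Log10 genotype likelihoods (0/0,0/1,1/1)">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  body <- paste(index$chrom_names[j$chrom_id + 1L], j$ref_pos + 1L, ".",
                j$ref, j$alt, ".", "PASS", ".", fmt,
                sample_field, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype-call VCF written by [write_calls_vcf()]
#'
#' @param path VCF file.
#' @param chrom_names Optional chromosome order for `chrom_id` assignment;
#'   defaults to order of appearance.
#' @return Tibble with `chrom`, `chrom_id`, `pos` (1-based), `ref`, `alt`,
#'   `gt`, `g` (reference-copy count) and `alt_allele`.
#' @export
read_calls_vcf <- function(path, chrom_names = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(tibble::tibble(chrom = character(0), chrom_id = integer(0),
                          pos = integer(0), ref = character(0),
                          alt = character(0), gt = character(0),
                          g = integer(0), alt_allele = integer(0)))
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  gt <- vapply(strsplit(f[, 10], ":", fixed = TRUE), `[`, character(1), 1L)
  al <- strsplit(gt, "[/|]")
  g <- vapply(al, function(x) sum(x == "0"), integer(1))
  alt_allele <- vapply(al, function(x) {
    a <- suppressWarnings(as.integer(x[x != "0"]))
    if (length(a)) a[1] else NA_integer_
  }, integer(1))
  chrom <- f[, 1]
  if (is.null(chrom_names)) chrom_names <- unique(chrom)
  tibble::tibble(chrom = chrom,
                 chrom_id = match(chrom, chrom_names) - 1L,
                 pos = as.integer(f[, 2]),
                 ref = f[, 4], alt = f[, 5], gt = gt,
                 g = g, alt_allele = alt_allele)
}
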