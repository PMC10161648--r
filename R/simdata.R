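## Synthetic panels, diploid donors and error-bearing reads with full truth.
## The generator emulates a phased multi-haplotype panel (SNVs + short
## indels at configurable allele frequencies), a possibly held-out diploid
## donor, and fixed-length reads with known placements.

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 150 bp reads at 25-fold coverage, SNVs at 0.01 per bp and indels
#' at 0.001 per bp with geometric lengths (mean `indel_mean`, capped at
#' `indel_max`), per-variant carrier fractions drawn from a (clamped)
#' Beta(0.8, 0.8) so every variant is polymorphic in the panel, and a
#' substitution error rate equal to the genotyper's default epsilon.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Chromosome length (bp).
#' @param n_haplotypes Panel haplotypes (excluding the reference document).
#' @param snv_rate,indel_rate Events per bp.
#' @param indel_mean Mean of the geometric indel-length distribution.
#' @param indel_max Maximum indel length (set above 50 to produce the SV
#'   class).
#' @param af_sampler Function of `n` returning per-variant carrier fractions
#'   in `[0, 1]`.
#' @param read_len Read length (bp; default 150).
#' @param coverage Fold coverage (default 25).
#' @param error_rate Per-base substitution error rate.
#' @param seed RNG seed; a fixed seed reproduces byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 1L, chrom_len = 10000L, n_haplotypes = 10L,
                       snv_rate = 0.01, indel_rate = 0.001,
                       indel_mean = 3, indel_max = 60L,
                       af_sampler = function(n) stats::rbeta(n, 0.8, 0.8),
                       read_len = 150L, coverage = 25, error_rate = 0.01,
                       seed = 1L) {
  stopifnot(snv_rate >= 0, snv_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            error_rate >= 0, error_rate <= 1, n_haplotypes >= 1)
  structure(list(n_chroms = n_chroms, chrom_len = chrom_len,
                 n_haplotypes = n_haplotypes, snv_rate = snv_rate,
                 indel_rate = indel_rate, indel_mean = indel_mean,
                 indel_max = indel_max, af_sampler = af_sampler,
                 read_len = read_len, coverage = coverage,
                 error_rate = error_rate, seed = seed),
            class = "sim_config")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Truncated geometric length >= 1 with approximate mean `mean`.
.rindel_len <- function(n, mean, max_len) {
  p <- 1 / mean
  pmin(stats::rgeom(n, p) + 1L, max_len)
}

#' Simulate a phased haplotype panel
#'
#' Draws a uniform-random reference, places non-overlapping SNVs and indels
#' (anchored VCF style), assigns carriers per variant from the configured
#' allele-frequency sampler (clamped so each variant has at least one
#' carrier and one non-carrier), and optionally writes `ref.fa` and a
#' phased, sorted `panel.vcf`. Haplotypes are paired into phased diploid
#' VCF samples (the last sample is haploid when `n_haplotypes` is odd).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory for `ref.fa` / `panel.vcf`.
#' @return A list of class `sim_panel`: `config`, `ref_seqs`, `variants`
#'   (tibble with `chrom_id`, `ref_pos` 0-based, `ref`, `alt`, `kind`),
#'   `gt` (variants x haplotypes allele matrix — the truth set), and file
#'   paths when written.
#' @export
simulate_panel <- function(config, dir = NULL) {
  set.seed(config$seed)
  nH <- config$n_haplotypes
  ref_seqs <- stats::setNames(
    vapply(seq_len(config$n_chroms), function(i) .random_dna(config$chrom_len),
           character(1)),
    paste0("chr", seq_len(config$n_chroms)))

  vs <- list()
  for (ci in seq_len(config$n_chroms)) {
    L <- config$chrom_len
    n_snv <- stats::rpois(1, config$snv_rate * L)
    n_ind <- stats::rpois(1, config$indel_rate * L)
    ## candidate anchors; position 0 avoided so indels always have an anchor
    pos_snv <- sample.int(L - 1L, min(n_snv, L - 1L)) # 1..L-1, 0-based
    pos_ind <- sample.int(L - 1L, min(n_ind, L - 1L))
    kind <- c(rep("snv", length(pos_snv)),
              sample(c("ins", "del"), length(pos_ind), replace = TRUE))
    pos <- c(pos_snv, pos_ind)
    o <- order(pos)
    pos <- pos[o]; kind <- kind[o]
    ilen <- .rindel_len(length(pos), config$indel_mean, config$indel_max)
    ref_a <- character(length(pos)); alt_a <- character(length(pos))
    for (i in seq_along(pos)) {
      base <- substr(ref_seqs[[ci]], pos[i] + 1L, pos[i] + 1L)
      if (kind[i] == "snv") {
        ref_a[i] <- base
        alt_a[i] <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
      } else if (kind[i] == "ins") {
        ref_a[i] <- base
        alt_a[i] <- paste0(base, .random_dna(ilen[i]))
      } else {
        span <- min(ilen[i], L - 1L - pos[i])
        if (span < 1L) { kind[i] <- "drop"; next }
        ref_a[i] <- substr(ref_seqs[[ci]], pos[i] + 1L, pos[i] + 1L + span)
        alt_a[i] <- base
      }
    }
    keep <- kind != "drop"
    pos <- pos[keep]; kind <- kind[keep]; ref_a <- ref_a[keep]; alt_a <- alt_a[keep]
    ## thin overlapping records (keep the earlier)
    end <- pos + nchar(ref_a)
    ok <- logical(length(pos)); last_end <- -1L
    for (i in seq_along(pos)) {
      if (pos[i] >= last_end) { ok[i] <- TRUE; last_end <- end[i] }
    }
    if (any(!ok)) {
      warning(sprintf("thinned %d overlapping simulated variant(s) on chr%d",
                      sum(!ok), ci))
    }
    vs[[ci]] <- tibble::tibble(chrom_id = ci - 1L, ref_pos = pos[ok],
                               ref = ref_a[ok], alt = alt_a[ok],
                               kind = kind[ok])
  }
  variants <- dplyr::bind_rows(vs)
  nv <- nrow(variants)

  gt <- matrix(0L, nrow = nv, ncol = nH)
  if (nv > 0L) {
    af <- config$af_sampler(nv)
    ncar <- pmin(pmax(round(af * nH), 1L), nH - 1L)
    for (i in seq_len(nv)) {
      gt[i, sample.int(nH, ncar[i])] <- 1L
    }
  }

  out <- structure(list(config = config, ref_seqs = ref_seqs,
                        variants = variants, gt = gt,
                        fasta = NULL, vcf = NULL),
                   class = "sim_panel")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$fasta <- file.path(dir, "ref.fa")
    out$vcf <- file.path(dir, "panel.vcf")
    write_sim_panel(out, out$fasta, out$vcf)
  }
  out
}

#' Write a simulated panel's FASTA and phased VCF
#' @param sim A `sim_panel`.
#' @param fasta,vcf Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_sim_panel <- function(sim, fasta, vcf) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$ref_seqs), fasta)
  v <- sim$variants
  nH <- ncol(sim$gt)
  n_samp <- ceiling(nH / 2)
  sample_names <- paste0("HAP", sprintf("%02d", seq_len(n_samp)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=markergt-simulate",
    paste0("##contig=<ID=", names(sim$ref_seqs), ",length=",
           nchar(sim$ref_seqs), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  if (nrow(v) > 0L) {
    gt_str <- vapply(seq_len(n_samp), function(s) {
      h1 <- 2L * s - 1L; h2 <- 2L * s
      if (h2 <= nH) paste(sim$gt[, h1], sim$gt[, h2], sep = "|")
      else as.character(sim$gt[, h1])
    }, character(nrow(v)))
    if (nrow(v) == 1L) gt_str <- matrix(gt_str, nrow = 1L)
    body <- paste(names(sim$ref_seqs)[v$chrom_id + 1L], v$ref_pos + 1L, ".",
                  v$ref, v$alt, ".", "PASS", ".", "GT",
                  apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  } else body <- character(0)
  writeLines(c(header, body), vcf)
  invisible(list(fasta = fasta, vcf = vcf))
}

#' Build one haplotype's full sequence from a simulated panel
#' @param sim A `sim_panel`.
#' @param hap Haplotype index (1-based), or 0 for the reference.
#' @return Named character vector, one sequence per chromosome.
#' @export
haplotype_seqs <- function(sim, hap) {
  v <- sim$variants
  vapply(seq_along(sim$ref_seqs), function(ci) {
    sel <- if (hap == 0L) integer(0)
           else which(v$chrom_id == ci - 1L & sim$gt[, hap] > 0L)
    if (!length(sel)) return(sim$ref_seqs[[ci]])
    cp <- vapply(sel, function(i) .common_prefix(v$ref[i], v$alt[i]), integer(1))
    .apply_haplotype(sim$ref_seqs[[ci]], v$ref_pos[sel], v$ref[sel],
                     v$alt[sel], cp)$seq
  }, character(1)) |> stats::setNames(names(sim$ref_seqs))
}

#' Convert a simulated panel to a `haplotype_panel`
#'
#' Optionally restricts to a subset of haplotypes (e.g. excluding a held-out
#' donor) and drops variants that are monomorphic — carried by none or all —
#' among the retained haplotypes, mirroring an `AF > 0` build.
#'
#' @param sim A `sim_panel`.
#' @param haps Haplotype indices to keep (default all).
#' @return A `haplotype_panel`.
#' @export
as_haplotype_panel <- function(sim, haps = NULL) {
  if (is.null(haps)) haps <- seq_len(ncol(sim$gt))
  gt <- sim$gt[, haps, drop = FALSE]
  nc <- rowSums(gt > 0L)
  keep <- nc > 0L & nc < ncol(gt)
  if (nrow(sim$variants) == 0L) keep <- logical(0)
  haplotype_panel(sim$ref_seqs,
                  sim$variants[keep, c("chrom_id", "ref_pos", "ref", "alt")],
                  gt[keep, , drop = FALSE],
                  hap_names = paste0("H", haps))
}

#' Pick a diploid donor from the panel
#'
#' The donor is a pair of panel haplotypes. With `leave_out = TRUE` the pair
#' is meant to be excluded from the index build (use [subset_panel()] /
#' `exclude` on the kept haplotypes). The per-site truth genotype is the
#' donor's number of reference-allele copies.
#'
#' @param sim A `sim_panel`.
#' @param haps Optional pair of haplotype indices; drawn at random otherwise.
#' @param seed Seed for the random draw.
#' @return A list of class `sim_donor`: `haps`, `seqs` (list of two
#'   per-chromosome sequence vectors), and `truth` (tibble with `chrom_id`,
#'   `ref_pos`, `ref`, `alt`, `class`, `allele_h1`, `allele_h2`, `truth_g`).
#' @export
simulate_diploid_donor <- function(sim, haps = NULL, seed = 1L) {
  nH <- ncol(sim$gt)
  stopifnot(nH >= 2L)
  if (is.null(haps)) {
    set.seed(seed)
    haps <- sample.int(nH, 2L)
  }
  stopifnot(length(haps) == 2L)
  a1 <- if (nrow(sim$variants)) sim$gt[, haps[1]] else integer(0)
  a2 <- if (nrow(sim$variants)) sim$gt[, haps[2]] else integer(0)
  truth <- tibble::tibble(
    chrom_id = sim$variants$chrom_id,
    ref_pos = sim$variants$ref_pos,
    ref = sim$variants$ref,
    alt = sim$variants$alt,
    class = classify_variants(sim$variants$ref, sim$variants$alt),
    allele_h1 = a1, allele_h2 = a2,
    truth_g = (a1 == 0L) + (a2 == 0L))
  structure(list(haps = haps,
                 seqs = list(haplotype_seqs(sim, haps[1]),
                             haplotype_seqs(sim, haps[2])),
                 truth = truth),
            class = "sim_donor")
}

#' Simulate error-bearing reads from donor sequences
#'
#' Uniform start positions over all donor haplotypes/chromosomes and both
#' strands; independent per-base substitution errors; constant quality
#' (`I`). The read count is `round(coverage * total_length / read_len)`.
#'
#' @param donor A `sim_donor`, or a list of per-chromosome sequence vectors.
#' @param read_len Read length (bp).
#' @param coverage Fold coverage.
#' @param error_rate Per-base substitution error rate.
#' @param seed RNG seed.
#' @param fastq Optional FASTQ output path.
#' @return A tibble with `read_id`, `seq`, and truth placement columns
#'   `hap`, `chrom`, `start` (0-based on the donor haplotype sequence) and
#'   `strand`.
#' @export
simulate_reads <- function(donor, read_len = 150L, coverage = 25,
                           error_rate = 0.01, seed = 1L, fastq = NULL) {
  seqs <- if (inherits(donor, "sim_donor")) donor$seqs else donor
  set.seed(seed)
  src <- tibble::tibble(
    hap = rep(seq_along(seqs), lengths(seqs)),
    chrom = unlist(lapply(seqs, seq_along)),
    seq = unlist(seqs, use.names = FALSE))
  src$len <- nchar(src$seq)
  if (any(src$len < read_len)) stop("read_len exceeds a donor sequence length")
  total <- sum(src$len)
  n_reads <- round(coverage * total / read_len)
  pick <- sample.int(nrow(src), n_reads, replace = TRUE, prob = src$len)
  start <- vapply(pick, function(i) sample.int(src$len[i] - read_len + 1L, 1L),
                  integer(1)) - 1L
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  raw <- substring(src$seq[pick], start + 1L, start + read_len)
  ## substitution errors
  nerr <- stats::rbinom(n_reads, read_len, error_rate)
  has <- which(nerr > 0L)
  if (length(has)) {
    chars <- strsplit(raw[has], "", fixed = TRUE)
    for (j in seq_along(has)) {
      at <- sample.int(read_len, nerr[has[j]])
      chars[[j]][at] <- vapply(chars[[j]][at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    raw[has] <- vapply(chars, paste, character(1), collapse = "")
  }
  out_seq <- raw
  neg <- strand == "-"
  if (any(neg)) {
    out_seq[neg] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(raw[neg])))
  }
  reads <- tibble::tibble(
    read_id = seq_len(n_reads),
    seq = out_seq,
    hap = src$hap[pick],
    chrom = src$chrom[pick],
    start = start,
    strand = strand)
  if (!is.null(fastq)) write_fastq(reads, fastq)
  reads
}

#' Write reads as FASTQ (constant quality `I`)
#' @param reads Tibble with `read_id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  writeLines(as.vector(rbind(paste0("@read", reads$read_id),
                             reads$seq, "+", qual)), path)
  invisible(path)
}

#' Read a FASTA/FASTQ file into a read tibble
#' @param path FASTA or FASTQ file (gzip accepted).
#' @return Tibble with `read_id` and `seq`.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble::tibble(read_id = names(x) %||% as.character(seq_along(x)),
                 seq = as.character(x))
}
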