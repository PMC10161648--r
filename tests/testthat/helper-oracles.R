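# Independent oracles and shared fixtures.  Oracles deliberately take the
# "other direction" from the implementation: naive sorts and scans, and
# window lookups computed from the suffix-array side rather than by smearing
# markers leftward.

# Naive suffix array: sort all suffixes as strings (byte order = alphabet order).
naive_suffix_array <- function(s) {
  if (!is.character(s)) s <- dna_decode(s)
  n <- nchar(s)
  order(substring(s, 1:n, n), method = "radix") - 1L
}

# Naive occurrence count by direct substring comparison.
naive_count <- function(text, pat) {
  n <- nchar(text); m <- nchar(pat)
  if (m > n) return(0L)
  sum(substring(text, 1:(n - m + 1L), m:n) == pat)
}

# Naive BWT from the definition L[i] = T[sa[i] - 1].
naive_bwt <- function(s) {
  sa <- naive_suffix_array(s)
  prev <- ifelse(sa == 0L, nchar(s), sa)
  paste(substring(s, prev, prev), collapse = "")
}

# Definition-2 oracle: for every SA rank, look up markers at text positions
# sa[i] .. sa[i]+w (clipped at the document end), appending in window order.
# Returns the per-rank key strings ("" = empty list).
oracle_maw_keys <- function(markers, sa, w, text) {
  n <- length(sa)
  gkey <- character(text$n)
  if (nrow(markers)) {
    m <- markers[order(markers$gpos, markers$word), ]
    sp <- split(m$word, m$gpos)
    gkey[as.integer(names(sp)) + 1L] <- vapply(sp, paste, character(1), collapse = "\x1f")
  }
  span <- text$doc_bounds$end - text$doc_bounds$start
  doc_end <- rep.int(text$doc_bounds$end, span)
  res <- character(n)
  base_end <- doc_end[sa + 1L]
  for (d in 0:w) {
    pos <- sa + d
    kk <- ifelse(pos < base_end, gkey[pmin(pos, text$n - 1L) + 1L], "")
    ne <- kk != ""
    res[ne] <- ifelse(res[ne] == "", kk[ne], paste(res[ne], kk[ne], sep = "\x1f"))
  }
  res
}

# Naive marker query: locate every occurrence of q with the retained SA, then
# report markers overlapped by each occurrence span.
naive_marker_query <- function(index, markers, q, text_str) {
  m <- nchar(q)
  starts <- which(substring(text_str, 1:(nchar(text_str) - m + 1L),
                            m:nchar(text_str)) == q) - 1L
  hits <- lapply(starts, function(s) {
    sel <- markers$gpos >= s & markers$gpos <= s + m - 1L
    markers[sel, c("gpos", "word")]
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(text_offset = integer(0), word = character(0)))
  }
  dplyr::distinct(tibble::tibble(text_offset = out$gpos, word = out$word))
}

# --- toy fixtures -----------------------------------------------------------

toy_snv_panel <- function() {
  # ref ACGTA; SNV G->T at offset 2 carried by the single haplotype H1
  haplotype_panel(c(chr1 = "ACGTA"),
                  tibble::tibble(chrom_id = 0L, ref_pos = 2L, ref = "G", alt = "T"),
                  matrix(1L, 1, 1))
}

toy_del_panel <- function() {
  # ref ACGTA; deletion CG->C at offset 1 carried by H1
  haplotype_panel(c(chr1 = "ACGTA"),
                  tibble::tibble(chrom_id = 0L, ref_pos = 1L, ref = "CG", alt = "C"),
                  matrix(1L, 1, 1))
}

write_toy_vcf <- function(records, samples = "S1", dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), vcf)
  vcf
}

write_toy_fasta <- function(seqs, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "toy.fa")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), fa)
  fa
}

# random ACGT text ending in "#"
random_text <- function(len, seed) {
  set.seed(seed)
  paste0(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "#")
}

# random small panel built through the simulator
random_panel <- function(n_hap, len, seed, snv_rate = 0.01, indel_rate = 0.002) {
  cfg <- sim_config(chrom_len = as.integer(len), n_haplotypes = as.integer(n_hap),
                    snv_rate = snv_rate, indel_rate = indel_rate, seed = seed)
  simulate_panel(cfg)
}

# --- shared mid-size fixture (built once per test run) ----------------------

.fx <- new.env()

fixture_mid <- function() {
  if (is.null(.fx$mid)) {
    cfg <- sim_config(chrom_len = 20000L, n_haplotypes = 10L, seed = 7)
    sim <- simulate_panel(cfg)
    idx <- build_marker_index(as_haplotype_panel(sim, haps = 1:9), w = 19L)
    .fx$mid <- list(sim = sim, idx = idx, held_out = 10L)
  }
  .fx$mid
}

# truth table (haploid) for a held-out haplotype at an index's marked sites
holdout_truth <- function(sim, idx, hap) {
  v <- sim$variants
  v$allele <- sim$gt[, hap]
  tr <- dplyr::inner_join(idx$sites, v[, c("chrom_id", "ref_pos", "allele")],
                          by = c("chrom_id", "ref_pos"))
  tibble::tibble(chrom_id = tr$chrom_id, ref_off = tr$mark_off,
                 truth_allele = tr$allele, ref = tr$ref, alt = tr$alt)
}

# truth table (diploid) for a donor at an index's marked sites
donor_truth <- function(donor, idx) {
  tr <- dplyr::inner_join(idx$sites,
                          donor$truth[, c("chrom_id", "ref_pos", "truth_g")],
                          by = c("chrom_id", "ref_pos"))
  tibble::tibble(chrom_id = tr$chrom_id, ref_off = tr$mark_off,
                 truth_g = tr$truth_g, ref = tr$ref, alt = tr$alt)
}
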