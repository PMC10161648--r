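# Read scanning, evidence rules, likelihoods, callers.

test_that("an exact read across a variant yields exactly its allele evidence", {
  # 2 kb, one SNV carried by H1 of 2 haplotypes
  set.seed(1)
  ref <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  p <- haplotype_panel(
    c(chr1 = ref),
    tibble::tibble(chrom_id = 0L, ref_pos = 1000L,
                   ref = substr(ref, 1001, 1001),
                   alt = setdiff(c("A", "C", "G", "T"), substr(ref, 1001, 1001))[1]),
    matrix(c(1L, 0L), 1, 2))
  idx <- build_marker_index(p, w = 19L)
  tx_str <- dna_decode(idx$text$codes)
  d1 <- idx$doc_bounds$start[2]
  h1 <- substr(tx_str, d1 + 1L, idx$doc_bounds$end[2] - 1L)
  read <- substr(h1, 952, 1051)           # 100 bp across the variant (0-based 951..1050)
  ev <- genotype_read(read, idx, min_seed_len = 80L, strand_seed = 1L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$allele, 1L)
  expect_equal(ev$ref_off, 1000L)
  expect_gte(ev$ext_len, 80L)
})

test_that("a read of Ns yields no extensions and no evidence", {
  fx <- fixture_mid()
  ev <- genotype_read(strrep("N", 100), fx$idx)
  expect_equal(nrow(ev), 0L)
})

test_that("reads shorter than the minimum seed cannot qualify", {
  fx <- fixture_mid()
  tx_str <- dna_decode(fx$idx$text$codes)
  ev <- genotype_read(substr(tx_str, 101, 160), fx$idx, min_seed_len = 80L)
  expect_equal(nrow(ev), 0L)
})

test_that("evidence spanning two chromosomes in one extension is discarded", {
  set.seed(2)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  refs <- c(chrA = mk(1000), chrB = mk(1000))
  alt_of <- function(s, i) setdiff(c("A", "C", "G", "T"), substr(s, i + 1, i + 1))[1]
  p <- haplotype_panel(
    refs,
    tibble::tibble(chrom_id = c(0L, 1L), ref_pos = c(960L, 30L),
                   ref = c(substr(refs[1], 961, 961), substr(refs[2], 31, 31)),
                   alt = c(alt_of(refs[1], 960L), alt_of(refs[2], 30L))),
    matrix(c(1L, 0L, 1L, 0L), 2, 2, byrow = TRUE))
  idx <- build_marker_index(p, w = 19L)
  tx_str <- dna_decode(idx$text$codes)
  # H1's document: chrA then chrB contiguously (document 1 starts at 2001)
  doc1 <- substr(tx_str, 2002, 4002)
  junction_read <- substr(doc1, 941, 1060)   # 60 bp chrA tail + 60 bp chrB head
  ev <- genotype_read(junction_read, idx, min_seed_len = 80L, strand_seed = 1L)
  expect_equal(nrow(ev), 0L)
  # sanity: the chrA-only part of the same region does give evidence
  ok_read <- substr(doc1, 901, 1000)
  ev2 <- genotype_read(ok_read, idx, min_seed_len = 80L, strand_seed = 1L)
  expect_gte(nrow(ev2), 1L)
  expect_true(all(ev2$chrom_id == 0L))

  # two sub-threshold extensions (non-adjacent pieces) yield nothing
  frank <- paste0(substr(doc1, 101, 160), substr(doc1, 501, 560))
  ev3 <- genotype_read(frank, idx, min_seed_len = 80L, strand_seed = 1L)
  expect_equal(nrow(ev3), 0L)
})

test_that("evidence collection is sound on exact reads from indexed haplotypes", {
  fx <- fixture_mid()
  sim <- fx$sim; idx <- fx$idx
  hap <- 3L                                   # indexed haplotype
  reads <- simulate_reads(list(haplotype_seqs(sim, hap)), read_len = 150L,
                          coverage = 3, error_rate = 0, seed = 11)
  ev <- genotype_reads(reads, idx, min_seed_len = 80L, strand_seed = 2L)
  expect_gt(nrow(ev), 20L)
  truth <- holdout_truth(sim, idx, hap)
  j <- dplyr::inner_join(ev, truth, by = c("chrom_id", "ref_off"))
  expect_equal(nrow(j), nrow(ev))             # every site is a marked site
  expect_true(all(j$allele == j$truth_allele))
})

test_that("tally_evidence counts once per read per site", {
  ev <- tibble::tibble(
    read_id = c(1:10, 1L, 1L),
    chrom_id = 0L, ref_off = 500L,
    allele = c(rep(0L, 10), 0L, 0L))
  t1 <- tally_evidence(ev[1:10, ])
  expect_equal(t1$k, 10L); expect_equal(t1$l, 10L)
  # duplicate observations from one read collapse
  t2 <- tally_evidence(ev)
  expect_equal(t2$k, 10L)
  # mixed evidence
  ev3 <- tibble::tibble(read_id = 1:10, chrom_id = 0L, ref_off = 1L,
                        allele = rep(c(0L, 1L), 5))
  t3 <- tally_evidence(ev3)
  expect_equal(t3$k, 10L); expect_equal(t3$l, 5L)
  expect_equal(t3$alt_allele, 1L); expect_equal(t3$alt_count, 5L)
})

test_that("genotype likelihoods match closed forms", {
  # epsilon -> 0, l = k: L(2) -> 1, L(1) = 2^-k, L(0) -> 0
  eps <- 1e-12
  for (k in c(1, 5, 10)) {
    expect_equal(genotype_likelihood(2, k, k, eps), 1, tolerance = 1e-9)
    expect_equal(genotype_likelihood(1, k, k, eps), 2^(-k))
    expect_lt(genotype_likelihood(0, k, k, eps), 1e-10)
  }
  expect_equal(genotype_likelihood(2, 10, 10, 0.01), 0.99^10, tolerance = 1e-12)
  expect_equal(genotype_likelihood(1, 10, 10, 0.01), 2^-10)
  expect_equal(genotype_likelihood(2, 10, 5, 0.01), 0.99^5 * 0.01^5,
               tolerance = 1e-12)
  expect_error(genotype_likelihood(3, 5, 5, 0.01), "g must be")
  expect_error(genotype_likelihood(1, 5, 6, 0.01), "l <= k")
  expect_error(genotype_likelihood(1, 5, 5, 0), "epsilon")
})

test_that("likelihoods are proper probabilities over outcomes", {
  for (k in c(1, 4, 9)) {
    for (g in 0:2) {
      for (eps in c(0.01, 0.3)) {
        tot <- sum(choose(k, 0:k) * genotype_likelihood(g, k, 0:k, eps))
        expect_equal(tot, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("diploid calls take the likelihood argmax with REF-ward ties", {
  t20 <- tibble::tibble(chrom_id = 0L, ref_off = c(1L, 2L, 3L),
                        k = c(20L, 20L, 20L), l = c(20L, 0L, 10L),
                        alt_allele = c(NA, 1L, 1L), alt_count = c(0L, 20L, 10L))
  calls <- call_diploid(t20, epsilon = 0.01)
  expect_equal(calls$g, c(2L, 0L, 1L))
  expect_equal(calls$L2[1], genotype_likelihood(2, 20, 20, 0.01))
  # heterozygous is the argmax only in the middle of the l range
  gs <- vapply(0:20, function(l)
    call_diploid(tibble::tibble(chrom_id = 0L, ref_off = 1L, k = 20L, l = l,
                                alt_allele = 1L, alt_count = 20L - l))$g,
    integer(1))
  expect_equal(gs[1], 0L); expect_equal(gs[21], 2L)
  expect_equal(gs[11], 1L)
  expect_true(!is.unsorted(gs))
  # no evidence -> homozygous reference, with all likelihoods tied at 1
  empty <- call_diploid(tally_evidence(tibble::tibble(read_id = integer(0),
                                                      chrom_id = integer(0),
                                                      ref_off = integer(0),
                                                      allele = integer(0))),
                        sites = tibble::tibble(chrom_id = 0L, mark_off = 9L))
  expect_equal(empty$g, 2L)
  expect_equal(empty$k, 0L)
})

test_that("haploid calls take the majority allele with REF on ties", {
  tt <- tibble::tibble(chrom_id = 0L, ref_off = c(1L, 2L, 3L),
                       k = c(8L, 8L, 0L), l = c(3L, 4L, 0L),
                       alt_allele = c(1L, 1L, NA), alt_count = c(5L, 4L, 0L))
  calls <- call_haploid(tt)
  expect_equal(calls$allele, c(1L, 0L, 0L))
})

test_that("calls round-trip through VCF", {
  fx <- fixture_mid()
  sim <- fx$sim; idx <- fx$idx
  donor <- simulate_diploid_donor(sim, haps = c(9L, 10L))
  reads <- simulate_reads(donor, read_len = 150L, coverage = 5,
                          error_rate = 0, seed = 4)
  calls <- call_diploid(tally_evidence(genotype_reads(reads, idx)),
                        sites = idx$sites)
  path <- tempfile(fileext = ".vcf")
  write_calls_vcf(calls, idx, path)
  back <- read_calls_vcf(path, chrom_names = idx$chrom_names)
  expect_equal(nrow(back), nrow(calls))
  key_out <- paste(calls$chrom_id, calls$ref_off)
  sites <- idx$sites
  back3 <- dplyr::inner_join(dplyr::mutate(back, ref_pos = pos - 1L),
                             sites[, c("chrom_id", "ref_pos", "mark_off")],
                             by = c("chrom_id", "ref_pos"))
  expect_setequal(paste(back3$chrom_id, back3$mark_off), key_out)
  expect_equal(sort(back$g), sort(calls$g))
  # genotype conventions
  expect_true(all(back$gt[back$g == 2L] == "0/0"))
  expect_true(all(back$g[back$gt == "0/1"] == 1L))
})
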