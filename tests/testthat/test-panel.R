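# Panel parsing, text materialization, marker extraction, marker words.

test_that("parse_panel reads a phased VCF and applies the MAF filter", {
  fa <- write_toy_fasta(c(chr1 = "ACGTA"))
  vcf <- write_toy_vcf("chr1\t3\t.\tG\tT\t.\tPASS\t.\tGT\t1|0")
  p <- parse_panel(vcf, fa, min_af = 0)
  expect_s3_class(p, "haplotype_panel")
  expect_equal(nrow(p$variants), 1L)
  expect_equal(p$n_haplotypes, 2L)
  expect_equal(p$variants$ref_pos, 2L)        # 0-based
  expect_equal(p$variants$ref, "G")
  expect_equal(p$variants$alts[[1]], "T")
  expect_equal(as.vector(p$gt), c(1L, 0L))

  # MAF = 0.5 is not > 0.6
  p2 <- parse_panel(vcf, fa, min_af = 0.6)
  expect_equal(nrow(p2$variants), 0L)
  expect_equal(unname(p2$skipped["low_af"]), 1L)
})

test_that("parse_panel skips REF-inconsistent records with a tally", {
  fa <- write_toy_fasta(c(chr1 = "ACGTA"))
  vcf <- write_toy_vcf("chr1\t3\t.\tC\tT\t.\tPASS\t.\tGT\t1|0")
  expect_warning(p <- parse_panel(vcf, fa, min_af = 0), "skipped")
  expect_equal(nrow(p$variants), 0L)
  expect_equal(unname(p$skipped["ref_mismatch"]), 1L)
})

test_that("parse_panel rejects unphased or missing genotypes and absent chromosomes", {
  fa <- write_toy_fasta(c(chr1 = "ACGTA"))
  expect_error(parse_panel(write_toy_vcf("chr1\t3\t.\tG\tT\t.\tPASS\t.\tGT\t1/0"),
                           fa), "phased")
  expect_error(parse_panel(write_toy_vcf("chr2\t3\t.\tG\tT\t.\tPASS\t.\tGT\t1|0"),
                           fa), "missing from")
})

test_that("overlapping records are skipped, keeping the earlier one", {
  fa <- write_toy_fasta(c(chr1 = "ACGTACGTAC"))
  vcf <- write_toy_vcf(c("chr1\t2\t.\tCGT\tC\t.\tPASS\t.\tGT\t1|0",
                         "chr1\t4\t.\tT\tA\t.\tPASS\t.\tGT\t0|1"))
  expect_warning(p <- parse_panel(vcf, fa, min_af = 0), "skipped")
  expect_equal(nrow(p$variants), 1L)
  expect_equal(p$variants$ref, "CGT")
  expect_equal(unname(p$skipped["overlap"]), 1L)
})

test_that("materialize_text applies alleles and records provenance", {
  tx <- materialize_text(toy_snv_panel())
  expect_equal(dna_decode(tx$codes), "ACGTA$ACTTA#")
  # provenance of H1's substituted base (global offset 8) is ref column 2
  expect_equal(tx$doc_id[9], 1L)
  expect_equal(tx$prov_off[9], 2L)
  expect_true(is.na(tx$prov_off[6]))          # separator has no provenance

  # deletion: H1 document drops the G, provenance skips column 2
  tx2 <- materialize_text(toy_del_panel())
  expect_equal(dna_decode(tx2$codes), "ACGTA$ACTA#")
  expect_equal(tx2$prov_off[7:10], c(0L, 1L, 3L, 4L))
})

test_that("a panel with zero variants yields reference-identical documents", {
  novar <- tibble::tibble(chrom_id = integer(0), ref_pos = integer(0),
                          ref = character(0), alt = character(0))
  p <- haplotype_panel(c(chr1 = "ACGTA"), novar, matrix(integer(0), 0, 2))
  tx <- materialize_text(p)
  expect_equal(dna_decode(tx$codes), "ACGTA$ACGTA$ACGTA#")
})

test_that("extract_markers marks one position per variant per document", {
  p <- toy_snv_panel()
  tx <- materialize_text(p)
  mx <- extract_markers(p, tx)
  expect_equal(nrow(mx$markers), 2L)          # T_0's G and H1's T
  expect_equal(mx$markers$gpos, c(2L, 8L))
  expect_equal(mx$markers$allele, c(0L, 1L))
  expect_equal(mx$markers$ref_off, c(2L, 2L))
  expect_equal(mx$total_sites, 1L)

  # stored reference-allele mark decodes to allele id 0 ("no edit")
  ref_word <- mx$markers$word[mx$markers$doc == 0L]
  expect_equal(decode_marker(ref_word)$allele_id, 0L)

  # deletion marks the base immediately left of the indel in both documents
  p2 <- toy_del_panel()
  tx2 <- materialize_text(p2)
  mx2 <- extract_markers(p2, tx2)
  expect_equal(mx2$markers$ref_off, c(1L, 1L))
  expect_equal(mx2$markers$gpos, c(1L, 7L))   # the 'C' in each document
  expect_equal(mx2$markers$allele, c(0L, 1L))
  expect_equal(mx2$edit_table$kind, "del")
})

test_that("marker words encode/decode exactly and preserve order", {
  expect_equal(encode_marker(0, 0, 0), "0x0000000000000000")
  # second header chromosome gets chromosome field 0x001
  expect_equal(substr(sub("^0x", "", encode_marker(1, 0, 0)), 1, 3), "001")

  set.seed(101)
  n <- 10000
  chrom <- sample(0:(2^12 - 1), n, replace = TRUE)
  off <- floor(runif(n) * (2^48 - 1))
  allele <- sample(0:15, n, replace = TRUE)
  w <- encode_marker(chrom, off, allele)
  d <- decode_marker(w)
  expect_equal(d$chrom_id, chrom)
  expect_equal(d$ref_offset, off)
  expect_equal(d$allele_id, allele)

  # unsigned word order == (chrom, offset, allele) order
  o1 <- order(w, method = "radix")
  o2 <- order(chrom, off, allele, method = "radix")
  expect_equal(w[o1], w[o2])

  expect_error(encode_marker(2^12, 0, 0), "overflow")
  expect_error(encode_marker(0, 0, 16), "overflow")
})

test_that("marker count and projection monotonicity hold on random panels", {
  for (seed in c(11, 12)) {
    sim <- random_panel(n_hap = 6, len = 2000, seed = seed)
    p <- as_haplotype_panel(sim)
    tx <- materialize_text(p)
    mx <- extract_markers(p, tx)
    expect_equal(nrow(mx$markers), nrow(p$variants) * tx$n_docs)
    for (d in 0:(tx$n_docs - 1L)) {
      for (ci in seq_along(p$chrom_names) - 1L) {
        off <- tx$prov_off[tx$doc_id == d & !is.na(tx$prov_off) &
                           tx$prov_chrom == ci]
        expect_true(all(diff(off) >= 0))
      }
    }
  }
})

test_that("marked positions sit exactly in polymorphic columns (SNV-only panel)", {
  sim <- random_panel(n_hap = 8, len = 2000, seed = 21, indel_rate = 0)
  p <- as_haplotype_panel(sim)
  tx <- materialize_text(p)
  mx <- extract_markers(p, tx)
  # for SNV-only panels every position projecting to a variant column is
  # marked, and nothing else is
  poly_cols <- paste(p$variants$chrom_id, p$variants$ref_pos)
  in_poly <- which(!is.na(tx$prov_off) &
                   paste(tx$prov_chrom, tx$prov_off) %in% poly_cols) - 1L
  expect_setequal(mx$markers$gpos, in_poly)
})
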