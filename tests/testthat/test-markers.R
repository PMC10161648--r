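# Sparse S/E/X/B encoding, marker arrays MA and MA^w, FL marker query.

test_that("sparse encoding of the worked example has the stated S/E/X/B", {
  sm <- sparse_encode(list(NULL, "m1", "m1", NULL, "m2"))
  expect_equal(sm$S, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(sm$E, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(sm$X, c("m1", "m2"))
  expect_equal(sm$B, c(TRUE, TRUE))

  # access: A[2] non-empty because S.rank1(3)=1 > E.rank1(2)=0
  expect_equal(sparse_access(sm, 2L), "m1")
  expect_equal(sparse_access(sm, 3L), character(0))
  expect_equal(sparse_access(sm, 4L), "m2")
  expect_error(sparse_access(sm, 5L), "out of range")
})

test_that("multi-payload runs share one X slice delimited by B", {
  sm <- sparse_encode(list(NULL, c("m1", "m2"), c("m1", "m2")))
  expect_equal(sum(sm$S), 1L)
  expect_equal(sm$X, c("m1", "m2"))
  expect_equal(sm$B, c(TRUE, FALSE))
  expect_equal(sparse_access(sm, 1L), c("m1", "m2"))
  expect_equal(sparse_access(sm, 2L), c("m1", "m2"))
  expect_equal(sparse_access(sm, 0L), character(0))
})

test_that("all-empty arrays encode to empty structures", {
  sm <- sparse_encode(rep(list(NULL), 6))
  expect_equal(sum(sm$S), 0L)
  expect_equal(sum(sm$E), 0L)
  expect_length(sm$X, 0L)
})

test_that("sparse encode/decode round-trips 100 random multimap arrays", {
  set.seed(77)
  syms <- sprintf("m%02d", 1:8)
  for (case in 1:100) {
    n <- sample(1:40, 1)
    A <- lapply(seq_len(n), function(i) {
      if (runif(1) < 0.5) NULL
      else sample(syms, sample(1:3, 1))
    })
    # encourage runs (list-assign keeps NULL elements in place)
    if (n > 3) for (i in 2:n) if (runif(1) < 0.4) A[i] <- list(A[[i - 1L]])
    sm <- sparse_encode(A)
    got <- lapply(seq_len(n) - 1L, function(i) sparse_access(sm, i))
    want <- lapply(A, function(p) if (is.null(p)) character(0) else p)
    expect_equal(got, want)
    # run-length sanity: runs never exceed non-empty entries
    expect_lte(sum(sm$S), sum(lengths(want) > 0))
  }
})

test_that("MA matches Definition 1 on the toy panel", {
  p <- toy_snv_panel()
  tx <- materialize_text(p)
  mx <- extract_markers(p, tx)
  sa <- build_suffix_array(tx)
  ma <- build_marker_array(mx$markers, sa, tx)
  dense <- sparse_decode(ma$sparse)
  nonempty <- which(lengths(dense) > 0) - 1L
  expect_length(nonempty, 2L)
  expect_setequal(sa[nonempty + 1L], mx$markers$gpos)
  for (i in nonempty) {
    expect_equal(sparse_access(ma$sparse, i),
                 mx$markers$word[mx$markers$gpos == sa[i + 1L]])
  }
})

test_that("an empty marker map yields an all-empty marker array", {
  novar <- tibble::tibble(chrom_id = integer(0), ref_pos = integer(0),
                          ref = character(0), alt = character(0))
  p <- haplotype_panel(c(chr1 = "ACGTACGTAC"), novar, matrix(integer(0), 0, 2))
  tx <- materialize_text(p)
  mx <- extract_markers(p, tx)
  sa <- build_suffix_array(tx)
  ma <- build_marker_array(mx$markers, sa, tx)
  expect_equal(sum(ma$sparse$S), 0L)
})

test_that("MA^w equals the Definition-2 window oracle for several w", {
  sim <- random_panel(n_hap = 5, len = 2000, seed = 31)
  p <- as_haplotype_panel(sim)
  tx <- materialize_text(p)
  mx <- extract_markers(p, tx)
  sa <- build_suffix_array(tx)
  for (w in c(0L, 1L, 3L, 19L)) {
    maw <- build_augmented_marker_array(mx$markers, sa, w, tx)
    expect_equal(markergt:::.sparse_keys(maw$sparse),
                 oracle_maw_keys(mx$markers, sa, w, tx),
                 info = paste("w =", w))
  }
  # w = 0 degenerates to MA
  ma <- build_marker_array(mx$markers, sa, tx)
  maw0 <- build_augmented_marker_array(mx$markers, sa, 0L, tx)
  expect_identical(ma$sparse$S, maw0$sparse$S)
  expect_identical(ma$sparse$X, maw0$sparse$X)
})

test_that("smeared entries list markers in increasing text-offset order", {
  # two SNVs 2 apart; w = 3 windows overlap both
  p <- haplotype_panel(
    c(chr1 = "ACGTACGTACGTACGT"),
    tibble::tibble(chrom_id = c(0L, 0L), ref_pos = c(8L, 10L),
                   ref = c("A", "G"), alt = c("T", "C")),
    matrix(c(1L, 1L), 2, 1))
  tx <- materialize_text(p)
  mx <- extract_markers(p, tx)
  sa <- build_suffix_array(tx)
  maw <- build_augmented_marker_array(mx$markers, sa, 3L, tx)
  lens <- lengths(sparse_decode(maw$sparse))
  expect_true(any(lens == 2L))
  # a rank whose window holds both markers lists the left one first
  i2 <- which(lens == 2L)[1] - 1L
  pay <- sparse_access(maw$sparse, i2)
  offs <- decode_marker(pay)$ref_offset
  expect_equal(offs, sort(offs))
})

test_that("smearing never crosses a document separator", {
  # marker near a document start: the previous document's tail stays empty
  p <- toy_snv_panel()
  tx <- materialize_text(p)
  mx <- extract_markers(p, tx)
  sa <- build_suffix_array(tx)
  maw <- build_augmented_marker_array(mx$markers, sa, 19L, tx)
  dense <- sparse_decode(maw$sparse)
  marked_pos <- sa[which(lengths(dense) > 0)]
  # H1's variant sits at gpos 8, document start 6: the smear may reach back
  # only to position 6; positions 0..5 (T_0 + separator) carry only T_0's mark
  h1_positions <- marked_pos[marked_pos >= 6L]
  expect_true(all(h1_positions >= 6L & h1_positions <= 8L))
  expect_false(5L %in% marked_pos)  # T_0's separator is never marked
})

test_that("fl_marker_query returns exactly the overlapped markers", {
  fx <- fixture_mid()
  sim <- fx$sim; idx <- fx$idx
  tx <- idx$text
  text_str <- dna_decode(tx$codes)
  mm <- marker_map(idx$markers)

  # a query spanning H1's copy of a variant reports that marker only
  v1 <- idx$markers[idx$markers$doc == 1L & idx$markers$allele > 0L, ][1, ]
  q <- substr(text_str, v1$gpos - 2L, v1$gpos + 4L)       # 7-mer over the site
  got <- fl_marker_query(idx$fm, mm, q)
  want <- naive_marker_query(idx$fm, idx$markers, q, text_str)
  expect_equal(dplyr::arrange(got, text_offset, word),
               dplyr::arrange(want, text_offset, word))
  expect_true(v1$word %in% got$word)

  # an invariant region yields nothing: query inside a marker-free gap of T_0
  g0 <- sort(idx$markers$gpos[idx$markers$doc == 0L])
  gap <- which(diff(g0) > 80L)[1]
  lo0 <- g0[gap] + 20L                                    # 0-based, well clear
  qi <- substr(text_str, lo0 + 1L, lo0 + 40L)
  expect_equal(nrow(fl_marker_query(idx$fm, mm, qi)), 0L)

  # a query over T_0's copy reports the allele-0 marker
  v0 <- idx$markers[idx$markers$doc == 0L, ][5, ]
  q0 <- substr(text_str, v0$gpos - 3L, v0$gpos + 3L)
  got0 <- fl_marker_query(idx$fm, mm, q0)
  expect_equal(dplyr::arrange(got0, text_offset, word),
               dplyr::arrange(naive_marker_query(idx$fm, idx$markers, q0, text_str),
                              text_offset, word))
  expect_true(v0$word %in% got0$word)
})
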