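test_that("N-terminal truncation arithmetic matches the Delta notation", {
  set.seed(40)
  p <- seq_record("YlSQE", random_protein(40), "protein")
  d1 <- truncate_n(p, 1, 37)
  expect_equal(nchar(d1$seq), 3L)
  expect_equal(d1$seq, substr(p$seq, 38, 40))
  expect_match(d1$id, "_d1-37$")

  d2 <- truncate_n(p, 1, 37, keep_initial_met = TRUE)
  expect_equal(nchar(d2$seq), 4L)
  expect_equal(d2$seq, paste0(substr(p$seq, 1, 1), substr(p$seq, 38, 40)))
  expect_match(d2$id, "_d2-37$")
  expect_identical(d2$seq, truncate_n(p, 2, 37)$seq)

  expect_error(truncate_n(p, 1, 40), "C-terminus")
  expect_error(truncate_n(p, 0, 5), "invalid deletion range")
  expect_error(truncate_n(p, 5, 10, keep_initial_met = TRUE),
               "delete_from is 1 or 2")
})

test_that("truncation composes consistently and never recovers residues", {
  set.seed(60)
  p <- seq_record("x", random_protein(60), "protein")
  t1 <- truncate_n(p, 1, 20)
  expect_equal(nchar(t1$seq), 40L)
  t2 <- truncate_n(t1, 1, 10)
  expect_equal(t2$seq, substr(p$seq, 31, 60))
  expect_false(grepl(substr(p$seq, 2, 20), t2$seq, fixed = TRUE))
})

test_that("linker fusion lengths and linker text are exact", {
  set.seed(100)
  up <- seq_record("MdOSCm", paste0(random_protein(100), "*"), "protein")
  dn <- seq_record("trYlSQE", random_protein(50, first_met = FALSE),
                   "protein")
  f1 <- fuse(up, dn)
  expect_equal(nchar(f1$seq), 153L)
  expect_equal(substr(f1$seq, 101, 103), "GSG")
  expect_false(grepl("\\*", f1$seq))  # upstream stop removed

  f4 <- fuse(up, dn, repeats = 4)
  expect_equal(nchar(f4$seq), 162L)
  expect_equal(substr(f4$seq, 101, 112), "GSGGSGGSGGSG")
  expect_equal(f4$id, "MdOSCm-GSGx4-trYlSQE")

  f0 <- fuse(up, dn, repeats = 0)
  expect_equal(nchar(f0$seq), 150L)
  expect_equal(f0$seq, paste0(substr(up$seq, 1, 100), dn$seq))

  expect_error(fuse(seq_record("d", "ATG", "dna"), dn), "expected a protein")
})

test_that("fusion is associative at the sequence level", {
  set.seed(45)
  a <- seq_record("a", random_protein(20), "protein")
  b <- seq_record("b", random_protein(15, first_met = FALSE), "protein")
  c_ <- seq_record("c", random_protein(10, first_met = FALSE), "protein")
  expect_equal(fuse(fuse(a, b), c_)$seq, fuse(a, fuse(b, c_))$seq)
})

test_that("NTM-domain swap splices at codon boundaries and preserves frame", {
  set.seed(202)
  ut <- random_usage_table(202)
  don_p <- random_protein(60)
  rcp_p <- random_protein(480)
  don <- back_translate_strict(don_p, ut)
  rcp <- back_translate_strict(rcp_p, ut)

  ch <- swap_ntm(rcp, don, recipient_boundary = 28, donor_boundary = 30)
  expect_equal(nchar(ch$record$seq) %% 3L, 0L)
  expect_equal(nchar(ch$translation$seq), 30L + (480L - 28L))
  expect_equal(ch$translation$seq,
               paste0(substr(don_p, 1, 30), substr(rcp_p, 29, 480)))

  # translation oracle: chimera translation equals the concatenation of the
  # independently translated segments
  seg_don <- translate_cds(seq_record("s1", substr(don$seq, 1, 90), "dna"))
  expect_equal(substr(ch$translation$seq, 1, 30), seg_don$seq)

  # self-swap with equal boundaries is the identity
  self <- swap_ntm(rcp, rcp, 40, 40)
  expect_equal(self$record$seq, rcp$seq)

  expect_error(swap_ntm(rcp, don, 480, 30), "boundary")
  expect_error(swap_ntm(rcp, don, 28, 60), "boundary")
  expect_error(swap_ntm(seq_record("f", "ATGAA", "dna"), don, 1, 1),
               "not divisible by 3")
})

test_that("swap trace records splice coordinates in nt and residues", {
  set.seed(7)
  ut <- random_usage_table(7)
  don <- back_translate_strict(random_protein(40), ut)
  rcp <- back_translate_strict(random_protein(50), ut)
  ch <- swap_ntm(rcp, don, 20, 25)
  expect_equal(nrow(ch$trace), 2L)
  expect_match(ch$trace$to[1], "residues 1-25 \\(nt \\[0,75\\)\\)")
  expect_match(ch$trace$to[2], "nt \\[60,153\\)")
})
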