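test_that("strict back-translation picks family-maximal codons and a stop", {
  tab <- compute_usage_table(list(seq_record("a", "ATGAAAAAATAA", "dna")))
  expect_equal(back_translate_strict("MK", tab)$seq, "ATGAAATAA")
  expect_equal(back_translate_strict("M", tab)$seq, "ATGTAA")
  expect_error(back_translate_strict(seq_record("bad", "MX*", "protein"),
                                     tab),
               "invalid protein characters")

  set.seed(3)
  ut <- random_usage_table(3)
  p <- random_protein(100)
  expect_equal(cai(back_translate_strict(p, ut), ut), 1)
})

test_that("scan_violations finds the stated textbook cases", {
  cs <- constraint_set(forbidden_motifs = c(EcoRI = "GAATTC"),
                       max_homopolymer = 8, gc_window = NULL)
  r <- scan_violations("GAATTC", cs)
  expect_equal(nrow(r), 1L)
  expect_equal(r$kind, "motif")
  expect_equal(c(r$start, r$end), c(0L, 6L))

  r2 <- scan_violations("AAAAAAAAA", cs)
  expect_equal(r2$kind, "homopolymer")
  expect_equal(c(r2$start, r2$end), c(0L, 9L))
  expect_equal(nrow(scan_violations("", cs)), 0L)

  # reverse-strand motif hit (BsaI is not palindromic)
  cs2 <- constraint_set(forbidden_motifs = c(BsaI = "GGTCTC"),
                        max_homopolymer = 8, gc_window = NULL)
  expect_equal(scan_violations("GAGACC", cs2)$kind, "motif")
})

test_that("scan_violations agrees with a naive rescanner on random DNA", {
  cs <- constraint_set(
    forbidden_motifs = c(EcoRI = "GAATTC", BsaI = "GGTCTC", AT4 = "WWWW"),
    max_homopolymer = 4,
    gc_window = c(width = 20, min_gc = 0.35, max_gc = 0.65),
    global_gc = c(min = 0.40, max = 0.60))
  set.seed(97)
  for (i in 1:20) {
    s <- random_dna(sample(50:500, 1))
    expect_equal(report_triples(scan_violations(s, cs)),
                 report_triples(naive_scan(s, cs)),
                 info = paste("sequence", i))
  }
})

test_that("optimization is a no-op when the strict encoding is compliant", {
  # table whose maximal codons spell a motif-free, run-free periodic pattern
  ut <- compute_usage_table(list(seq_record("t", "GACGTCAAATTCTAA", "dna")))
  p <- paste(rep(c("D", "V", "K", "F"), 10), collapse = "")
  cs <- constraint_set(gc_window = NULL)
  strict <- back_translate_strict(p, ut)
  expect_equal(nrow(scan_violations(strict, cs)), 0L)
  res <- optimize_codons(p, ut, cs)
  expect_equal(res$record$seq, strict$seq)
  expect_equal(nrow(res$trace), 0L)
  expect_equal(res$cai_after, 1)
})

test_that("optimizer attains the exhaustive-search CAI optimum on small instances", {
  set.seed(123)
  n_hit_motif <- 0L
  for (i in 1:40) {
    ut <- random_usage_table(1000 + i, n_genes = 40)
    p <- random_protein(sample(3:7, 1), first_met = (runif(1) < 0.5))
    while (!grepl("[^MW]", p)) {
      p <- random_protein(sample(3:7, 1), first_met = FALSE)
    }
    motif <- substr(back_translate_strict(p, ut)$seq, 4, 9)
    cs <- constraint_set(forbidden_motifs = c(site = motif),
                         max_homopolymer = Inf, gc_window = NULL)
    stop_codon <- substr(back_translate_strict("M", ut)$seq, 4, 6)
    oracle <- best_compliant_cai(p, ut, motif, stop_codon)
    res <- tryCatch(optimize_codons(p, ut, cs),
                    constraint_infeasible = function(e) NULL)
    if (is.null(oracle)) {
      expect_null(res, info = "no compliant encoding exists")
      next
    }
    expect_false(is.null(res))
    expect_equal(res$cai_after, oracle$best, tolerance = 1e-9,
                 info = paste("protein", p))
    if (nrow(res$trace) > 0) n_hit_motif <- n_hit_motif + 1L
  }
  expect_gt(n_hit_motif, 10L)  # the forced motif actually bites
})

test_that("poly-Lys repair caps homopolymer runs by alternating codons", {
  tab <- compute_usage_table(list(
    seq_record("k", paste0(strrep("AAA", 5), "AAGTAA"), "dna")))
  cs <- constraint_set(forbidden_motifs = character(0), max_homopolymer = 5,
                       gc_window = NULL)
  res <- optimize_codons(strrep("K", 12), tab, cs)
  expect_equal(nrow(scan_violations(res$record, cs)), 0L)
  expect_equal(translate_cds(res$record)$seq, paste0(strrep("K", 12), "*"))
  expect_true(all(res$trace$to == "AAG"))
  expect_lt(res$cai_after, 1)
})

test_that("optimization preserves translation, complies, and is deterministic", {
  set.seed(77)
  ut <- random_usage_table(77)
  cs <- constraint_set()  # package defaults incl. GC window
  for (i in 1:25) {
    p <- random_protein(sample(20:60, 1))
    res <- tryCatch(optimize_codons(p, ut, cs),
                    constraint_infeasible = function(e) e)
    if (inherits(res, "constraint_infeasible")) {
      expect_s3_class(res$report, "data.frame")
      next
    }
    expect_equal(translate_cds(res$record)$seq, paste0(p, "*"))
    expect_equal(nrow(scan_violations(res$record, cs)), 0L)
    expect_true(res$cai_after <= 1)
    expect_equal(res$cai_after == 1, nrow(res$trace) == 0L)
    res2 <- optimize_codons(p, ut, cs)
    expect_identical(res$record$seq, res2$record$seq)
    expect_identical(res$trace, res2$trace)
  }
})

test_that("infeasible constraints raise a classed error carrying the report", {
  tab <- compute_usage_table(list(
    seq_record("k", paste0(strrep("AAA", 3), "TAA"), "dna")))
  cs <- constraint_set(forbidden_motifs = c(runA = "AAAA", runG = "AAG"),
                       max_homopolymer = 3, gc_window = NULL)
  err <- tryCatch(optimize_codons(strrep("K", 8), tab, cs),
                  constraint_infeasible = function(e) e)
  expect_s3_class(err, "constraint_infeasible")
  expect_true(nrow(err$report) > 0)
})
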