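test_that("rank_top_genes orders by expression with lexicographic ties", {
  tab <- data.frame(gene = c("g1", "g2", "g3"), expression = c(10, 5, 10))
  expect_equal(rank_top_genes(tab, 2), c("g1", "g3"))
  expect_equal(rank_top_genes(data.frame(gene = "g1", expression = 1), 1),
               "g1")
  expect_error(rank_top_genes(tab, 4), "only 3 rows")
  expect_error(
    rank_top_genes(data.frame(gene = character(0),
                              expression = numeric(0)), 1),
    "empty")
})

test_that("rank_top_genes matches an exhaustive full-sort oracle", {
  set.seed(71)
  tab <- data.frame(gene = sprintf("gene%04d", sample(1:1000)),
                    expression = runif(1000, 0, 1e5))
  oracle <- tab$gene[order(tab$expression, decreasing = TRUE)][1:100]
  expect_equal(rank_top_genes(tab, 100), oracle)
})

test_that("compute_usage_table reproduces hand counts and family weights", {
  t1 <- compute_usage_table(list(seq_record("a", "ATGAAAAAATAA", "dna")))
  expect_equal(unname(t1$counts[["AAA"]]), 2)
  expect_equal(unname(t1$freq[["AAA"]]), 1)
  expect_equal(unname(t1$weight[["AAA"]]), 1)

  t2 <- compute_usage_table(list(seq_record("b", "ATGTTGCTGCTGTAA", "dna")))
  expect_equal(unname(t2$counts[["TTG"]]), 1)
  expect_equal(unname(t2$counts[["CTG"]]), 2)
  expect_equal(unname(t2$freq[["CTG"]]), 2 / 3)
  expect_equal(unname(t2$weight[["CTG"]]), 1)
  expect_equal(unname(t2$weight[["TTG"]]), 0.5)
})

test_that("usage-table invariants hold on a generated gene set", {
  tab <- compute_usage_table(generate_cds_set(bias_spec(n_genes = 40,
                                                        seed = 5)))
  fams <- split(names(tab$aa), unname(tab$aa))
  for (aa in names(fams)) {
    if (aa %in% tab$unobserved) next
    expect_equal(sum(tab$freq[fams[[aa]]]), 1, tolerance = 1e-9)
    expect_equal(max(tab$weight[fams[[aa]]]), 1)
  }
  expect_true(all(tab$weight > 0 & tab$weight <= 1))
})

test_that("table construction is permutation-invariant and additive", {
  set.seed(11)
  a <- generate_cds_set(bias_spec(n_genes = 8, length_range = c(30, 60),
                                  seed = 21))
  b <- generate_cds_set(bias_spec(n_genes = 8, length_range = c(30, 60),
                                  seed = 22))
  t_ab <- compute_usage_table(c(a, b))
  t_perm <- compute_usage_table(sample(c(a, b)))
  expect_equal(t_ab$counts, t_perm$counts)
  expect_equal(t_ab$counts,
               compute_usage_table(a)$counts + compute_usage_table(b)$counts)
})

test_that("frame and stop anomalies are reported", {
  expect_error(compute_usage_table(list(seq_record("x", "ATGAA", "dna"))),
               "'x'.*not divisible by 3")
  expect_warning(
    compute_usage_table(list(seq_record("y", "ATGTAAAAATAA", "dna"))),
    "internal stop")
  unobs <- compute_usage_table(list(seq_record("z", "ATGAAATAA", "dna")))
  expect_true("L" %in% unobs$unobserved)
  expect_equal(unname(unobs$freq[["CTG"]]), 1 / 6)
  expect_equal(unname(unobs$weight[["CTG"]]), 1 / 6)
})

test_that("CAI matches its definition and a log-domain product oracle", {
  tab <- random_usage_table_seeded <- local({
    set.seed(31)
    random_usage_table(31)
  })
  maximal <- vapply(FAMILIES64[AA20], function(fam) {
    fam[which.max(tab$weight[fam])]
  }, character(1))
  all_max <- paste0(paste0(maximal[c("K", "L", "F", "E")], collapse = ""))
  expect_equal(cai(all_max, tab), 1)

  # two includable codons with weights 1 and 0.25 -> sqrt(0.25)
  lys <- FAMILIES64[["K"]]
  toy <- compute_usage_table(list(
    seq_record("t", paste0(strrep(lys[1], 4), lys[2], "TAA"), "dna")))
  expect_equal(unname(toy$weight[[lys[2]]]), 0.25)
  expect_equal(cai(paste0(lys[1], lys[2]), toy), 0.5)

  set.seed(13)
  cds <- paste0("ATG", random_dna(294), "TAA")
  codons <- substring(cds, seq(1, 298, 3), seq(3, 300, 3))
  aa <- GC_CODE[codons]
  keep <- !(aa %in% c("M", "W")) & !(aa == "*")
  oracle <- exp(sum(log(tab$weight[codons[keep]])) / sum(keep))
  expect_equal(cai(cds, tab), oracle, tolerance = 1e-12)
  expect_error(cai("ATGTGG", tab), "no includable codons")
})

test_that("usage tables round-trip through the TSV format", {
  tab <- local({
    set.seed(41)
    random_usage_table(41)
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_usage_table(tab, path)
  back <- read_usage_table(path)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$freq, tab$freq, tolerance = 1e-6)
  expect_equal(back$weight, tab$weight, tolerance = 1e-6)
  expect_equal(back$unobserved, tab$unobserved)

  lines <- readLines(path)
  drop_one <- lines[-length(lines)]
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(drop_one, p2)
  expect_error(read_usage_table(p2), "all 64 codons")

  bad <- lines
  i <- grep("^AAA\t", bad)[1]
  f <- strsplit(bad[i], "\t")[[1]]
  f[4] <- sprintf("%.6f", as.numeric(f[4]) + 0.02)
  bad[i] <- paste(f, collapse = "\t")
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(bad, p3)
  expect_error(read_usage_table(p3), "normalization error")
})

test_that("expression tables read with auto-detected separator and header", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\texpression", "g1\t10.5", "g2\t3"), p)
  tab <- read_expression_table(p)
  expect_equal(tab$gene, c("g1", "g2"))
  expect_equal(tab$expression, c(10.5, 3))
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,1", "g2,2"), p2)
  expect_equal(read_expression_table(p2)$expression, c(1, 2))
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,1", "g1,2"), p3)
  expect_error(read_expression_table(p3), "duplicate")
})
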