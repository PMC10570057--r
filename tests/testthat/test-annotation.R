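mk_gene <- function(exons, strand = "+", contig = "c1") {
  mu <- merge_intervals(exons$start, exons$end)
  ex <- data.frame(start = mu[, 1], end = mu[, 2])
  list(gene_id = "g", contig = contig, start = min(ex$start),
       end = max(ex$end), strand = strand,
       transcripts = list(t = ex), exons = ex,
       exon_union_length = sum(ex$end - ex$start))
}
mk_te <- function(start, end, contig = "c1", family = "roo",
                  copy_id = "roo_1") {
  data.frame(copy_id = copy_id, family = family, contig = contig,
             start = start, end = end, strand = "+",
             length = end - start, stringsAsFactors = FALSE)
}

test_that("TE length filter uses the strict <80 bp rule", {
  tes <- rbind(mk_te(0, 79, copy_id = "a"), mk_te(0, 80, copy_id = "b"))
  kept <- filter_te_length(tes, 80)
  expect_equal(kept$copy_id, "b")     # 79 removed, 80 retained
  expect_equal(nrow(filter_te_length(tes[0, ], 80)), 0)
})

test_that("tandem repeat fraction matches exhaustive enumeration", {
  cfg <- prep_config()
  expect_equal(tandem_repeat_fraction(strrep("AC", 50), cfg), 1.0)
  # period-3 repeat half + verified repeat-free half
  clean <- "CTGACTAGATCTCGCCAACTCAACAGGTCTAGTTGAATCTTCTCTTATGTGATGCATCTTCCAACCACAGCACGCTCGAGTGGAGTTGTCCTCTATGATG"
  expect_equal(oracle_tandem_fraction(clean), 0)
  mixed <- paste0(strrep("AGT", 33), "A", clean)  # 100 bp period-3 + 100 bp clean
  expect_equal(tandem_repeat_fraction(mixed, cfg),
               oracle_tandem_fraction(mixed))
  expect_equal(tandem_repeat_fraction(mixed, cfg), 0.5)
  expect_equal(tandem_repeat_fraction("ACGTACGGACTTAGCA", cfg), 0.0)
  expect_error(tandem_repeat_fraction("", cfg), "empty")
})

test_that("tandem repeat scan agrees with brute force on random strings", {
  cfg <- prep_config(max_period = 4, repeat_min_copies = 3)
  set.seed(7)
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:30, 1),
                      replace = TRUE), collapse = "")
    expect_equal(tandem_repeat_fraction(s, cfg),
                 oracle_tandem_fraction(s, 4, 3), info = s)
  }
})

test_that("SSR filter removes TEs above (not at) the 50% boundary", {
  clean100 <- "CTGACTAGATCTCGCCAACTCAACAGGTCTAGTTGAATCTTCTCTTATGTGATGCATCTTCCAACCACAGCACGCTCGAGTGGAGTTGTCCTCTATGATG"
  at50 <- paste0(strrep("AT", 25), substr(clean100, 1, 50))     # exactly 0.5
  above <- paste0(strrep("AT", 30), substr(clean100, 1, 40))    # 0.6
  stopifnot(oracle_tandem_fraction(at50) == 0.5,
            oracle_tandem_fraction(above) == 0.6)
  genome <- c(c1 = paste0(at50, above, clean100))
  tes <- rbind(mk_te(0, 100, copy_id = "at_boundary"),
               mk_te(100, 200, copy_id = "above"),
               mk_te(200, 300, copy_id = "clean"))
  suppressMessages(kept <- filter_te_ssr(tes, genome, prep_config()))
  expect_equal(kept$copy_id, c("at_boundary", "clean"))
  expect_error(filter_te_ssr(mk_te(0, 100, contig = "cX"), genome,
                             prep_config()), "cX")
})

test_that("gene windows are strand-aware and clamped", {
  g <- mk_gene(data.frame(start = 5000, end = 8000))
  w <- gene_windows(g, 3000, 20000)
  expect_equal(unlist(w$upstream), c(start = 2000, end = 5000))
  expect_equal(unlist(w$downstream), c(start = 8000, end = 11000))
  gneg <- mk_gene(data.frame(start = 5000, end = 8000), strand = "-")
  wn <- gene_windows(gneg, 3000, 20000)
  expect_equal(unlist(wn$upstream), c(start = 8000, end = 11000))
  expect_equal(unlist(wn$downstream), c(start = 2000, end = 5000))
  gedge <- mk_gene(data.frame(start = 1000, end = 2000))
  expect_equal(unlist(gene_windows(gedge, 3000, 20000)$upstream),
               c(start = 0, end = 1000))
})

test_that("TE position classification matches the stated geometry", {
  g <- mk_gene(data.frame(start = c(5000, 6000), end = c(6000, 7000)))
  g$exons <- data.frame(start = 5000, end = 6000)   # exon + intron to 7000
  g$end <- 7000
  expect_equal(classify_te_vs_gene(mk_te(5200, 5350)[1, ], g), "embedded")
  expect_equal(classify_te_vs_gene(mk_te(5900, 6100)[1, ], g), "overlapped")
  expect_equal(classify_te_vs_gene(mk_te(6100, 6500)[1, ], g), "intronic")
  # boundary: gap of 3001 bp from a window of 3000 -> none
  g2 <- mk_gene(data.frame(start = 5000, end = 8000))
  expect_equal(classify_te_vs_gene(mk_te(1900, 1999)[1, ], g2, 3000),
               "none")
  expect_equal(classify_te_vs_gene(mk_te(1900, 2000)[1, ], g2, 3000),
               "upstream")
  expect_equal(classify_te_vs_gene(mk_te(0, 100, contig = "c2")[1, ], g2),
               "none")
})

test_that("classification agrees with a base-wise classifier on random geometries", {
  set.seed(13)
  for (i in 1:60) {
    n_ex <- sample(1:3, 1)
    bounds <- sort(sample(seq(3000, 9000, by = 25), 2 * n_ex))
    ex <- data.frame(start = bounds[seq(1, 2 * n_ex, 2)],
                     end = bounds[seq(2, 2 * n_ex, 2)])
    ex <- ex[ex$end > ex$start, , drop = FALSE]
    if (!nrow(ex)) next
    g <- mk_gene(ex, strand = sample(c("+", "-"), 1))
    te_s <- sample(0:11000, 1)
    te <- mk_te(te_s, te_s + sample(c(50, 150, 400), 1))[1, ]
    w <- sample(c(500, 3000), 1)
    got <- classify_te_vs_gene(te, g, w, 15000)
    want <- oracle_classify(te, g, w, 15000)
    expect_equal(got, want,
                 info = sprintf("te=(%d,%d) w=%d", te$start, te$end, w))
    if (got %in% c("embedded", "overlapped", "intronic"))
      expect_gt(overlap_bp(te$start, te$end, g$start, g$end), 0)
    # widening the window never loses an inside category, never
    # downgrades a window category to none
    got_wide <- classify_te_vs_gene(te, g, w + 2000, 15000)
    if (got %in% c("embedded", "overlapped", "intronic"))
      expect_equal(got_wide, got)
    if (got %in% c("upstream", "downstream"))
      expect_false(got_wide == "none")
  }
})

test_that("length and SSR filters commute", {
  clean100 <- "CTGACTAGATCTCGCCAACTCAACAGGTCTAGTTGAATCTTCTCTTATGTGATGCATCTTCCAACCACAGCACGCTCGAGTGGAGTTGTCCTCTATGATG"
  genome <- c(c1 = paste0(strrep("AT", 60), clean100, strrep("GAT", 20)))
  tes <- rbind(mk_te(0, 120, copy_id = "ssr"),        # pure SSR
               mk_te(120, 190, copy_id = "short"),     # 70 bp
               mk_te(120, 220, copy_id = "good"))
  cfg <- prep_config()
  a <- suppressMessages(
    filter_te_ssr(filter_te_length(tes, cfg$te_min_length), genome, cfg))
  b <- suppressMessages(
    filter_te_length(filter_te_ssr(tes, genome, cfg), cfg$te_min_length))
  expect_equal(a, b)
  expect_equal(a$copy_id, "good")
})
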