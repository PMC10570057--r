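test_that("fpkm follows the closed form", {
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(0, 1000, 1e6), 0)
  expect_equal(fpkm(3, 1500, 2e5), 3 * 1e9 / (1500 * 2e5))
  expect_equal(fpkm(3, 1500, 2e5), 10)
  expect_error(fpkm(1, 1000, 0), "no mapped fragments")
  # linear in count, inverse-linear in length
  set.seed(1)
  for (i in 1:10) {
    cnt <- sample(1:50, 1); len <- sample(200:5000, 1)
    tot <- sample(1e4:1e6, 1)
    expect_equal(fpkm(2 * cnt, len, tot), 2 * fpkm(cnt, len, tot))
    expect_equal(fpkm(cnt, 2 * len, tot), fpkm(cnt, len, tot) / 2)
  }
})

test_that("the expression gate is inclusive at the threshold", {
  rec <- data.frame(feature_id = c("a", "b", "c"),
                    fpkm = c(1.0, 0.99, 5))
  expect_equal(filter_expressed(rec, 1), c("a", "c"))
  expect_equal(filter_expressed(rec, 0), c("a", "b", "c"))
  expect_equal(filter_expressed(c(x = 0.5), 1), character(0))
})

test_that("count_fragments applies overlap and strand gates", {
  g <- list(gA = list(gene_id = "gA", contig = "c1", start = 1000,
                      end = 2000, strand = "+",
                      transcripts = list(),
                      exons = data.frame(start = 1000, end = 2000),
                      exon_union_length = 1000),
            gB = list(gene_id = "gB", contig = "c1", start = 1100,
                      end = 1900, strand = "-",
                      transcripts = list(),
                      exons = data.frame(start = 1100, end = 1900),
                      exon_union_length = 800))
  # rf library: mate 2 carries the transcript strand
  rec <- mk_records(c("p1", "p1"), c(1, 2), c("-", "+"),
                    c(1200, 1400), c(1300, 1500))
  cf <- count_fragments(rec, g, strandedness = "rf")
  expect_equal(unname(cf$counts["gA"]), 1)   # + strand pair
  expect_equal(unname(cf$counts["gB"]), 0)   # strand gate
  expect_equal(cf$total_fragments, 1)
  cf2 <- count_fragments(rec, g, strandedness = "fwd")
  expect_equal(unname(cf2$counts["gA"]), 0)  # flipped convention
  expect_equal(unname(cf2$counts["gB"]), 1)
  expect_error(count_fragments(rec, list()), "empty feature")
})

test_that("fragment counts are conserved for disjoint features", {
  b <- fx_small()
  w <- b$world
  rec <- select_informative_alignments(b$genome_alignments[[1]],
                                       mode1_config())
  cf <- count_fragments(rec, w$genes, strandedness = "rf")
  expect_lte(sum(cf$counts), cf$total_fragments)
  expect_gt(sum(cf$counts), 0)
})
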