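simple_gene <- function(id = "g1", exons = data.frame(start = 5000,
                                                      end = 6000),
                        strand = "+", contig = "c1") {
  list(gene_id = id, contig = contig, start = min(exons$start),
       end = max(exons$end), strand = strand,
       transcripts = list(t = exons), exons = exons,
       exon_union_length = sum(exons$end - exons$start))
}

test_that("alignment filter keeps unique concordant pairs only", {
  rec <- mk_records(c("a", "b", "c"), 1, "+", c(0, 0, 0), c(100, 100, 100),
                    mapq = c(255L, 3L, 255L),
                    proper = c(TRUE, TRUE, TRUE),
                    mate_mapped = c(TRUE, TRUE, FALSE))
  kept <- select_informative_alignments(rec, mode1_config())
  expect_equal(kept$read_id, "a")
})

test_that("exon and TE read lists implement overlap rules", {
  g <- simple_gene()
  # pair strand: rf, mate2 on +
  rec <- mk_records(c("p1", "p1", "p2", "p2", "p3", "p3"),
                    c(1, 2, 1, 2, 1, 2),
                    c("-", "+", "-", "+", "-", "+"),
                    bstart = list(5100, 5300, 4000, 4200,
                                  c(5050, 5500), 5700),
                    bend = list(5200, 5400, 4100, 4300,
                                c(5100, 5550), 5800))
  hits <- reads_on_exons(rec, list(g), "rf")
  expect_setequal(unique(hits$read_id), c("p1", "p3"))
  # p3 split read across two exon regions yields one hit per record
  expect_equal(sum(hits$read_id == "p3" & hits$mate == 1), 1)

  tes <- data.frame(copy_id = "t1", family = "roo", contig = "c1",
                    start = 5000, end = 6000, strand = "+", length = 1000,
                    stringsAsFactors = FALSE)
  r50 <- mk_records("q1", 1, "+", 4950, 5050)   # 50 of 100 bp inside
  r49 <- mk_records("q2", 1, "+", 4949, 5049)   # 49 bp inside (100 bp read)
  expect_equal(reads_on_tes(r50, tes, mode1_config())$read_id, "q1")
  expect_equal(nrow(reads_on_tes(r49, tes, mode1_config())), 0)
  # split read: 70 bp block inside the TE of a 100 bp read
  rsplit <- mk_records("q3", 1, "+", bstart = list(c(3000, 5100)),
                       bend = list(c(3030, 5170)))
  expect_equal(reads_on_tes(rsplit, tes, mode1_config())$read_id, "q3")
})

test_that("chimeric pairs are the read-level intersection of the lists", {
  eh <- data.frame(read_id = c("p1", "p2"), mate = c(1, 1),
                   gene_id = "g1", stringsAsFactors = FALSE)
  th <- data.frame(read_id = c("p1", "p3"), mate = c(2, 2),
                   te_copy_id = "t1", stringsAsFactors = FALSE)
  pairs <- find_chimeric_pairs(eh, th)
  expect_equal(pairs$read_id, "p1")
  expect_equal(nrow(find_chimeric_pairs(eh[0, ], th)), 0)
})

test_that("TE-initiated and TE-terminated calls respect the window and
          the no-chimeric-reads rule", {
  g <- simple_gene()
  mk_tes <- function(start, end) data.frame(
    copy_id = "t1", family = "roo", contig = "c1", start = start,
    end = end, strand = "+", length = end - start,
    stringsAsFactors = FALSE)
  pairs <- data.frame(read_id = c("a", "b", "c"), gene_id = "g1",
                      te_copy_id = "t1", stringsAsFactors = FALSE)
  up <- detect_te_initiated(list(g), mk_tes(4200, 4500), pairs,
                            mode1_config())
  expect_equal(up$count, 3)
  expect_equal(up$category, "upstream")
  # no chimeric reads -> discarded
  none <- detect_te_initiated(list(g), mk_tes(4200, 4500), pairs[0, ],
                              mode1_config())
  expect_equal(nrow(none), 0)
  # 3001 bp gap -> outside the window
  far <- detect_te_initiated(list(g), mk_tes(1900, 1999), pairs,
                             mode1_config())
  expect_equal(nrow(far), 0)
  dn <- detect_te_terminated(list(g), mk_tes(6100, 6400), pairs,
                             mode1_config())
  expect_equal(dn$category, "downstream")
  # minus-strand gene: a TE left of the gene is downstream
  gneg <- simple_gene(strand = "-")
  dn2 <- detect_te_terminated(list(gneg), mk_tes(4200, 4500), pairs,
                              mode1_config())
  expect_equal(dn2$count, 3)
})

test_that("embedded TEs require gene-side evidence on the exon portions", {
  g <- simple_gene()                       # exon 5000-6000
  tes <- data.frame(copy_id = "t1", family = "roo", contig = "c1",
                    start = 5400, end = 5600, strand = "+", length = 200,
                    stringsAsFactors = FALSE)
  # p1: mate1 inside TE, mate2 on the flanking exon portion -> counts
  # p2: both mates wholly inside the TE -> excluded
  rec <- mk_records(c("p1", "p1", "p2", "p2"), c(1, 2, 1, 2),
                    c("-", "+", "-", "+"),
                    bstart = c(5450, 5200, 5410, 5500),
                    bend = c(5550, 5300, 5500, 5590))
  eh <- reads_on_exons(rec, list(g), "rf")
  th <- reads_on_tes(rec, tes, mode1_config())
  pairs <- find_chimeric_pairs(eh, th)
  expect_setequal(unique(pairs$read_id), c("p1", "p2"))
  raw <- detect_te_exonized(list(g), tes, pairs, rec, mode1_config())
  expect_equal(raw$category, "embedded")
  expect_equal(raw$count, 1)              # only p1
  # intronic TE: ordinary pair evidence suffices
  g2 <- simple_gene(exons = data.frame(start = c(5000, 7000),
                                       end = c(6000, 8000)))
  tes2 <- data.frame(copy_id = "t2", family = "roo", contig = "c1",
                     start = 6200, end = 6600, strand = "+", length = 400,
                     stringsAsFactors = FALSE)
  rec2 <- mk_records(c("p4", "p4"), c(1, 2), c("-", "+"),
                     bstart = c(6300, 5800), bend = c(6400, 5900))
  pairs2 <- find_chimeric_pairs(reads_on_exons(rec2, list(g2), "rf"),
                                reads_on_tes(rec2, tes2, mode1_config()))
  raw2 <- detect_te_exonized(list(g2), tes2, pairs2, rec2, mode1_config())
  expect_equal(raw2$category, "intronic")
  expect_equal(raw2$count, 1)
})

test_that("replicate consensus implements the presence and mean rules", {
  mk_raw <- function(count) if (is.null(count)) NULL else
    data.frame(gene_id = "g", te_copy_id = "t", category = "upstream",
               count = count, stringsAsFactors = FALSE)
  cfg <- mode1_config()   # cutoff 2, min_replicates 2
  kept <- replicate_consensus(list(mk_raw(3), mk_raw(1)), cfg)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$mean_coverage, 2)
  expect_equal(kept$counts[[1]], c(3, 1))
  dropped1 <- replicate_consensus(list(mk_raw(5), NULL), cfg)
  expect_equal(nrow(dropped1), 0)         # present in one replicate only
  dropped2 <- replicate_consensus(list(mk_raw(1), mk_raw(1), mk_raw(1)),
                                  cfg)
  expect_equal(nrow(dropped2), 0)         # mean 1 < cutoff 2
  expect_error(replicate_consensus(list(mk_raw(3)), cfg),
               "1 replicate")
})

test_that("full genome-guided detection equals the brute-force reference", {
  cfg <- mode1_config(cutoff = 1, min_replicates = 1)
  for (seed in c(101, 202, 303, 404, 505)) {
    inst <- random_mode1_instance(seed)
    got <- chimera_mode1(inst$replicates, inst$genes, inst$tes, cfg,
                         inst$contig_lengths)
    want <- oracle_mode1(inst$replicates, inst$genes, inst$tes, cfg,
                         inst$contig_lengths)
    expect_equal(
      sort(paste(got$gene_id, got$te_copy_id, got$category,
                 got$mean_coverage)),
      sort(paste(want$gene_id, want$te_copy_id, want$category,
                 want$mean_coverage)),
      info = paste("seed", seed))
  }
})

test_that("calls are invariant under reverse-complementing the world", {
  inst <- random_mode1_instance(777)
  cfg <- mode1_config(cutoff = 1, min_replicates = 1)
  fwd <- chimera_mode1(inst$replicates, inst$genes, inst$tes, cfg,
                       inst$contig_lengths)
  mir <- mirror_mode1(inst$genes, inst$tes, inst$replicates[[1]],
                      inst$contig_lengths)
  mir2 <- mirror_mode1(inst$genes, inst$tes, inst$replicates[[2]],
                       inst$contig_lengths)
  rev <- chimera_mode1(list(mir$records, mir2$records), mir$genes,
                       mir$tes, cfg, inst$contig_lengths)
  expect_equal(paste(fwd$gene_id, fwd$te_copy_id, fwd$category,
                     fwd$mean_coverage),
               paste(rev$gene_id, rev$te_copy_id, rev$category,
                     rev$mean_coverage))
})
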