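test_that("fixture generation is deterministic under the seed", {
  cfg <- fixture_config(seed = 21, n_genes = 6,
                        planted = default_plants()[1:2, ])
  w1 <- make_genome_and_annotations(cfg)
  w2 <- make_genome_and_annotations(cfg)
  expect_identical(w1$genome, w2$genome)
  expect_identical(w1$truth, w2$truth)
  r1 <- simulate_fragments(w1, 1)
  r2 <- simulate_fragments(w2, 1)
  expect_identical(r1, r2)
  # different replicate index -> different read stream
  expect_false(identical(r1$seq, simulate_fragments(w1, 2)$seq))
})

test_that("planted geometries match their categories by construction", {
  w <- fx_small()$world
  for (i in seq_len(nrow(w$truth))) {
    tr <- w$truth[i, ]
    te <- w$tes[w$tes$copy_id == tr$te_copy_id, ]
    g <- w$genes[[tr$gene_id]]
    expect_equal(classify_te_vs_gene(te, g, 3000,
                                     w$contig_lengths[[g$contig]]),
                 tr$category, info = tr$te_copy_id)
  }
  # decoy TEs exist and have no chimeric relationship in the truth table
  expect_gt(nrow(w$tes), nrow(w$truth))
})

test_that("background fragment counts follow the coverage formula", {
  w <- fx_small()$world
  rd <- fx_small()$reads[[1]]
  decoys <- names(w$isoforms)[vapply(w$isoforms, function(i)
    i$kind == "decoy_gene", logical(1))]
  iso <- w$isoforms[[decoys[1]]]
  n_bg <- length(unique(rd$read_id[rd$isoform_id == iso$id & rd$mate ==
                                     if (w$config$strandedness == "rf") 2
                                     else 1]))
  expect_equal(n_bg, ceiling(w$config$depth * iso$length /
                               (2 * w$config$read_length)))
})

test_that("artifact pairs are flagged, seeded and absent at rate zero", {
  cfg0 <- fixture_config(seed = 5, n_genes = 6,
                         planted = default_plants()[1:2, ])
  w0 <- make_genome_and_annotations(cfg0)
  expect_equal(sum(simulate_fragments(w0, 1)$artifact), 0)
  cfg <- fixture_config(seed = 5, n_genes = 6,
                        planted = default_plants()[1:2, ],
                        artifact_rate = 0.1)
  w <- make_genome_and_annotations(cfg)
  a1 <- sum(simulate_fragments(w, 1)$artifact) / 2
  expect_gt(a1, 0)
  expect_identical(a1, sum(simulate_fragments(w, 1)$artifact) / 2)
  expect_error(fixture_config(artifact_rate = 1.5), "artifact_rate")
})

test_that("junction-spanning reads receive N-gapped placements", {
  b <- fx_small()
  rec <- b$genome_alignments[[1]]
  nblk <- vapply(rec$bstart, length, integer(1))
  spliced <- rec[nblk > 1, ]
  expect_gt(nrow(spliced), 0)
  # every N gap matches the distance between consecutive genomic blocks
  # of the source isoform
  i <- which(nblk > 1)[1]
  gaps <- rec$bstart[[i]][-1] - rec$bend[[i]][-length(rec$bend[[i]])]
  expect_true(all(gaps > 0))
  # and the ideal aligner refuses foreign reads
  rd <- b$reads[[1]][1, ]
  rd$isoform_id <- "not_an_isoform"
  expect_error(ideal_align_genome(rd, b$world), "unknown isoform")
})

test_that("unsatisfiable simulation settings error out", {
  cfg <- fixture_config(seed = 8, n_genes = 6,
                        planted = default_plants()[1:2, ],
                        fragment_mean = 10000)
  w <- make_genome_and_annotations(cfg)
  expect_error(simulate_fragments(w, 1), "fragment_length > isoform")
})

test_that("mode 2 re-expression excises polymorphic TEs from the reference", {
  b <- fx_small()
  w <- b$world
  m2 <- b$m2
  poly <- w$truth[w$truth$polymorphic, ][1, ]
  te <- w$tes[w$tes$copy_id == poly$te_copy_id, ]
  tx <- m2$transcript_seqs[[paste0("T_", poly$gene_id)]]
  g <- w$genes[[poly$gene_id]]
  expect_equal(nchar(tx), g$exon_union_length - te$length)
  # the TE sequence is present in the TE set but absent from the
  # reference transcript
  te_seq <- m2$te_seqs[[paste0(te$copy_id, "#", te$family)]]
  expect_false(grepl(te_seq, tx, fixed = TRUE))
  # non-polymorphic embedded references keep their TE
  emb <- w$truth[w$truth$category == "embedded" & !w$truth$polymorphic, ]
  if (nrow(emb)) {
    te2 <- w$tes[w$tes$copy_id == emb$te_copy_id[1], ]
    tx2 <- m2$transcript_seqs[[paste0("T_", emb$gene_id[1])]]
    expect_equal(nchar(tx2), w$genes[[emb$gene_id[1]]]$exon_union_length)
  }
})
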