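mk_set_rec <- function(read_id, mate, target, proper = FALSE,
                       space = "te_set", pos = 0, rl = 100) {
  mk_records(read_id, mate, "+", pos, pos + rl, target = target,
             mapq = 255L, proper = proper, mate_mapped = proper,
             space = space)
}

test_that("per-mate ID lists ignore whether the mate aligned", {
  te <- mk_set_rec("a", 1, "roo#roo")
  tx <- rbind(mk_set_rec("b", 1, "T1", space = "transcript_set"),
              mk_set_rec("b", 2, "T1", space = "transcript_set"))
  ids <- build_id_lists(te, tx)
  expect_equal(ids$te_read1, "a")
  expect_equal(ids$te_read2, character(0))
  expect_equal(ids$tx_read1, "b")
  expect_equal(ids$tx_read2, "b")
  empty <- build_id_lists(te[0, ], tx[0, ])
  expect_true(all(lengths(empty) == 0))
})

test_that("mate matching distinguishes singleton and concordant evidence", {
  # r1: mate1 on TE, mate2 on transcript, not concordant -> singleton
  # r2: concordant within T1 and mate1 also inside a TE -> concordant
  # r3: transcript only -> nothing
  te <- rbind(mk_set_rec("r1", 1, "c1#roo"),
              mk_set_rec("r2", 1, "c1#roo"))
  tx <- rbind(mk_set_rec("r1", 2, "T1", space = "transcript_set"),
              mk_set_rec("r2", 1, "T1", proper = TRUE,
                         space = "transcript_set"),
              mk_set_rec("r2", 2, "T1", proper = TRUE,
                         space = "transcript_set"),
              mk_set_rec("r3", 1, "T2", space = "transcript_set"),
              mk_set_rec("r3", 2, "T2", space = "transcript_set"))
  ev <- match_chimeric_mates(build_id_lists(te, tx), te, tx)
  expect_setequal(ev$read_id, c("r1", "r2"))
  expect_equal(ev$mapping_class[ev$read_id == "r1"], "singleton")
  expect_equal(ev$mapping_class[ev$read_id == "r2"], "concordant")
  expect_equal(unique(ev$te_family), "roo")
  expect_false("r3" %in% ev$read_id)
})

test_that("mate matching equals the brute-force cross-product scan", {
  b <- fx_small()
  fams <- b$m2$te_families
  for (r in 1:2) {
    te <- b$te_alignments[[r]]; tx <- b$tx_alignments[[r]]
    ev <- match_chimeric_mates(build_id_lists(te, tx), te, tx, fams)
    got <- sort(unique(paste(ev$read_id, ev$transcript_id, ev$te_family)))
    expect_equal(got, oracle_mode2_match(te, tx, fams))
  }
})

test_that("family resolution keeps the best-covered family with a
          lexicographic tie-break", {
  ev <- data.frame(
    read_id = c(sprintf("a%d", 1:5), sprintf("b%d", 1:2)),
    te_family = c(rep("roo", 5), rep("412", 2)),
    transcript_id = "T1", mapping_class = "singleton",
    stringsAsFactors = FALSE)
  r <- resolve_te_family(ev)
  expect_equal(r$te_family, "roo")
  expect_equal(r$count, 5)
  tie <- data.frame(read_id = c(sprintf("a%d", 1:3), sprintf("b%d", 1:3)),
                    te_family = rep(c("roo", "412"), each = 3),
                    transcript_id = "T1", mapping_class = "singleton",
                    stringsAsFactors = FALSE)
  expect_equal(resolve_te_family(tie)$te_family, "412")
  one <- resolve_te_family(ev[ev$te_family == "roo", ])
  expect_equal(one$count, 5)
})

test_that("assembly scan demands junction-spanning support", {
  rh <- data.frame(target = "asmA", start = 500, end = 700,
                   family = "roo", stringsAsFactors = FALSE)
  alen <- c(asmA = 1500, asmB = 1000)
  cfg <- mode2_config()
  # 3 pairs spanning the junction: one mate in the TE, one outside
  spanning <- do.call(rbind, lapply(1:3, function(i) rbind(
    mk_set_rec(paste0("s", i), 1, "asmA", pos = 550, space = "assembly"),
    mk_set_rec(paste0("s", i), 2, "asmA", pos = 750, space = "assembly"))))
  cand <- assembly_chimera_scan(spanning, rh, alen, cfg)
  expect_equal(cand$assembly_id, "asmA")
  expect_equal(cand$n_junction_pairs, 3)
  # reads only inside the TE region: no candidate
  inside <- do.call(rbind, lapply(1:4, function(i) rbind(
    mk_set_rec(paste0("i", i), 1, "asmA", pos = 510, space = "assembly",
               rl = 80),
    mk_set_rec(paste0("i", i), 2, "asmA", pos = 600, space = "assembly",
               rl = 80))))
  expect_equal(nrow(assembly_chimera_scan(inside, rh, alen, cfg)), 0)
  # repeat-free assembled transcript never becomes a candidate
  expect_equal(nrow(assembly_chimera_scan(spanning, rh[0, ], alen, cfg)), 0)
})

test_that("the 80/80 homology filter enforces both legs", {
  cand <- data.frame(assembly_id = "asmA", family = "roo",
                     n_junction_pairs = 3, stringsAsFactors = FALSE)
  refs <- c(T1 = strrep("ACGTT", 100))          # 500 bp reference
  hits_ok <- data.frame(qseqid = "asmA", sseqid = "T1", pident = 95,
                        length = 450, mismatch = 0, gapopen = 0,
                        qstart = 1, qend = 450, sstart = 1, send = 450,
                        evalue = 0, bitscore = 100)
  r <- homology_filter(cand, NULL, refs, mode2_config(), hits = hits_ok)
  expect_equal(r$transcript_id, "T1")
  hits_lowid <- transform(hits_ok, pident = 79)
  expect_equal(nrow(homology_filter(cand, NULL, refs, mode2_config(),
                                    hits = hits_lowid)), 0)
  hits_short <- transform(hits_ok, length = 375)   # 0.75 of reference
  expect_equal(nrow(homology_filter(cand, NULL, refs, mode2_config(),
                                    hits = hits_short)), 0)
  # internal aligner: a candidate containing the full reference passes
  set.seed(5)
  ref <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  te <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
              collapse = "")
  asm <- c(asmA = paste0(substr(ref, 1, 200), te, substr(ref, 201, 400)))
  r2 <- homology_filter(cand, asm, c(T1 = ref), mode2_config())
  expect_equal(r2$transcript_id, "T1")
  expect_gte(r2$identity, 0.8)
  expect_gte(r2$coverage, 0.8)
})

test_that("evidence classes merge as chimeric_reads/assembly/double", {
  rc <- data.frame(transcript_id = c("T1", "T2"),
                   family = c("roo", "412"),
                   mean_coverage = c(5, 3), replicates_present = 2L,
                   category = "unpositioned", stringsAsFactors = FALSE)
  rc$counts <- I(list(c(5, 5), c(3, 3)))
  ac <- data.frame(transcript_id = c("T1", "T3"),
                   family = c("roo", "hobo"),
                   mean_coverage = c(4, 2), replicates_present = 2L,
                   stringsAsFactors = FALSE)
  ac$counts <- I(list(c(4, 4), c(2, 2)))
  m <- merge_evidence(rc, ac)
  expect_equal(m$evidence[m$transcript_id == "T1"], "double")
  expect_equal(m$evidence[m$transcript_id == "T2"],
               "chimeric_reads_only")
  expect_equal(m$evidence[m$transcript_id == "T3"], "assembly_only")
})

test_that("genome-blind detection recovers polymorphic plants via
          singleton evidence and upgrades them with assemblies", {
  b <- fx_small()
  w <- b$world
  reps <- lapply(1:2, function(r) list(te = b$te_alignments[[r]],
                                       tx = b$tx_alignments[[r]]))
  calls <- chimera_mode2(reps, b$m2$transcripts, mode2_config(),
                         te_families = b$m2$te_families,
                         tx2gene = b$m2$tx2gene)
  # every planted chimera is recovered at transcript level
  expect_setequal(calls$gene_id, w$truth$gene_id)
  # the polymorphic plant's TE is absent from the reference transcript,
  # so its support must be singleton mate pairs
  poly_gene <- w$truth$gene_id[w$truth$polymorphic][1]
  poly_tx <- paste0("T_", poly_gene)
  ev <- match_chimeric_mates(build_id_lists(reps[[1]]$te, reps[[1]]$tx),
                             reps[[1]]$te, reps[[1]]$tx,
                             b$m2$te_families)
  poly_ev <- ev[ev$transcript_id == poly_tx, ]
  expect_gt(nrow(poly_ev), 0)
  expect_true(all(poly_ev$mapping_class == "singleton"))
  # a plant whose TE is inside the reference transcript yields
  # concordant evidence too
  emb_ref <- w$truth$gene_id[w$truth$category %in%
                               c("embedded", "overlapped") &
                               !w$truth$polymorphic]
  if (length(emb_ref)) {
    ce <- ev[ev$transcript_id == paste0("T_", emb_ref[1]), ]
    expect_true(any(ce$mapping_class == "concordant"))
  }
  # with perfect assemblies the evidence upgrades to double
  asm <- list(assemblies = b$m2$assemblies,
              alignments = b$assembly_alignments,
              repeat_hits = b$m2$repeat_hits)
  calls2 <- chimera_mode2(reps, b$m2$transcripts,
                          mode2_config(assembly_enabled = TRUE),
                          te_families = b$m2$te_families, assembly = asm,
                          reference_seqs = b$m2$transcript_seqs,
                          tx2gene = b$m2$tx2gene)
  expect_equal(calls2$evidence[calls2$transcript_id == poly_tx], "double")
  # reported coverage is exactly the mean of the per-replicate counts
  expect_equal(calls$mean_coverage,
               unname(vapply(calls$counts, mean, numeric(1))))
  expect_error(chimera_mode2(reps, b$m2$transcripts,
                             mode2_config(assembly_enabled = TRUE),
                             te_families = b$m2$te_families),
               "no assembled")
})
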