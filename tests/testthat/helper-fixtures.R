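# Shared fixture bundle (built once per test run) and generators for
# randomized micro-instances.

fx_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_fixture_bundle(fixture_config(seed = 11), 2)
    cache
  }
})

# A random Mode 1 micro-instance: random gene/TE geometry plus random
# alignment records (not simulated reads) on one contig.  Stresses the
# detection logic against the base-wise oracle.
random_mode1_instance <- function(seed, n_genes = 8, n_tes = 8,
                                  n_pairs = 100) {
  set.seed(seed)
  L <- 60000
  genes <- list()
  for (i in seq_len(n_genes)) {
    gs <- sample(0:(L - 3000), 1)
    n_ex <- sample(1:3, 1)
    bounds <- sort(gs + sample(seq(0, 2500, by = 50), 2 * n_ex))
    ex <- data.frame(start = bounds[seq(1, 2 * n_ex, 2)],
                     end = bounds[seq(2, 2 * n_ex, 2)])
    ex <- ex[ex$end > ex$start, , drop = FALSE]
    if (!nrow(ex)) ex <- data.frame(start = gs, end = gs + 500)
    mu <- merge_intervals(ex$start, ex$end)
    ex <- data.frame(start = mu[, 1], end = mu[, 2])
    gid <- sprintf("rg%02d", i)
    genes[[gid]] <- list(gene_id = gid, contig = "c1",
                         start = min(ex$start), end = max(ex$end),
                         strand = sample(c("+", "-"), 1),
                         transcripts = list(T1 = ex), exons = ex,
                         exon_union_length = sum(ex$end - ex$start))
  }
  tes <- data.frame(
    copy_id = sprintf("rt%02d", seq_len(n_tes)),
    family = sample(c("roo", "412", "copia"), n_tes, replace = TRUE),
    contig = "c1",
    start = sample(0:(L - 600), n_tes), stringsAsFactors = FALSE)
  tes$end <- tes$start + sample(c(100, 200, 400), n_tes, replace = TRUE)
  tes$strand <- sample(c("+", "-"), n_tes, replace = TRUE)
  tes$length <- tes$end - tes$start
  anchors <- c(vapply(genes, `[[`, numeric(1), "start"), tes$start)
  draw_records <- function(rep_tag) {
    read_id <- character(0); mate <- integer(0); strand <- character(0)
    mapq <- integer(0); prop <- logical(0); mm <- logical(0)
    bstart <- list(); bend <- list()
    for (p in seq_len(n_pairs)) {
      id <- sprintf("%s.p%04d", rep_tag, p)
      base <- if (stats::runif(1) < 0.8)
        sample(anchors, 1) + sample(-500:500, 1) else sample(0:(L - 1000), 1)
      base <- max(0, min(L - 1500, base))
      s1 <- base; s2 <- base + sample(100:400, 1)
      strand1 <- sample(c("+", "-"), 1)
      pp <- stats::runif(1) < 0.9
      mmp <- stats::runif(1) < 0.95
      for (m in 1:2) {
        s <- if (m == 1) s1 else s2
        if (stats::runif(1) < 0.25) {
          gap <- sample(50:300, 1)
          bs <- c(s, s + 60 + gap); be <- c(s + 60, s + 100 + gap)
        } else { bs <- s; be <- s + 100 }
        read_id <- c(read_id, id); mate <- c(mate, m)
        strand <- c(strand, if (m == 1) strand1
                    else if (strand1 == "+") "-" else "+")
        mapq <- c(mapq, sample(c(255L, 255L, 255L, 0L), 1))
        prop <- c(prop, pp); mm <- c(mm, mmp)
        bstart[[length(bstart) + 1L]] <- bs
        bend[[length(bend) + 1L]] <- be
      }
    }
    rec <- data.frame(read_id = read_id, mate = mate, target = "c1",
                      strand = strand, mapq = mapq, proper_pair = prop,
                      mate_mapped = mm, secondary = FALSE,
                      read_length = 100, target_space = "genome",
                      stringsAsFactors = FALSE)
    rec$bstart <- I(bstart); rec$bend <- I(bend)
    rec
  }
  list(genes = genes, tes = tes,
       replicates = list(draw_records("r1"), draw_records("r2")),
       contig_lengths = c(c1 = L))
}

# Mirror a Mode 1 problem: reverse-complement geometry on every contig.
mirror_mode1 <- function(genes, tes, records, contig_lengths) {
  fl <- function(contig, s, e) {
    L <- contig_lengths[[contig]]
    cbind(L - e, L - s)
  }
  genes2 <- lapply(genes, function(g) {
    m <- fl(g$contig, g$exons$start, g$exons$end)
    ex <- data.frame(start = m[, 1], end = m[, 2])
    ex <- ex[order(ex$start), , drop = FALSE]; rownames(ex) <- NULL
    gi <- fl(g$contig, g$start, g$end)
    list(gene_id = g$gene_id, contig = g$contig, start = gi[1, 1],
         end = gi[1, 2], strand = if (g$strand == "+") "-" else "+",
         transcripts = list(T1 = ex), exons = ex,
         exon_union_length = g$exon_union_length)
  })
  tes2 <- tes
  for (i in seq_len(nrow(tes))) {
    mi <- fl(tes$contig[i], tes$start[i], tes$end[i])
    tes2$start[i] <- mi[1, 1]; tes2$end[i] <- mi[1, 2]
    tes2$strand[i] <- if (tes$strand[i] == "+") "-" else "+"
  }
  rec2 <- records
  for (i in seq_len(nrow(records))) {
    mi <- fl(records$target[i], records$bstart[[i]], records$bend[[i]])
    o <- order(mi[, 1])
    rec2$bstart[[i]] <- mi[o, 1]; rec2$bend[[i]] <- mi[o, 2]
    rec2$strand[i] <- if (records$strand[i] == "+") "-" else "+"
  }
  list(genes = genes2, tes = tes2, records = rec2)
}

# minimal record constructor for unit tests
mk_records <- function(read_id, mate, strand, bstart, bend,
                       target = "c1", mapq = 255L, proper = TRUE,
                       mate_mapped = TRUE, read_length = 100,
                       space = "genome") {
  df <- data.frame(read_id = read_id, mate = mate, target = target,
                   strand = strand, mapq = mapq, proper_pair = proper,
                   mate_mapped = mate_mapped, secondary = FALSE,
                   read_length = read_length, target_space = space,
                   stringsAsFactors = FALSE)
  df$bstart <- I(as.list(bstart))
  df$bend <- I(as.list(bend))
  df
}
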