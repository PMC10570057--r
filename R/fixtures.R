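#' Synthetic fixture configuration
#'
#' The generator emits a stated world: a toy genome with genes and TE
#' copies planted in the five positional geometries (upstream within the
#' window, embedded within an exon, overlapping an exon boundary,
#' intronic, downstream), chimeric isoforms realising each plant, decoy
#' genes and TEs with no chimeric relationship, an autonomously expressed
#' TE, and stranded paired-end reads with per-plant junction support.
#' Defaults: 100 bp reads, fragment length 300 +/- 20 (typical short
#' insert mRNA libraries), 20x coverage, rf-stranded (dUTP) orientation,
#' 4 supporting junction pairs per plant per replicate, no artifactual
#' cross-molecule pairs.  Each TE copy carries a few seeded substitutions
#' relative to its family consensus, as real insertions do, which keeps
#' exact-match alignment of its reads unique.
#'
#' @param seed integer seed; identical seed + config gives byte-identical
#'   fixtures.
#' @param n_genes total genes including decoys (>= number of plants).
#' @param n_contigs contigs to spread gene units over.
#' @param planted data.frame with columns \code{category} (upstream,
#'   embedded, overlapped, intronic, downstream), \code{family},
#'   \code{support_depth}, \code{polymorphic} (TE absent from the Mode 2
#'   reference transcript set).
#' @param read_length read length in bp.
#' @param fragment_mean,fragment_sd fragment-length distribution.
#' @param depth fold-coverage for background fragments.
#' @param strandedness \code{"rf"} or \code{"fwd"}.
#' @param artifact_rate proportion of background pairs whose mates are
#'   drawn from two different molecules (jumping-PCR model), in [0, 1).
#' @param te_library named family -> consensus sequence; generated when
#'   NULL.
#' @return list of class \code{fixture_config}.
#' @export
fixture_config <- function(seed = 1, n_genes = 10, n_contigs = 2,
                           planted = default_plants(),
                           read_length = 100, fragment_mean = 300,
                           fragment_sd = 20, depth = 20,
                           strandedness = c("rf", "fwd"),
                           artifact_rate = 0, te_library = NULL) {
  strandedness <- match.arg(strandedness)
  if (artifact_rate < 0 || artifact_rate >= 1)
    stop("fixture_config: artifact_rate must be in [0, 1)")
  stopifnot(read_length >= 50, depth > 0, n_genes >= nrow(planted),
            n_contigs >= 1)
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_contigs = n_contigs, planted = planted,
                 read_length = read_length, fragment_mean = fragment_mean,
                 fragment_sd = fragment_sd, depth = depth,
                 strandedness = strandedness, artifact_rate = artifact_rate,
                 te_library = te_library),
            class = "fixture_config")
}

#' Default plant table: one chimera per positional category
#' @param support_depth junction pairs planted per replicate.
#' @return data.frame usable as \code{planted} in [fixture_config()].
#' @export
default_plants <- function(support_depth = 4) {
  data.frame(
    category = c("upstream", "embedded", "overlapped", "intronic",
                 "downstream"),
    family = c("roo", "blood", "copia", "jockey", "opus"),
    support_depth = support_depth,
    polymorphic = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# vectorised reverse complement (one Biostrings call for many sequences)
revcomp_vec <- function(s) {
  if (!length(s)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

default_te_library <- function(families, len = 300) {
  stats::setNames(vapply(families, function(f) random_dna(len),
                         character(1)), families)
}

# Mutate a family consensus into a distinguishable copy: deterministic
# seeded substitutions at ~4% of positions.
mutate_copy <- function(consensus, n_sub = NULL) {
  s <- strsplit(consensus, "")[[1]]
  if (is.null(n_sub)) n_sub <- max(8L, length(s) %/% 25L)
  pos <- sample(length(s), n_sub)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

# --- unit geometry -------------------------------------------------------
# A unit is one gene (or lone TE) plus its TE plant, laid out locally in
# transcription orientation then optionally mirrored for minus-strand
# genes.  All local coordinates 0-based half-open.
EXON1 <- 800; EXON2 <- 800; INTRON <- 400; TE_LEN <- 300
UNIT_PAD <- 8000   # spacing between units; > window so neighbours stay clear

build_unit <- function(kind, idx, family, te_seq, config) {
  rl <- config$read_length
  u <- list(kind = kind, gene = NULL, te = NULL, iso_blocks = NULL,
            junctions = list(), te_iso = NULL, local_len = 0)
  gs <- 200
  if (kind == "upstream") {
    te <- c(gs, gs + TE_LEN)                       # TE then 150 gap
    g0 <- te[2] + 150
    e1 <- c(g0, g0 + EXON1); e2 <- c(g0 + EXON1 + INTRON,
                                     g0 + EXON1 + INTRON + EXON2)
    u$gene <- list(start = g0, end = e2[2], exons = rbind(e1, e2))
    u$te <- te
    u$iso_blocks <- rbind(c(te[2] - 200, e1[2]), e2)
    u$junctions <- list(c(te[2] - 150, te[2] - 50, g0 + 50, g0 + 150))
  } else if (kind == "downstream") {
    e1 <- c(gs, gs + EXON1); e2 <- c(gs + EXON1 + INTRON,
                                     gs + EXON1 + INTRON + EXON2)
    ge <- e2[2]
    te <- c(ge + 150, ge + 150 + TE_LEN)
    u$gene <- list(start = gs, end = ge, exons = rbind(e1, e2))
    u$te <- te
    u$iso_blocks <- rbind(e1, c(e2[1], te[1] + 200))
    u$junctions <- list(c(ge - 150, ge - 50, te[1] + 50, te[1] + 150))
  } else if (kind == "embedded") {
    e1 <- c(gs, gs + EXON1)
    e2s <- gs + EXON1 + INTRON
    e2 <- c(e2s, e2s + 300 + TE_LEN + 500)          # TE inside, flanks 300/500
    te <- c(e2s + 300, e2s + 300 + TE_LEN)
    u$gene <- list(start = gs, end = e2[2], exons = rbind(e1, e2))
    u$te <- te
    u$iso_blocks <- rbind(e1, e2)
    u$junctions <- list(c(te[1] - 200, te[1] - 100, te[1] + 50, te[1] + 150),
                        c(te[2] - 150, te[2] - 50, te[2] + 100, te[2] + 200))
  } else if (kind == "overlapped") {
    e1 <- c(gs, gs + EXON1)
    te <- c(e1[2] - 150, e1[2] - 150 + TE_LEN)      # 150 bp exonic
    e2s <- gs + EXON1 + INTRON + TE_LEN
    e2 <- c(e2s, e2s + EXON2)
    u$gene <- list(start = gs, end = e2[2], exons = rbind(e1, e2))
    u$te <- te
    u$iso_blocks <- rbind(e1, e2)
    u$junctions <- list(c(e1[2] - 475, e1[2] - 375, e1[2] - 125, e1[2] - 25))
  } else if (kind == "intronic") {
    e1 <- c(gs, gs + EXON1)
    in1 <- c(e1[2], e1[2] + 150 + TE_LEN + 150)
    te <- c(e1[2] + 150, e1[2] + 150 + TE_LEN)
    e2 <- c(in1[2], in1[2] + EXON2)
    u$gene <- list(start = gs, end = e2[2], exons = rbind(e1, e2))
    u$te <- te
    u$iso_blocks <- rbind(e1, te, e2)
    u$junctions <- list(c(e1[2] - 100, e1[2], te[1] + 50, te[1] + 150),
                        c(te[2] - 150, te[2] - 50, e2[1] + 50, e2[1] + 150))
  } else if (kind == "decoy_gene") {
    e1 <- c(gs, gs + EXON1); e2 <- c(gs + EXON1 + INTRON,
                                     gs + EXON1 + INTRON + EXON2)
    u$gene <- list(start = gs, end = e2[2], exons = rbind(e1, e2))
    u$iso_blocks <- rbind(e1, e2)
  } else if (kind == "te_autonomous") {
    te <- c(gs, gs + TE_LEN)
    u$te <- te
    u$iso_blocks <- rbind(te)
  } else if (kind == "decoy_te") {
    u$te <- c(gs, gs + TE_LEN)
  } else stop("build_unit: unknown kind ", kind)
  ends <- c(if (!is.null(u$gene)) u$gene$end, if (!is.null(u$te)) u$te[2],
            if (!is.null(u$iso_blocks)) max(u$iso_blocks))
  u$local_len <- max(ends) + 200
  u
}

flip_unit <- function(u) {
  L <- u$local_len
  fl <- function(iv) cbind(L - iv[, 2, drop = FALSE], L - iv[, 1,
                                                             drop = FALSE])
  sortiv <- function(m) {
    m <- m[order(m[, 1]), , drop = FALSE]; dimnames(m) <- NULL; m
  }
  if (!is.null(u$gene)) {
    ex <- sortiv(fl(u$gene$exons))
    u$gene <- list(start = L - u$gene$end, end = L - u$gene$start,
                   exons = ex)
  }
  if (!is.null(u$te)) u$te <- c(L - u$te[2], L - u$te[1])
  if (!is.null(u$iso_blocks)) u$iso_blocks <- sortiv(fl(u$iso_blocks))
  u$junctions <- lapply(u$junctions, function(j)
    c(L - j[4], L - j[3], L - j[2], L - j[1]))
  u
}

#' Generate the fixture genome, annotations and truth table
#'
#' Deterministic under \code{config$seed}.  Returns the genome, gene
#' models, TE insertions, the isoform set that reads will be simulated
#' from (chimeric isoforms realising each plant, pure isoforms for decoy
#' genes, one autonomously transcribed TE), and the truth table of
#' planted chimeras.
#'
#' @param config a [fixture_config()].
#' @return list with \code{genome} (named contig sequences),
#'   \code{genes}, \code{tes}, \code{isoforms}, \code{truth},
#'   \code{te_library}, \code{contig_lengths}, \code{config}.
#' @export
make_genome_and_annotations <- function(config = fixture_config()) {
  set.seed(config$seed)
  plants <- config$planted
  fams <- unique(c(plants$family, "gypsy"))
  te_library <- config$te_library
  if (is.null(te_library)) te_library <- default_te_library(fams, TE_LEN)
  missing_fam <- setdiff(plants$family, names(te_library))
  if (length(missing_fam))
    stop("make_genome_and_annotations: no library sequence for family ",
         missing_fam[1])
  n_decoy_genes <- config$n_genes - nrow(plants)
  kinds <- c(plants$category, rep("decoy_gene", n_decoy_genes),
             "te_autonomous", "decoy_te")
  unit_fams <- c(plants$family, rep(NA, n_decoy_genes),
                 rep(names(te_library)[1], 2))
  genome <- stats::setNames(rep("", config$n_contigs),
                            paste0("chr", seq_len(config$n_contigs)))
  cursors <- stats::setNames(rep(0, config$n_contigs), names(genome))
  genes <- list(); tes <- list(); isoforms <- list(); truth <- list()
  gene_no <- 0; te_no <- 0
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    fam <- unit_fams[i]
    te_seq <- if (!is.na(fam)) mutate_copy(te_library[[fam]]) else NULL
    u <- build_unit(kind, i, fam, te_seq, config)
    strand <- if (kind %in% c("te_autonomous", "decoy_te")) "+"
              else sample(c("+", "-"), 1)
    if (strand == "-") u <- flip_unit(u)
    contig <- names(genome)[(i - 1L) %% config$n_contigs + 1L]
    off <- cursors[[contig]]
    # unit sequence: random background with the TE copy sequence spliced in
    useq <- random_dna(u$local_len)
    if (!is.null(u$te)) {
      body <- if (strand == "-") revcomp(te_seq) else te_seq
      substr(useq, u$te[1] + 1, u$te[2]) <- body
    }
    genome[[contig]] <- paste0(genome[[contig]], useq,
                               random_dna(UNIT_PAD))
    cursors[[contig]] <- off + u$local_len + UNIT_PAD
    gid <- NULL
    if (!is.null(u$gene)) {
      gene_no <- gene_no + 1
      gid <- sprintf("g%02d", gene_no)
      ex <- u$gene$exons + off
      genes[[gid]] <- list(
        gene_id = gid, contig = contig, start = u$gene$start + off,
        end = u$gene$end + off, strand = strand,
        transcripts = stats::setNames(
          list(data.frame(start = ex[, 1], end = ex[, 2])),
          paste0("T_", gid)),
        exons = data.frame(start = ex[, 1], end = ex[, 2]),
        exon_union_length = sum(ex[, 2] - ex[, 1]))
    }
    cid <- NULL
    if (!is.null(u$te)) {
      te_no <- te_no + 1
      cid <- sprintf("%s.c%02d", fam, te_no)
      tes[[cid]] <- data.frame(
        copy_id = cid, family = fam, contig = contig,
        start = u$te[1] + off, end = u$te[2] + off, strand = strand,
        length = u$te[2] - u$te[1], seq = te_seq, stringsAsFactors = FALSE)
    }
    if (!is.null(u$iso_blocks)) {
      iso_id <- if (!is.null(gid)) paste0("iso_", gid)
                else paste0("iso_te_", cid)
      blocks <- data.frame(start = u$iso_blocks[, 1] + off,
                           end = u$iso_blocks[, 2] + off)
      isoforms[[iso_id]] <- list(
        id = iso_id, gene_id = gid, contig = contig, strand = strand,
        blocks = blocks,
        junctions = lapply(u$junctions, function(j) j + off),
        te_copy = cid, kind = kind)
    }
    if (kind %in% plants$category[i] && i <= nrow(plants)) {
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = gid, te_copy_id = cid, family = fam,
        category = kind, polymorphic = plants$polymorphic[i],
        expected_min_support = plants$support_depth[i],
        stringsAsFactors = FALSE)
    }
  }
  contig_lengths <- vapply(genome, nchar, numeric(1))
  # materialise isoform sequences and isoform-coordinate TE segments
  for (id in names(isoforms)) {
    iso <- isoforms[[id]]
    iso$seq <- isoform_sequence(iso, genome)
    iso$length <- nchar(iso$seq)
    iso$te_iso <- isoform_te_segments(iso, tes)
    iso$.off <- iso_block_offsets(iso)
    isoforms[[id]] <- iso
  }
  list(genome = genome, genes = genes,
       tes = do.call(rbind, c(tes, list(make.row.names = FALSE))),
       isoforms = isoforms,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       te_library = te_library, contig_lengths = contig_lengths,
       config = config)
}

# Sequence of an isoform in transcription orientation.
isoform_sequence <- function(iso, genome) {
  s <- paste(vapply(seq_len(nrow(iso$blocks)), function(i)
    substr(genome[[iso$contig]], iso$blocks$start[i] + 1,
           iso$blocks$end[i]), character(1)), collapse = "")
  if (iso$strand == "-") revcomp(s) else s
}

# Cumulative isoform offsets of the genomic blocks, in transcription order.
iso_block_offsets <- function(iso) {
  if (!is.null(iso$.off)) return(iso$.off)
  bl <- iso$blocks$end - iso$blocks$start
  ord <- if (iso$strand == "-") rev(seq_len(nrow(iso$blocks)))
         else seq_len(nrow(iso$blocks))
  off <- cumsum(c(0, bl[ord]))[seq_along(ord)]
  list(order = ord, offsets = off, lengths = bl)
}

# Map a genomic interval lying within one isoform block to isoform coords.
genome_to_iso <- function(iso, gs, ge) {
  m <- iso_block_offsets(iso)
  for (k in seq_along(m$order)) {
    b <- m$order[k]
    bs <- iso$blocks$start[b]; be <- iso$blocks$end[b]
    if (gs >= bs && ge <= be) {
      if (iso$strand == "+") return(c(m$offsets[k] + (gs - bs),
                                      m$offsets[k] + (ge - bs)))
      return(c(m$offsets[k] + (be - ge), m$offsets[k] + (be - gs)))
    }
  }
  stop("genome_to_iso: interval not contained in one isoform block")
}

# Map an isoform interval [a, b) to sorted genomic blocks.
iso_to_genome <- function(iso, a, b) {
  m <- iso_block_offsets(iso)
  out <- NULL
  for (k in seq_along(m$order)) {
    bidx <- m$order[k]
    o <- m$offsets[k]; len <- m$lengths[bidx]
    lo <- max(a, o); hi <- min(b, o + len)
    if (lo < hi) {
      bs <- iso$blocks$start[bidx]; be <- iso$blocks$end[bidx]
      if (iso$strand == "+") out <- rbind(out, c(bs + (lo - o), bs + (hi - o)))
      else out <- rbind(out, c(be - (hi - o), be - (lo - o)))
    }
  }
  out <- out[order(out[, 1]), , drop = FALSE]
  data.frame(start = out[, 1], end = out[, 2])
}

# Isoform-coordinate segments derived from the planted TE copy.
isoform_te_segments <- function(iso, tes) {
  if (is.null(iso$te_copy)) return(NULL)
  te <- tes[[iso$te_copy]]
  m <- iso_block_offsets(iso)
  segs <- NULL
  for (k in seq_along(m$order)) {
    b <- m$order[k]
    bs <- iso$blocks$start[b]; be <- iso$blocks$end[b]
    lo <- max(bs, te$start); hi <- min(be, te$end)
    if (lo < hi) {
      ivs <- if (iso$strand == "+") c(m$offsets[k] + (lo - bs),
                                      m$offsets[k] + (hi - bs))
             else c(m$offsets[k] + (be - hi), m$offsets[k] + (be - lo))
      segs <- rbind(segs, data.frame(start = ivs[1], end = ivs[2],
                                     family = te$family,
                                     copy_id = te$copy_id,
                                     stringsAsFactors = FALSE))
    }
  }
  segs
}

#' Re-express the fixture world as Mode 2 inputs
#'
#' Builds the reference transcript set (one canonical transcript per
#' gene; for plants flagged polymorphic the TE segment is excised, so the
#' insertion is absent from the reference exactly as a polymorphic TE
#' would be), the TE insertion set (every planted copy, named
#' \code{copy_id#family}), the transcript-to-gene map, and the "perfect
#' assembly" set (the expressed isoform sequences) with its
#' truth-derived repeat annotation.
#'
#' @param world output of [make_genome_and_annotations()].
#' @return list with \code{transcripts} (data.frame \code{feature_id},
#'   \code{length}), \code{transcript_seqs}, \code{te_seqs},
#'   \code{te_families}, \code{tx2gene}, \code{assemblies},
#'   \code{repeat_hits}.
#' @export
mode2_inputs <- function(world) {
  tx_seqs <- character(0); tx2gene <- character(0)
  for (g in world$genes) {
    ex <- g$exons
    tr <- world$truth[world$truth$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(tr) && any(tr$polymorphic)) {
      te <- world$tes[world$tes$copy_id == tr$te_copy_id[1], ]
      m <- subtract_interval(ex$start, ex$end, te$start, te$end)
      ex <- data.frame(start = m[, "start"], end = m[, "end"])
    }
    pseudo <- list(contig = g$contig, strand = g$strand, blocks = ex)
    tid <- paste0("T_", g$gene_id)
    tx_seqs[[tid]] <- isoform_sequence(pseudo, world$genome)
    tx2gene[[tid]] <- g$gene_id
  }
  te_seqs <- stats::setNames(world$tes$seq,
                             paste0(world$tes$copy_id, "#",
                                    world$tes$family))
  te_families <- stats::setNames(world$tes$family, names(te_seqs))
  asm <- stats::setNames(
    vapply(world$isoforms, `[[`, character(1), "seq"),
    paste0("asm_", names(world$isoforms)))
  rh <- do.call(rbind, lapply(world$isoforms, function(iso) {
    if (is.null(iso$te_iso)) return(NULL)
    data.frame(target = paste0("asm_", iso$id), start = iso$te_iso$start,
               end = iso$te_iso$end, family = iso$te_iso$family,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rh))
    rh <- data.frame(target = character(0), start = numeric(0),
                     end = numeric(0), family = character(0))
  rownames(rh) <- NULL
  list(transcripts = data.frame(feature_id = names(tx_seqs),
                                length = unname(nchar(tx_seqs)),
                                stringsAsFactors = FALSE),
       transcript_seqs = tx_seqs, te_seqs = te_seqs,
       te_families = te_families, tx2gene = tx2gene,
       assemblies = asm, repeat_hits = rh)
}

#' Build a complete in-memory fixture bundle
#'
#' World + per-replicate reads + ideal alignments for every target space
#' both modes consume.  Deterministic under the config seed.
#'
#' @param config a [fixture_config()].
#' @param n_replicates RNA-seq replicates to simulate.
#' @param with_assembly also align reads against the perfect assemblies.
#' @return list with the world, \code{reads} (per replicate),
#'   \code{genome_alignments}, \code{tx_alignments},
#'   \code{te_alignments}, \code{assembly_alignments} (each a per
#'   replicate list), and the [mode2_inputs()] under \code{m2}.
#' @export
make_fixture_bundle <- function(config = fixture_config(),
                                n_replicates = 2, with_assembly = TRUE) {
  world <- make_genome_and_annotations(config)
  m2 <- mode2_inputs(world)
  reads <- lapply(seq_len(n_replicates), function(r)
    simulate_fragments(world, r))
  pdicts <- lapply(reads, function(rd) build_pdicts(rd$seq))
  al <- function(space, targets) lapply(seq_len(n_replicates), function(r)
    ideal_align_sets(reads[[r]], targets, space,
                     fragment_mean = config$fragment_mean,
                     pdicts = pdicts[[r]]))
  list(world = world, m2 = m2, reads = reads,
       genome_alignments = lapply(seq_len(n_replicates), function(r)
         ideal_align_genome(reads[[r]], world, pdicts[[r]])),
       tx_alignments = al("transcript_set", m2$transcript_seqs),
       te_alignments = al("te_set", m2$te_seqs),
       assembly_alignments = if (with_assembly)
         al("assembly", m2$assemblies) else NULL)
}
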