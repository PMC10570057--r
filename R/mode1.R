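#' Mode 1 (genome-guided) configuration
#'
#' Defaults encode the published thresholds: unique genome alignments
#' (MAPQ 255, the STAR unique-mapper convention), reads counting as
#' TE-derived when at least 50% of their length lies in a TE copy, a 3 kb
#' upstream/downstream window, an FPKM >= 1 expression gate, and the
#' replicate consensus (present in >= 2 replicates with a mean of >= 2
#' chimeric reads across all replicates).
#'
#' @param min_mapq minimum MAPQ for a unique alignment (default 255).
#' @param te_overlap_fraction minimum fraction of a read's length aligned
#'   within a TE copy for the read to count as TE-derived (default 0.5).
#' @param window upstream/downstream window in bp (default 3000).
#' @param min_fpkm expression gate (default 1).
#' @param cutoff minimum mean chimeric reads across replicates (default 2).
#' @param min_replicates minimum replicates a chimera must appear in
#'   (default 2).
#' @param strandedness \code{"rf"} (dUTP; mate 2 on the transcript
#'   strand) or \code{"fwd"}.
#' @return list of class \code{mode1_config}.
#' @export
mode1_config <- function(min_mapq = 255, te_overlap_fraction = 0.5,
                         window = 3000, min_fpkm = 1, cutoff = 2,
                         min_replicates = 2,
                         strandedness = c("rf", "fwd")) {
  strandedness <- match.arg(strandedness)
  stopifnot(te_overlap_fraction > 0, te_overlap_fraction <= 1,
            cutoff >= 0, min_replicates >= 1, window >= 0, min_fpkm >= 0)
  structure(list(min_mapq = min_mapq,
                 te_overlap_fraction = te_overlap_fraction, window = window,
                 min_fpkm = min_fpkm, cutoff = cutoff,
                 min_replicates = min_replicates, strandedness = strandedness),
            class = "mode1_config")
}

#' Keep only informative genome alignments
#'
#' Retains records that are uniquely aligned (MAPQ >= \code{min_mapq}),
#' properly paired, and whose mate is mapped — the concordant, unique
#' subset that all downstream Mode 1 evidence is drawn from.
#'
#' @param records alignment records (see [parse_sam()]).
#' @param config a [mode1_config()].
#' @return the retained records.
#' @export
select_informative_alignments <- function(records, config = mode1_config()) {
  out <- records[records$mapq >= config$min_mapq & records$proper_pair &
                   records$mate_mapped, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reads aligned to gene exons
#'
#' Emits a hit for every record with at least 1 bp of block overlap with
#' the gene's exon union, provided the pair's inferred transcription
#' strand matches the gene strand.
#'
#' @param records filtered alignment records.
#' @param genes gene-model list (expression-gated).
#' @param strandedness library strandedness.
#' @return data.frame with columns \code{read_id}, \code{mate},
#'   \code{gene_id}, unique rows.
#' @export
reads_on_exons <- function(records, genes, strandedness = c("rf", "fwd")) {
  strandedness <- match.arg(strandedness)
  tstrand <- pair_transcription_strand(records, strandedness)
  out <- list()
  for (g in genes) {
    rc <- records[records$target == g$contig, , drop = FALSE]
    if (!nrow(rc) || !nrow(g$exons)) next
    ov <- record_block_overlap(rc, g$exons)
    hit <- rc[ov > 0, c("read_id", "mate"), drop = FALSE]
    hit <- hit[!is.na(tstrand[hit$read_id]) &
                 tstrand[hit$read_id] == g$strand, , drop = FALSE]
    if (nrow(hit)) {
      hit$gene_id <- g$gene_id
      out[[length(out) + 1L]] <- hit
    }
  }
  collapse_hits(out, "gene_id")
}

#' Reads aligned to TE copies
#'
#' Emits a hit when the total overlap of a record's blocks with the TE
#' interval is at least \code{te_overlap_fraction} of the read length
#' (50% by default).  TE strand plays no role.
#'
#' @param records filtered alignment records.
#' @param tes TE insertion data.frame (post annotation filters).
#' @param config a [mode1_config()].
#' @return data.frame with columns \code{read_id}, \code{mate},
#'   \code{te_copy_id}, unique rows.
#' @export
reads_on_tes <- function(records, tes, config = mode1_config()) {
  out <- list()
  for (i in seq_len(nrow(tes))) {
    rc <- records[records$target == tes$contig[i], , drop = FALSE]
    if (!nrow(rc)) next
    ov <- record_block_overlap(rc, data.frame(start = tes$start[i],
                                              end = tes$end[i]))
    hit <- rc[ov / rc$read_length >= config$te_overlap_fraction,
              c("read_id", "mate"), drop = FALSE]
    if (nrow(hit)) {
      hit$te_copy_id <- tes$copy_id[i]
      out[[length(out) + 1L]] <- hit
    }
  }
  collapse_hits(out, "te_copy_id")
}

collapse_hits <- function(lst, id_col) {
  if (!length(lst))
    return(stats::setNames(data.frame(read_id = character(0),
                                      mate = integer(0), x = character(0),
                                      stringsAsFactors = FALSE),
                           c("read_id", "mate", id_col)))
  df <- do.call(rbind, lst)
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Intersect exon-read and TE-read lists into chimeric pairs
#'
#' A read pair supports a (gene, TE copy) association when one mate (or
#' one split block of a mate) hits the gene's exons and the other mate (or
#' another block) hits the TE.  Each read pair contributes at most once to
#' any (gene, TE copy).
#'
#' @param exon_hits output of [reads_on_exons()].
#' @param te_hits output of [reads_on_tes()].
#' @return data.frame with unique rows \code{read_id}, \code{gene_id},
#'   \code{te_copy_id}.
#' @export
find_chimeric_pairs <- function(exon_hits, te_hits) {
  if (!nrow(exon_hits) || !nrow(te_hits))
    return(data.frame(read_id = character(0), gene_id = character(0),
                      te_copy_id = character(0), stringsAsFactors = FALSE))
  m <- merge(exon_hits[, c("read_id", "gene_id")],
             te_hits[, c("read_id", "te_copy_id")], by = "read_id")
  m <- unique(m[, c("read_id", "gene_id", "te_copy_id")])
  rownames(m) <- NULL
  m
}

# All (gene, TE) classifications on shared contigs, excluding "none".
classify_all_pairs <- function(genes, tes, w, contig_lengths = NULL) {
  out <- list()
  for (g in genes) {
    L <- if (is.null(contig_lengths)) Inf else contig_lengths[[g$contig]]
    on_c <- tes[tes$contig == g$contig, , drop = FALSE]
    for (i in seq_len(nrow(on_c))) {
      cat <- classify_te_vs_gene(on_c[i, ], g, w, L)
      if (cat != "none")
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g$gene_id, te_copy_id = on_c$copy_id[i],
          family = on_c$family[i], category = cat, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), te_copy_id = character(0),
                      family = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

count_pairs_for <- function(chimeric_pairs, gene_id, te_copy_id,
                            valid_reads = NULL) {
  r <- chimeric_pairs$read_id[chimeric_pairs$gene_id == gene_id &
                                chimeric_pairs$te_copy_id == te_copy_id]
  if (!is.null(valid_reads)) r <- intersect(r, valid_reads)
  length(unique(r))
}

#' Detect TE-initiated chimeric transcripts (raw, one replicate)
#'
#' Genes with a TE copy classified \code{upstream} (within the window) and
#' at least one chimeric read pair; pairs with no chimeric reads are
#' discarded.
#'
#' @param genes expression-gated gene models.
#' @param tes filtered TE insertions.
#' @param chimeric_pairs output of [find_chimeric_pairs()].
#' @param config a [mode1_config()].
#' @param contig_lengths optional named contig lengths (window clamping).
#' @return raw call data.frame: \code{gene_id}, \code{te_copy_id},
#'   \code{family}, \code{category}, \code{count}.
#' @export
detect_te_initiated <- function(genes, tes, chimeric_pairs,
                                config = mode1_config(),
                                contig_lengths = NULL) {
  cls <- classify_all_pairs(genes, tes, config$window, contig_lengths)
  detect_for_categories(cls, "upstream", chimeric_pairs)
}

#' Detect TE-terminated chimeric transcripts (raw, one replicate)
#'
#' Mirror of [detect_te_initiated()] on the downstream window.
#'
#' @inheritParams detect_te_initiated
#' @return raw call data.frame.
#' @export
detect_te_terminated <- function(genes, tes, chimeric_pairs,
                                 config = mode1_config(),
                                 contig_lengths = NULL) {
  cls <- classify_all_pairs(genes, tes, config$window, contig_lengths)
  detect_for_categories(cls, "downstream", chimeric_pairs)
}

detect_for_categories <- function(cls, cats, chimeric_pairs,
                                  valid_by_te = NULL) {
  cls <- cls[cls$category %in% cats, , drop = FALSE]
  if (!nrow(cls)) return(cbind(cls, count = numeric(0)))
  cls$count <- vapply(seq_len(nrow(cls)), function(i) {
    vr <- if (is.null(valid_by_te)) NULL
          else valid_by_te[[paste(cls$gene_id[i], cls$te_copy_id[i])]]
    count_pairs_for(chimeric_pairs, cls$gene_id[i], cls$te_copy_id[i], vr)
  }, numeric(1))
  out <- cls[cls$count > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect TE-exonized chimeric transcripts (raw, one replicate)
#'
#' TEs inside the gene produce a call in subcategory \code{embedded},
#' \code{overlapped} or \code{intronic}.  For embedded and overlapped TEs
#' the exon is split at the TE: the gene-side evidence of a pair must
#' overlap at least 1 bp of exon-minus-TE sequence, so pairs lying wholly
#' within the TE never count — autonomous TE expression is not chimeric
#' evidence.  Intronic TEs use the standard chimeric-pair evidence.
#'
#' @inheritParams detect_te_initiated
#' @param records the filtered alignment records of this replicate (used
#'   to re-test gene-side evidence against exon portions).
#' @return raw call data.frame with the subcategory in \code{category}.
#' @export
detect_te_exonized <- function(genes, tes, chimeric_pairs, records,
                               config = mode1_config(),
                               contig_lengths = NULL) {
  cls <- classify_all_pairs(genes, tes, config$window, contig_lengths)
  cls <- cls[cls$category %in% c("embedded", "overlapped", "intronic"), ,
             drop = FALSE]
  if (!nrow(cls)) return(cbind(cls, count = numeric(0)))
  tstrand <- pair_transcription_strand(records, config$strandedness)
  gmap <- stats::setNames(genes, vapply(genes, `[[`, character(1), "gene_id"))
  valid <- list()
  for (i in seq_len(nrow(cls))) {
    if (cls$category[i] == "intronic") next
    g <- gmap[[cls$gene_id[i]]]
    te <- tes[tes$copy_id == cls$te_copy_id[i], , drop = FALSE]
    portions <- subtract_interval(g$exons$start, g$exons$end,
                                  te$start, te$end)
    key <- paste(cls$gene_id[i], cls$te_copy_id[i])
    if (!nrow(portions)) { valid[[key]] <- character(0); next }
    rc <- records[records$target == g$contig, , drop = FALSE]
    ov <- record_block_overlap(rc, data.frame(start = portions[, "start"],
                                              end = portions[, "end"]))
    ids <- unique(rc$read_id[ov > 0])
    ids <- ids[!is.na(tstrand[ids]) & tstrand[ids] == g$strand]
    valid[[key]] <- ids
  }
  detect_for_categories(cls, c("embedded", "overlapped", "intronic"),
                        chimeric_pairs, valid_by_te = valid)
}

#' Replicate-consensus filtering of raw chimera calls
#'
#' A call (keyed by gene, TE copy and category in Mode 1; transcript and
#' family in Mode 2) is kept when it appears with at least one chimeric
#' read in at least \code{min_replicates} replicates AND the arithmetic
#' mean of its counts across ALL supplied replicates (zeros included) is
#' at least \code{cutoff}.
#'
#' @param per_replicate_raw_calls list (one element per replicate) of raw
#'   call data.frames with a \code{count} column.
#' @param config a [mode1_config()] or [mode2_config()].
#' @param key_cols columns identifying a call.
#' @return data.frame of final calls with list-column \code{counts}
#'   (per-replicate), \code{mean_coverage} and \code{replicates_present};
#'   other columns are carried through from the raw calls.
#' @export
replicate_consensus <- function(per_replicate_raw_calls,
                                config = mode1_config(),
                                key_cols = c("gene_id", "te_copy_id",
                                             "category")) {
  nrep <- length(per_replicate_raw_calls)
  if (nrep < config$min_replicates)
    stop("replicate_consensus: ", nrep, " replicate(s) supplied but ",
         config$min_replicates, " required")
  raws <- lapply(per_replicate_raw_calls, function(df) {
    if (is.null(df) || !nrow(df)) return(NULL)
    df$.key <- do.call(paste, c(df[key_cols], sep = "\r"))
    df
  })
  all_raw <- do.call(rbind, raws)
  if (is.null(all_raw) || !nrow(all_raw)) {
    proto <- Filter(function(d) !is.null(d) && is.data.frame(d),
                    per_replicate_raw_calls)
    out <- if (length(proto)) proto[[1]][0, , drop = FALSE] else {
      z <- as.data.frame(stats::setNames(rep(list(character(0)),
                                             length(key_cols)), key_cols),
                         stringsAsFactors = FALSE)
      z$count <- numeric(0); z
    }
    out <- out[, setdiff(names(out), c("count", ".key")), drop = FALSE]
    out$counts <- I(list()); out$mean_coverage <- numeric(0)
    out$replicates_present <- integer(0)
    return(out)
  }
  keys <- unique(all_raw$.key)
  counts <- matrix(0, nrow = length(keys), ncol = nrep,
                   dimnames = list(keys, NULL))
  for (r in seq_len(nrep)) {
    df <- raws[[r]]
    if (!is.null(df)) counts[df$.key, r] <- df$count
  }
  present <- rowSums(counts >= 1)
  meanc <- rowMeans(counts)
  keep <- present >= config$min_replicates & meanc >= config$cutoff
  meta <- all_raw[!duplicated(all_raw$.key), , drop = FALSE]
  meta <- meta[match(keys, meta$.key), , drop = FALSE]
  out <- meta[keep, setdiff(names(meta), c("count", ".key")), drop = FALSE]
  out$counts <- I(unname(lapply(which(keep), function(i)
    unname(counts[i, ]))))
  out$mean_coverage <- unname(meanc[keep])
  out$replicates_present <- unname(as.integer(present[keep]))
  rownames(out) <- NULL
  out
}

#' Run the genome-guided (Mode 1) detection over replicates
#'
#' Per replicate: filter alignments to the unique concordant subset, gate
#' genes at FPKM >= \code{min_fpkm}, build exon-read and TE-read lists,
#' intersect them into chimeric pairs and classify raw calls by TE
#' position; then apply the replicate consensus.
#'
#' @param replicates list of alignment-record data.frames, one per
#'   replicate (genome space).
#' @param genes gene-model list (see [parse_gtf()]).
#' @param tes TE insertion data.frame, already passed through the
#'   annotation filters.
#' @param config a [mode1_config()].
#' @param contig_lengths optional named contig lengths.
#' @return final call data.frame: \code{gene_id}, \code{te_copy_id},
#'   \code{family}, \code{category}, \code{counts} (list), \code{mean_coverage},
#'   \code{replicates_present}, \code{gene_fpkm} (replicate mean),
#'   deterministically sorted.
#' @export
chimera_mode1 <- function(replicates, genes, tes, config = mode1_config(),
                          contig_lengths = NULL) {
  nrep <- length(replicates)
  if (nrep < config$min_replicates)
    stop("chimera_mode1: ", nrep, " replicate(s) supplied but ",
         config$min_replicates, " required")
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  fpkm_mat <- matrix(0, nrow = length(genes), ncol = nrep,
                     dimnames = list(gene_ids, NULL))
  raw <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    rec <- select_informative_alignments(replicates[[r]], config)
    cf <- count_fragments(rec, genes, min_mapq = config$min_mapq,
                          strandedness = config$strandedness)
    lens <- vapply(genes, `[[`, numeric(1), "exon_union_length")
    fp <- if (cf$total_fragments > 0)
      fpkm(cf$counts[gene_ids], pmax(1, lens), cf$total_fragments)
      else stats::setNames(numeric(length(genes)), gene_ids)
    fpkm_mat[, r] <- fp
    expressed <- filter_expressed(fp, config$min_fpkm)
    gexp <- genes[gene_ids %in% expressed]
    exon_hits <- reads_on_exons(rec, gexp, config$strandedness)
    te_hits <- reads_on_tes(rec, tes, config)
    pairs <- find_chimeric_pairs(exon_hits, te_hits)
    raw[[r]] <- rbind(
      detect_te_initiated(gexp, tes, pairs, config, contig_lengths),
      detect_te_terminated(gexp, tes, pairs, config, contig_lengths),
      detect_te_exonized(gexp, tes, pairs, rec, config, contig_lengths))
  }
  final <- replicate_consensus(raw, config,
                               key_cols = c("gene_id", "te_copy_id",
                                            "category"))
  final$gene_fpkm <- rowMeans(fpkm_mat)[final$gene_id]
  o <- order(final$gene_id, final$family, final$category, final$te_copy_id)
  final <- final[o, , drop = FALSE]
  rownames(final) <- NULL
  attr(final, "fpkm") <- fpkm_mat
  final
}

#' Roll Mode 1 per-copy calls up to (gene, family, category)
#'
#' Several copies of one family supporting the same gene are reported
#' per-copy in the main table; this helper additionally aggregates them at
#' the family level, summing mean coverage across copies.
#'
#' @param calls output of [chimera_mode1()].
#' @return data.frame keyed by \code{gene_id}, \code{family},
#'   \code{category} with \code{n_copies} and \code{mean_coverage}.
#' @export
family_rollup <- function(calls) {
  if (!nrow(calls))
    return(data.frame(gene_id = character(0), family = character(0),
                      category = character(0), n_copies = integer(0),
                      mean_coverage = numeric(0), stringsAsFactors = FALSE))
  key <- paste(calls$gene_id, calls$family, calls$category, sep = "\r")
  agg <- rowsum(calls$mean_coverage, key)
  cnt <- table(key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  out <- data.frame(gene_id = parts[, 1], family = parts[, 2],
                    category = parts[, 3],
                    n_copies = as.integer(cnt[rownames(agg)]),
                    mean_coverage = agg[, 1], stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$family, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
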