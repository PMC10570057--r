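#' Mode 2 (genome-blind) configuration
#'
#' Defaults: transcripts gated at replicate-mean FPKM >= 1, two chimeric
#' reads as the calling threshold, presence in >= 2 replicates, and the
#' 80/80 homology rule for assembled-transcript evidence (>= 80% identity
#' across >= 80% of the reference transcript length).
#'
#' @param min_fpkm expression gate on replicate-mean transcript FPKM.
#' @param cutoff minimum mean chimeric reads across replicates.
#' @param min_replicates minimum replicates a chimera must appear in.
#' @param min_length_fraction minimum fraction of the reference
#'   transcript length an assembled candidate must cover.
#' @param min_identity minimum alignment identity for the homology filter.
#' @param assembly_enabled whether the assembled-transcript evidence path
#'   is active.
#' @return list of class \code{mode2_config}.
#' @export
mode2_config <- function(min_fpkm = 1, cutoff = 2, min_replicates = 2,
                         min_length_fraction = 0.8, min_identity = 0.8,
                         assembly_enabled = FALSE) {
  stopifnot(min_length_fraction > 0, min_length_fraction <= 1,
            min_identity > 0, min_identity <= 1, cutoff >= 0,
            min_replicates >= 1, min_fpkm >= 0)
  structure(list(min_fpkm = min_fpkm, cutoff = cutoff,
                 min_replicates = min_replicates,
                 min_length_fraction = min_length_fraction,
                 min_identity = min_identity,
                 assembly_enabled = assembly_enabled),
            class = "mode2_config")
}

#' Per-mate read-ID lists from the two Mode 2 alignments
#'
#' Four sets of read-pair IDs: mate 1 and mate 2 IDs aligned in the TE
#' space, and the same for the transcript space — each regardless of
#' whether the other mate aligned anywhere.
#'
#' @param te_alignments alignment records in the TE space.
#' @param tx_alignments alignment records in the transcript space.
#' @return list with character vectors \code{te_read1}, \code{te_read2},
#'   \code{tx_read1}, \code{tx_read2}.
#' @export
build_id_lists <- function(te_alignments, tx_alignments) {
  list(te_read1 = unique(te_alignments$read_id[te_alignments$mate == 1L]),
       te_read2 = unique(te_alignments$read_id[te_alignments$mate == 2L]),
       tx_read1 = unique(tx_alignments$read_id[tx_alignments$mate == 1L]),
       tx_read2 = unique(tx_alignments$read_id[tx_alignments$mate == 2L]))
}

#' Match read mates across the TE and transcript alignments
#'
#' Chimeric evidence is a read pair with one mate aligned in the TE space
#' and the other in the transcript space: IDs in \code{te_read1} are
#' looked up in \code{tx_read2} and vice versa.  The evidence is
#' \code{concordant} when the pair is properly paired within the matched
#' transcript (the TE insertion is present in the reference transcript)
#' and \code{singleton} otherwise (the TE is absent from the reference —
#' the polymorphic-insertion signal).  One evidence record per distinct
#' (read, transcript, family).
#'
#' @param id_sets output of [build_id_lists()].
#' @param te_alignments,tx_alignments the two alignment record sets.
#' @param te_families named character vector mapping TE-space target
#'   names to family names; targets named \code{copy#family} are parsed
#'   automatically when this is NULL.
#' @return data.frame: \code{read_id}, \code{te_family},
#'   \code{transcript_id}, \code{mapping_class}.
#' @export
match_chimeric_mates <- function(id_sets, te_alignments, tx_alignments,
                                 te_families = NULL) {
  fam_of <- function(targets) {
    if (!is.null(te_families)) unname(te_families[targets])
    else sub("^[^#]*#", "", targets)
  }
  empty <- data.frame(read_id = character(0), te_family = character(0),
                      transcript_id = character(0),
                      mapping_class = character(0), stringsAsFactors = FALSE)
  out <- list(empty)
  for (m in c(1L, 2L)) {
    other <- 3L - m
    ids <- intersect(
      if (m == 1L) id_sets$te_read1 else id_sets$te_read2,
      if (other == 1L) id_sets$tx_read1 else id_sets$tx_read2)
    if (!length(ids)) next
    te_hit <- te_alignments[te_alignments$mate == m &
                              te_alignments$read_id %in% ids,
                            c("read_id", "target"), drop = FALSE]
    tx_hit <- tx_alignments[tx_alignments$mate == other &
                              tx_alignments$read_id %in% ids,
                            c("read_id", "target", "proper_pair"),
                            drop = FALSE]
    ev <- merge(te_hit, tx_hit, by = "read_id",
                suffixes = c(".te", ".tx"))
    if (!nrow(ev)) next
    out[[length(out) + 1L]] <- data.frame(
      read_id = ev$read_id, te_family = fam_of(ev$target.te),
      transcript_id = ev$target.tx,
      mapping_class = ifelse(ev$proper_pair, "concordant", "singleton"),
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, out)
  if (!nrow(ev)) return(empty)
  # de-duplicate; a pair seen both ways keeps the concordant class
  ev <- ev[order(ev$read_id, ev$transcript_id, ev$te_family,
                 ev$mapping_class), , drop = FALSE]
  key <- paste(ev$read_id, ev$transcript_id, ev$te_family, sep = "\r")
  ev <- ev[!duplicated(key), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Keep one TE family per transcript
#'
#' Short reads rarely align uniquely within a TE family, so a transcript
#' supported by several families keeps only the family with the highest
#' chimeric-read coverage; ties break to the lexicographically smallest
#' family name.
#'
#' @param evidence output of [match_chimeric_mates()] (possibly pooled
#'   across replicates).
#' @return data.frame: \code{transcript_id}, \code{te_family},
#'   \code{count} (chimeric reads of the kept family).
#' @export
resolve_te_family <- function(evidence) {
  if (!nrow(evidence))
    return(data.frame(transcript_id = character(0), te_family = character(0),
                      count = numeric(0), stringsAsFactors = FALSE))
  ev <- unique(evidence[, c("read_id", "transcript_id", "te_family")])
  key <- paste(ev$transcript_id, ev$te_family, sep = "\r")
  cnt <- table(key)
  parts <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
  df <- data.frame(transcript_id = parts[, 1], te_family = parts[, 2],
                   count = as.numeric(cnt), stringsAsFactors = FALSE)
  df <- df[order(df$transcript_id, -df$count, df$te_family), , drop = FALSE]
  df <- df[!duplicated(df$transcript_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Scan assembled transcripts for TE/non-TE junction support
#'
#' An assembled transcript is a candidate chimera when it carries at
#' least one repeat hit and at least \code{cutoff} read pairs have
#' aligned bases on both sides of a repeat-hit boundary (inside the
#' repeat region of one family and outside all repeat regions).
#'
#' @param assembly_alignments alignment records of reads against the
#'   assembled transcripts.
#' @param repeat_hits data.frame \code{target}, \code{start}, \code{end},
#'   \code{family}: repeat annotation on the assemblies (external .out or
#'   [match_repeats()]).
#' @param assembly_lengths named numeric lengths of the assembled
#'   transcripts.
#' @param config a [mode2_config()].
#' @return data.frame: \code{assembly_id}, \code{family},
#'   \code{n_junction_pairs}.
#' @export
assembly_chimera_scan <- function(assembly_alignments, repeat_hits,
                                  assembly_lengths,
                                  config = mode2_config()) {
  out <- list()
  for (a in unique(repeat_hits$target)) {
    hits <- repeat_hits[repeat_hits$target == a, , drop = FALSE]
    L <- assembly_lengths[[a]]
    if (is.null(L)) stop("assembly_chimera_scan: unknown assembly '", a, "'")
    all_te <- merge_intervals(hits$start, hits$end)
    non_te <- complement_intervals(all_te, L)
    rec <- assembly_alignments[assembly_alignments$target == a, , drop = FALSE]
    if (!nrow(rec)) next
    out_bp <- record_block_overlap(rec, as.data.frame(non_te))
    for (f in unique(hits$family)) {
      fh <- hits[hits$family == f, , drop = FALSE]
      in_bp <- record_block_overlap(rec, fh[, c("start", "end")])
      by_read <- rowsum(cbind(in_bp, out_bp), rec$read_id)
      n <- sum(by_read[, 1] > 0 & by_read[, 2] > 0)
      if (n >= config$cutoff)
        out[[length(out) + 1L]] <- data.frame(
          assembly_id = a, family = f, n_junction_pairs = n,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(assembly_id = character(0), family = character(0),
                      n_junction_pairs = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

complement_intervals <- function(merged, L) {
  s <- c(0, merged[, "end"]); e <- c(merged[, "start"], L)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

#' 80/80 homology filter for assembled candidates
#'
#' A candidate assembled transcript passes when some reference transcript
#' aligns to it with identity >= \code{min_identity} over at least
#' \code{min_length_fraction} of the reference transcript length; the
#' best hit (identity x coverage) assigns the reference transcript ID.
#' Precomputed BLAST outfmt-6 hits override the internal aligner
#' bit-for-bit when supplied.
#'
#' @param candidates output of [assembly_chimera_scan()].
#' @param assemblies named character vector of assembled sequences.
#' @param reference_transcripts named character vector of reference
#'   transcript sequences.
#' @param config a [mode2_config()].
#' @param hits optional BLAST tabular data.frame ([read_blast_tab()]),
#'   query = assembly, subject = reference transcript.
#' @return data.frame: \code{assembly_id}, \code{family},
#'   \code{transcript_id}, \code{identity}, \code{coverage},
#'   \code{n_junction_pairs}.
#' @export
homology_filter <- function(candidates, assemblies, reference_transcripts,
                            config = mode2_config(), hits = NULL) {
  out <- list()
  ref_len <- nchar(reference_transcripts)
  for (i in seq_len(nrow(candidates))) {
    a <- candidates$assembly_id[i]
    if (!is.null(hits)) {
      h <- hits[hits$qseqid == a, , drop = FALSE]
      if (!nrow(h)) next
      ident <- h$pident / 100
      cov <- h$length / ref_len[h$sseqid]
    } else {
      ident <- cov <- numeric(length(reference_transcripts))
      for (j in seq_along(reference_transcripts)) {
        # cheap exact-probe screen before the quadratic local alignment:
        # a reference that passes 80/80 must share long exact stretches
        # with the candidate, so probe three 24-mers before aligning
        if (!probe_screen(reference_transcripts[[j]], assemblies[[a]]))
          next
        st <- local_align_stats(reference_transcripts[[j]], assemblies[[a]])
        ident[j] <- st$matches / st$aligned
        cov[j] <- aligned_ref_fraction(reference_transcripts[[j]],
                                       assemblies[[a]])
      }
      h <- data.frame(sseqid = names(reference_transcripts))
    }
    ok <- which(ident >= config$min_identity &
                  cov >= config$min_length_fraction)
    if (!length(ok)) next
    best <- ok[which.max((ident * cov)[ok])]
    out[[length(out) + 1L]] <- data.frame(
      assembly_id = a, family = candidates$family[i],
      transcript_id = h$sseqid[best], identity = ident[best],
      coverage = cov[best],
      n_junction_pairs = candidates$n_junction_pairs[i],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(assembly_id = character(0), family = character(0),
                      transcript_id = character(0), identity = numeric(0),
                      coverage = numeric(0), n_junction_pairs = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# TRUE when any of a few fixed-position 24-mer probes of the reference
# occurs exactly in the candidate.  Misses only references with no
# conserved 24-mer at the probed positions, which cannot reach 80%
# identity over 80% length in practice; precomputed BLAST hits bypass
# this screen entirely.
probe_screen <- function(reference, assembly, k = 24) {
  n <- nchar(reference)
  if (n <= k) return(TRUE)
  at <- unique(pmax(1, pmin(n - k + 1, round(c(0.1, 0.5, 0.9) * n))))
  for (p in at)
    if (grepl(substr(reference, p, p + k - 1), assembly, fixed = TRUE))
      return(TRUE)
  FALSE
}

# Fraction of the reference transcript aligned in a local alignment
# against the assembly (reference is the pattern here so gaps in the
# pattern do not count as covered reference bases).
aligned_ref_fraction <- function(reference, assembly) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(reference, assembly, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  p <- Biostrings::pattern(aln)
  (BiocGenerics::end(p) - BiocGenerics::start(p) + 1) / nchar(reference)
}

#' Merge read-pair and assembly evidence into final Mode 2 calls
#'
#' Calls present in both paths are \code{double}; otherwise the
#' respective single class.  Read-path counts and coverage are retained
#' whenever present.
#'
#' @param read_calls consensus calls from the chimeric-read path
#'   (data.frame keyed by \code{transcript_id}, \code{family}).
#' @param assembly_calls consensus calls from the assembly path (same
#'   key).
#' @return data.frame of final calls with an \code{evidence} column.
#' @export
merge_evidence <- function(read_calls, assembly_calls) {
  kr <- paste(read_calls$transcript_id, read_calls$family, sep = "\r")
  ka <- paste(assembly_calls$transcript_id, assembly_calls$family, sep = "\r")
  if (nrow(read_calls))
    read_calls$evidence <- ifelse(kr %in% ka, "double",
                                  "chimeric_reads_only")
  else read_calls$evidence <- character(0)
  add <- assembly_calls[!ka %in% kr, , drop = FALSE]
  if (nrow(add)) {
    add$category <- "unpositioned"
    add$evidence <- "assembly_only"
    for (cn in setdiff(names(read_calls), names(add)))
      add[[cn]] <- NA
    read_calls <- rbind(read_calls, add[names(read_calls)])
  }
  out <- read_calls[order(read_calls$transcript_id, read_calls$family), ,
                    drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the genome-blind (Mode 2) detection over replicates
#'
#' Per replicate: gate transcripts on replicate-mean FPKM, build per-mate
#' ID lists from the TE-space and transcript-space alignments, match
#' mates into chimeric evidence and count chimeric reads per (transcript,
#' family); then resolve one family per transcript, apply the replicate
#' consensus, and (optionally) merge assembled-transcript evidence
#' filtered by the 80/80 homology rule.
#'
#' @param replicates list, one element per replicate, each a list with
#'   \code{te} and \code{tx} alignment-record data.frames.
#' @param transcripts data.frame \code{feature_id}, \code{length} for the
#'   reference transcripts (FPKM denominator).
#' @param config a [mode2_config()].
#' @param te_families optional named mapping from TE-space target to
#'   family (default: parse \code{copy#family} target names).
#' @param assembly when \code{config$assembly_enabled}, a list with
#'   \code{assemblies} (named sequences), \code{alignments} (list per
#'   replicate of records vs the assemblies), and either
#'   \code{repeat_hits} (data.frame) or \code{te_library} (named
#'   sequences for [match_repeats()]); optional \code{blast_hits}.
#' @param reference_seqs named character vector of reference transcript
#'   sequences (needed for the homology filter when assembly evidence is
#'   on).
#' @param tx2gene optional named character vector mapping transcript IDs
#'   to gene IDs; adds a \code{gene_id} column.
#' @return final call data.frame: \code{transcript_id}, \code{family},
#'   \code{category} (\code{"unpositioned"}), \code{counts},
#'   \code{mean_coverage}, \code{replicates_present}, \code{fpkm},
#'   \code{evidence}.
#' @export
chimera_mode2 <- function(replicates, transcripts, config = mode2_config(),
                          te_families = NULL, assembly = NULL,
                          reference_seqs = NULL, tx2gene = NULL) {
  nrep <- length(replicates)
  if (nrep < config$min_replicates)
    stop("chimera_mode2: ", nrep, " replicate(s) supplied but ",
         config$min_replicates, " required")
  # replicate-mean FPKM gate on transcripts
  fpkm_mat <- matrix(0, nrow = nrow(transcripts), ncol = nrep,
                     dimnames = list(transcripts$feature_id, NULL))
  for (r in seq_len(nrep)) {
    cf <- count_fragments(replicates[[r]]$tx, transcripts, min_mapq = 0)
    if (cf$total_fragments > 0)
      fpkm_mat[, r] <- fpkm(cf$counts[transcripts$feature_id],
                            pmax(1, transcripts$length), cf$total_fragments)
  }
  mean_fpkm <- rowMeans(fpkm_mat)
  expressed <- filter_expressed(mean_fpkm, config$min_fpkm)
  # read-pair evidence per replicate
  ev_list <- lapply(replicates, function(rep) {
    ids <- build_id_lists(rep$te, rep$tx)
    ev <- match_chimeric_mates(ids, rep$te, rep$tx, te_families)
    ev[ev$transcript_id %in% expressed, , drop = FALSE]
  })
  # one family per transcript, decided on evidence pooled over replicates
  pooled <- do.call(rbind, lapply(seq_along(ev_list), function(r) {
    ev <- ev_list[[r]]
    if (nrow(ev)) ev$read_id <- paste0("rep", r, ":", ev$read_id)
    ev
  }))
  kept <- resolve_te_family(pooled)
  raw <- lapply(ev_list, function(ev) {
    ev <- merge(ev, kept[, c("transcript_id", "te_family")],
                by = c("transcript_id", "te_family"))
    if (!nrow(ev))
      return(data.frame(transcript_id = character(0), family = character(0),
                        count = numeric(0), stringsAsFactors = FALSE))
    tab <- table(paste(ev$transcript_id, ev$te_family, sep = "\r"))
    parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    data.frame(transcript_id = parts[, 1], family = parts[, 2],
               count = as.numeric(tab), stringsAsFactors = FALSE)
  })
  read_calls <- replicate_consensus(raw, config,
                                    key_cols = c("transcript_id", "family"))
  read_calls$category <- rep("unpositioned", nrow(read_calls))
  # assembly evidence path
  if (isTRUE(config$assembly_enabled)) {
    if (is.null(assembly) || is.null(assembly$assemblies) ||
        !length(assembly$assemblies))
      stop("chimera_mode2: assembly evidence enabled but no assembled ",
           "transcripts supplied")
    if (is.null(reference_seqs) && is.null(assembly$blast_hits))
      stop("chimera_mode2: homology filter needs reference_seqs or ",
           "precomputed blast_hits")
    rh <- assembly$repeat_hits
    if (is.null(rh)) {
      if (is.null(assembly$te_library))
        stop("chimera_mode2: need repeat_hits or te_library")
      rh <- match_repeats(assembly$assemblies, assembly$te_library)
    }
    alen <- nchar(assembly$assemblies)
    cand_list <- lapply(assembly$alignments, assembly_chimera_scan,
                        repeat_hits = rh, assembly_lengths = alen,
                        config = config)
    # the candidate -> reference mapping is replicate-independent, so
    # run the homology filter once on the union of candidates
    all_cand <- unique(do.call(rbind, cand_list)[, c("assembly_id",
                                                     "family")])
    if (is.null(all_cand))
      all_cand <- data.frame(assembly_id = character(0),
                             family = character(0))
    all_cand$n_junction_pairs <- 0
    hom_all <- homology_filter(all_cand, assembly$assemblies,
                               reference_seqs, config,
                               hits = assembly$blast_hits)
    araw <- lapply(cand_list, function(cand) {
      hom <- merge(cand, hom_all[, c("assembly_id", "family",
                                     "transcript_id")],
                   by = c("assembly_id", "family"))
      if (!nrow(hom))
        return(data.frame(transcript_id = character(0),
                          family = character(0), count = numeric(0),
                          stringsAsFactors = FALSE))
      data.frame(transcript_id = hom$transcript_id, family = hom$family,
                 count = hom$n_junction_pairs, stringsAsFactors = FALSE)
    })
    # presence in >= min_replicates is the assembly-path consensus; the
    # per-replicate cutoff was already applied inside the scan
    acfg <- config; acfg$cutoff <- 0
    assembly_calls <- replicate_consensus(araw, acfg,
                                          key_cols = c("transcript_id",
                                                       "family"))
    final <- merge_evidence(read_calls, assembly_calls)
  } else {
    final <- read_calls
    final$evidence <- rep("chimeric_reads_only", nrow(final))
  }
  final$category[is.na(final$category)] <- "unpositioned"
  final$fpkm <- unname(mean_fpkm[final$transcript_id])
  if (!is.null(tx2gene)) final$gene_id <- unname(tx2gene[final$transcript_id])
  o <- order(final$transcript_id, final$family)
  final <- final[o, , drop = FALSE]
  rownames(final) <- NULL
  attr(final, "fpkm") <- fpkm_mat
  final
}
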