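#' @title Expression quantification and the FPKM gate
#' @description
#' Expression is quantified from uniquely aligned, properly paired
#' fragments and converted to FPKM with the closed form
#' \code{count * 1e9 / (length * total)}.  This replaces probabilistic
#' multi-mapper allocation deliberately: the value is only compared with
#' the "expressed" gate (FPKM >= 1 by default), where a deterministic
#' unique-fragment estimate is sufficient and exactly testable.
#' @name expression-module
NULL

# Total overlap (bp) of each record's blocks with a set of intervals
# (data.frame start/end, assumed disjoint).  Flattened and vectorised:
# one pass per interval over all blocks of all records.
record_block_overlap <- function(records, ivs) {
  n <- nrow(records)
  if (!n || !nrow(ivs)) return(numeric(n))
  lens <- lengths(records$bstart)
  row <- rep.int(seq_len(n), lens)
  bs <- unlist(records$bstart, use.names = FALSE)
  be <- unlist(records$bend, use.names = FALSE)
  tot <- numeric(length(bs))
  for (k in seq_len(nrow(ivs)))
    tot <- tot + overlap_bp(bs, be, ivs$start[k], ivs$end[k])
  out <- numeric(n)
  agg <- rowsum(tot, row)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Transcription strand of each read pair under the library convention:
# rf-stranded libraries read mate 2 on the transcript strand, fwd-stranded
# libraries mate 1.  Returns a named character vector keyed by read_id.
pair_transcription_strand <- function(records, strandedness = c("rf", "fwd")) {
  strandedness <- match.arg(strandedness)
  carrier <- if (strandedness == "rf") 2L else 1L
  rec <- records[records$mate == carrier & !records$secondary, , drop = FALSE]
  st <- rec$strand[!duplicated(rec$read_id)]
  names(st) <- rec$read_id[!duplicated(rec$read_id)]
  st
}

#' Count fragments per feature
#'
#' A fragment (read pair) is counted once for a feature when it passes the
#' alignment filter (MAPQ >= \code{min_mapq}, properly paired, mate
#' mapped), a block of either mate overlaps the feature's exon union
#' (genome space) or the record's target equals the feature (transcript
#' space), and the pair's inferred transcription strand matches the
#' feature strand.
#'
#' @param alignments alignment records from one replicate and one target
#'   space (see [parse_sam()]).
#' @param features a gene-model list (genome space) or a data.frame with
#'   columns \code{feature_id}, \code{length} and optionally \code{strand}
#'   (transcript space; strand defaults to \code{"+"} in transcript
#'   coordinates).
#' @param min_mapq minimum MAPQ (255 for the genome-space unique filter;
#'   use 0 for transcript-space alignments).
#' @param strandedness \code{"rf"} or \code{"fwd"}.
#' @return list with \code{counts} (named numeric per feature) and
#'   \code{total_fragments} (all pairs passing the alignment filter).
#' @export
count_fragments <- function(alignments, features, min_mapq = 255,
                            strandedness = c("rf", "fwd")) {
  strandedness <- match.arg(strandedness)
  genome_space <- !is.data.frame(features)
  if (genome_space && !length(features))
    stop("count_fragments: empty feature set")
  if (!genome_space && !nrow(features))
    stop("count_fragments: empty feature set")
  rec <- alignments[alignments$mapq >= min_mapq & alignments$proper_pair &
                      alignments$mate_mapped, , drop = FALSE]
  total <- length(unique(rec$read_id))
  tstrand <- pair_transcription_strand(rec, strandedness)
  if (genome_space) {
    ids <- vapply(features, `[[`, character(1), "gene_id")
    counts <- stats::setNames(numeric(length(features)), ids)
    for (g in features) {
      on_contig <- rec[vapply(rec$bstart, length, integer(1)) > 0 &
                         rec$target == g$contig, , drop = FALSE]
      if (!nrow(on_contig)) next
      ov <- record_block_overlap(on_contig, g$exons)
      hit_ids <- unique(on_contig$read_id[ov > 0])
      hit_ids <- hit_ids[tstrand[hit_ids] == g$strand]
      counts[g$gene_id] <- length(hit_ids[!is.na(hit_ids)])
    }
  } else {
    fstrand <- if ("strand" %in% names(features)) features$strand
               else rep("+", nrow(features))
    counts <- stats::setNames(numeric(nrow(features)), features$feature_id)
    for (i in seq_len(nrow(features))) {
      fid <- features$feature_id[i]
      on_t <- rec[rec$target == fid, , drop = FALSE]
      if (!nrow(on_t)) next
      ts <- pair_transcription_strand(on_t, strandedness)
      counts[fid] <- sum(ts == fstrand[i], na.rm = TRUE)
    }
  }
  list(counts = counts, total_fragments = total)
}

#' Fragments per kilobase per million mapped fragments
#'
#' \code{fpkm = count * 1e9 / (length_bp * total_fragments)}.
#'
#' @param fragment_count fragments assigned to the feature (vectorised).
#' @param length_bp exon-union or transcript length in bp, >= 1.
#' @param total_fragments total mapped fragments in the replicate, >= 1.
#' @return numeric FPKM values.
#' @export
fpkm <- function(fragment_count, length_bp, total_fragments) {
  if (any(total_fragments == 0))
    stop("fpkm: no mapped fragments")
  stopifnot(all(length_bp >= 1))
  # double arithmetic throughout: integer length * total overflows 2^31
  out <- as.numeric(fragment_count) * 1e9 /
    (as.numeric(length_bp) * as.numeric(total_fragments))
  names(out) <- names(fragment_count)
  out
}

#' Apply the expression gate
#'
#' Keeps features whose FPKM is greater than or equal to \code{min_fpkm}
#' (FPKM >= 1 counts as expressed by default; the boundary is inclusive).
#'
#' @param records a data.frame with columns \code{feature_id} and
#'   \code{fpkm}, or a named numeric vector of FPKM values.
#' @param min_fpkm gate value, >= 0.
#' @return character vector of expressed feature ids.
#' @export
filter_expressed <- function(records, min_fpkm = 1) {
  stopifnot(min_fpkm >= 0)
  if (is.data.frame(records)) {
    records$feature_id[records$fpkm >= min_fpkm]
  } else {
    names(records)[records >= min_fpkm]
  }
}
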