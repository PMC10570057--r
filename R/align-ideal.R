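#' Ideal spliced alignment of simulated reads to the fixture genome
#'
#' Places every read at its true locus (reconstructed from the source
#' isoform, with N-gapped blocks across introns) plus at every other
#' exact-match locus of the full read sequence on either strand.  Reads
#' with a single placement get MAPQ 255, multi-placed reads MAPQ 0 with
#' all placements reported (extras as secondary records) — mirroring the
#' unique/multi-mapper MAPQ convention the genome-guided filter expects.
#' A pair is proper when both mates place uniquely on one contig in FR
#' orientation within 10 fragment lengths.
#'
#' @param reads output of [simulate_fragments()].
#' @param world output of [make_genome_and_annotations()].
#' @param pdicts optional prebuilt read dictionaries shared across
#'   target spaces.
#' @return alignment records (schema of [parse_sam()]) plus a
#'   \code{seq_fwd} column carrying the reference-forward read sequence
#'   for SAM export.
#' @export
ideal_align_genome <- function(reads, world, pdicts = NULL) {
  config <- world$config
  rl <- config$read_length
  iso <- world$isoforms
  bad <- setdiff(unique(reads$isoform_id), names(iso))
  if (length(bad))
    stop("ideal_align_genome: read not generated from this genome ",
         "(unknown isoform ", bad[1], ")")
  n <- nrow(reads)
  # truth placements
  t_contig <- character(n); t_strand <- character(n)
  t_blocks <- vector("list", n)
  for (i in seq_len(n)) {
    is_ <- iso[[reads$isoform_id[i]]]
    blk <- iso_to_genome(is_, reads$iso_start[i], reads$iso_end[i])
    t_contig[i] <- is_$contig
    t_strand[i] <- if (reads$sense[i] == (is_$strand == "+")) "+" else "-"
    t_blocks[[i]] <- blk
  }
  # exhaustive exact-match scan for extra placements
  extra <- exact_match_placements(reads$seq, world$genome, rl, pdicts)
  placements <- vector("list", n)
  for (i in seq_len(n)) {
    tb <- t_blocks[[i]]
    pc <- t_contig[i]; ps <- tb$start[1]; po <- t_strand[i]
    pb <- nrow(tb)
    ex <- extra[[i]]
    if (!is.null(ex)) {
      pc <- c(pc, ex$contig); ps <- c(ps, ex$start)
      po <- c(po, ex$strand); pb <- c(pb, rep(1L, length(ex$start)))
    }
    keep <- !duplicated(paste(pc, ps, po, pb))
    placements[[i]] <- list(contig = pc[keep], start = ps[keep],
                            strand = po[keep], nblk = pb[keep])
  }
  nplace <- vapply(placements, function(p) length(p$start), integer(1))
  mapq <- ifelse(nplace == 1L, 255L, 0L)
  # proper-pair decision from unique truth placements
  span_max <- 10 * config$fragment_mean
  t_start <- vapply(t_blocks, function(b) min(b$start), numeric(1))
  t_end <- vapply(t_blocks, function(b) max(b$end), numeric(1))
  by_id <- split(seq_len(n), reads$read_id)
  prop <- vapply(by_id, function(ix) {
    if (length(ix) != 2L || any(mapq[ix] < 255L)) return(FALSE)
    if (t_contig[ix[1]] != t_contig[ix[2]]) return(FALSE)
    left <- ix[which.min(t_start[ix])]
    right <- setdiff(ix, left)
    t_strand[left] == "+" && t_strand[right] == "-" &&
      max(t_end[ix]) - min(t_start[ix]) <= span_max
  }, logical(1))
  # emit records: truth placement first, extra contiguous placements after
  prop_per_read <- unname(prop[reads$read_id])
  out <- list()
  for (i in seq_len(n)) {
    p <- placements[[i]]
    tb <- t_blocks[[i]]
    is_truth <- p$contig == t_contig[i] & p$start == tb$start[1] &
      p$strand == t_strand[i] & p$nblk == nrow(tb)
    ks <- order(!is_truth)   # truth placement first
    first <- TRUE
    for (k in ks) {
      bs <- if (first && is_truth[k]) tb$start else p$start[k]
      be <- if (first && is_truth[k]) tb$end else p$start[k] + rl
      out[[length(out) + 1L]] <- list(
        read_id = reads$read_id[i], mate = reads$mate[i],
        target = p$contig[k], strand = p$strand[k], mapq = mapq[i],
        proper_pair = prop_per_read[i] && first,
        mate_mapped = TRUE, secondary = !first,
        read_length = rl, seq = reads$seq[i],
        bstart = bs, bend = be)
      first <- FALSE
    }
  }
  records_from_list(out, "genome")
}

records_from_list <- function(lst, space) {
  if (!length(lst)) {
    df <- alignment_df(space)
    df$seq_fwd <- character(0)
    return(df)
  }
  sc <- function(f) unlist(lapply(lst, `[[`, f), use.names = FALSE)
  data.frame(read_id = sc("read_id"), mate = sc("mate"),
             target = sc("target"), strand = sc("strand"),
             mapq = sc("mapq"), proper_pair = sc("proper_pair"),
             mate_mapped = sc("mate_mapped"), secondary = sc("secondary"),
             read_length = sc("read_length"), target_space = space,
             bstart = I(lapply(lst, `[[`, "bstart")),
             bend = I(lapply(lst, `[[`, "bend")),
             seq_fwd = {
               sq <- sc("seq")
               neg <- sc("strand") == "-"
               sq[neg] <- revcomp_vec(sq[neg])
               sq
             }, stringsAsFactors = FALSE)
}

# For each read sequence, all exact contiguous matches (both strands) on
# the given sequence set.  Returns a list (one element per read, NULL for
# no hits) of lists with vectors contig, start (0-based), strand.
exact_match_placements <- function(seqs, targets, width, pdicts = NULL) {
  n <- length(seqs)
  out <- rep(list(NULL), n)
  if (is.null(pdicts)) pdicts <- build_pdicts(seqs)
  pd_f <- pdicts$fwd
  pd_r <- pdicts$rev
  for (cn in names(targets)) {
    subject <- Biostrings::DNAString(targets[[cn]])
    for (ori in c("+", "-")) {
      pd <- if (ori == "+") pd_f else pd_r
      m <- Biostrings::matchPDict(pd, subject)
      st <- Biostrings::startIndex(m)
      for (i in which(lengths(st) > 0)) {
        k <- length(st[[i]])
        if (is.null(out[[i]]))
          out[[i]] <- list(contig = rep(cn, k), start = st[[i]] - 1,
                           strand = rep(ori, k))
        else
          out[[i]] <- list(contig = c(out[[i]]$contig, rep(cn, k)),
                           start = c(out[[i]]$start, st[[i]] - 1),
                           strand = c(out[[i]]$strand, rep(ori, k)))
      }
    }
  }
  out
}

# Precompute the forward/reverse-complement PDicts of a read set so
# several alignment calls can share them.
build_pdicts <- function(seqs) {
  ss <- Biostrings::DNAStringSet(seqs)
  list(fwd = Biostrings::PDict(ss),
       rev = Biostrings::PDict(Biostrings::reverseComplement(ss)))
}

#' Ideal end-to-end alignment of reads against a sequence set
#'
#' Mode 2 style: each read is placed wherever its full sequence matches a
#' target exactly (either orientation); mates are reported independently,
#' so singletons are allowed.  Reads spanning a junction absent from
#' every target stay unaligned — exactly the loss of sensitivity the
#' assembly evidence path exists to recover.  A pair is proper on a
#' target when both mates hit it in FR orientation within 10 fragment
#' lengths; MAPQ is 255 for a unique placement within the set, else 0.
#'
#' @param reads output of [simulate_fragments()].
#' @param targets named character vector of target sequences.
#' @param space \code{"transcript_set"}, \code{"te_set"} or
#'   \code{"assembly"}.
#' @param fragment_mean expected fragment length (proper-pair bound).
#' @param pdicts optional prebuilt read dictionaries ([build_pdicts()]
#'   internal) shared across target spaces for speed.
#' @return alignment records (schema of [parse_sam()] plus
#'   \code{seq_fwd}).
#' @export
ideal_align_sets <- function(reads, targets,
                             space = c("transcript_set", "te_set",
                                       "assembly"),
                             fragment_mean = 300, pdicts = NULL) {
  space <- match.arg(space)
  rl <- nchar(reads$seq[1])
  hits <- exact_match_placements(reads$seq, targets, rl, pdicts)
  nhits <- vapply(hits, function(h) if (is.null(h)) 0L else length(h$start),
                  integer(1))
  mapq <- ifelse(nhits == 1L, 255L, 0L)
  # pair-level info per target for proper-pair flags
  out <- list()
  for (i in seq_len(nrow(reads))) {
    h <- hits[[i]]
    if (is.null(h) || !length(h$start)) next
    for (k in seq_along(h$start)) {
      out[[length(out) + 1L]] <- list(
        read_id = reads$read_id[i], mate = reads$mate[i],
        target = h$contig[k], strand = h$strand[k], mapq = mapq[i],
        proper_pair = FALSE, mate_mapped = FALSE, secondary = k > 1L,
        read_length = rl, seq = reads$seq[i],
        bstart = h$start[k], bend = h$start[k] + rl)
    }
  }
  rec <- records_from_list(out, space)
  if (!nrow(rec)) return(rec)
  # mate_mapped: other mate aligned to the same target
  key <- paste(rec$read_id, rec$target)
  has_m1 <- unique(key[rec$mate == 1L]); has_m2 <- unique(key[rec$mate == 2L])
  rec$mate_mapped <- ifelse(rec$mate == 1L, key %in% has_m2,
                            key %in% has_m1)
  # proper pair: both mates on target, FR, within 10 fragment lengths
  span_max <- 10 * fragment_mean
  pri <- which(!rec$secondary)
  pstart <- vapply(rec$bstart[pri], min, numeric(1))
  pend <- vapply(rec$bend[pri], max, numeric(1))
  by_key <- split(seq_along(pri), key[pri])
  proper_keys <- names(by_key)[vapply(by_key, function(jx) {
    if (length(jx) != 2L) return(FALSE)
    if (length(unique(rec$mate[pri[jx]])) != 2L) return(FALSE)
    left <- jx[which.min(pstart[jx])]
    right <- setdiff(jx, left)
    rec$strand[pri[left]] == "+" && rec$strand[pri[right]] == "-" &&
      max(pend[jx]) - min(pstart[jx]) <= span_max
  }, logical(1))]
  rec$proper_pair <- key %in% proper_keys & !rec$secondary
  rec
}

#' Write alignment records as SAM text
#'
#' Minimal valid SAM with \code{@SQ} headers; one line per record, with
#' N-gapped CIGARs reconstructing split blocks.  Round-trips through
#' [parse_sam()].
#'
#' @param records alignment records carrying \code{seq_fwd}.
#' @param target_lengths named lengths of the reference sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, target_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(target_lengths),
                   as.integer(target_lengths)))
  n <- nrow(records)
  if (!n) { writeLines(hdr, path); return(invisible(path)) }
  # mate strand / position from the mate's primary record (first if several)
  prim <- records[!records$secondary, , drop = FALSE]
  mk <- paste(prim$read_id, prim$mate)
  first <- !duplicated(mk)
  mstrand <- stats::setNames(prim$strand[first], mk[first])
  mpos <- stats::setNames(vapply(prim$bstart[first], min, numeric(1)),
                          mk[first])
  mtarget <- stats::setNames(prim$target[first], mk[first])
  okey <- paste(records$read_id, 3L - records$mate)
  has_mate <- okey %in% mk
  ms <- mstrand[okey]; mt <- mtarget[okey]; mp <- mpos[okey]
  flag <- 1L + ifelse(records$proper_pair, 2L, 0L) +
    ifelse(!has_mate, 8L, 0L) +
    ifelse(records$strand == "-", 16L, 0L) +
    ifelse(has_mate & !is.na(ms) & ms == "-", 32L, 0L) +
    ifelse(records$mate == 1L, 64L, 128L) +
    ifelse(records$secondary, 256L, 0L)
  pos1 <- as.integer(vapply(records$bstart, min, numeric(1)) + 1)
  cig <- vapply(seq_len(n), function(i) {
    bs <- records$bstart[[i]]
    if (length(bs) == 1L)
      sprintf("%dM", as.integer(records$bend[[i]] - bs))
    else block_cigar(bs, records$bend[[i]])
  }, character(1))
  rnext <- ifelse(!has_mate, "*", ifelse(mt == records$target, "=", mt))
  pnext <- ifelse(!has_mate, 0L, as.integer(mp + 1))
  lines <- paste(records$read_id, flag, records$target, pos1, records$mapq,
                 cig, rnext, pnext, 0L, records$seq_fwd, "*", sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

block_cigar <- function(bstart, bend) {
  o <- order(bstart)
  bstart <- bstart[o]; bend <- bend[o]
  parts <- sprintf("%dM", as.integer(bend[1] - bstart[1]))
  for (k in seq_along(bstart)[-1]) {
    parts <- c(parts, sprintf("%dN", as.integer(bstart[k] - bend[k - 1])),
               sprintf("%dM", as.integer(bend[k] - bstart[k])))
  }
  paste(parts, collapse = "")
}
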