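#' TE-annotation preparation configuration
#'
#' Defaults follow the published filters for building a robust TE
#' annotation: insertions shorter than 80 bp are discarded (the length leg
#' of the 80-80-80 rule), and insertions whose sequence is more than 50%
#' simple sequence repeat (SSR) are discarded because they cannot be
#' distinguished from satellite DNA.  The SSR content is measured by a
#' perfect-tandem-run scan (see [tandem_repeat_fraction()]) rather than an
#' external tandem-repeat finder.
#'
#' @param te_min_length minimum TE insertion length in bp (default 80).
#' @param ssr_max_fraction maximum tolerated SSR fraction (default 0.5;
#'   strictly greater is removed).
#' @param window upstream/downstream search window in bp (default 3000).
#' @param max_period largest repeat period searched by the tandem scan.
#' @param repeat_min_copies minimum consecutive unit copies for a tandem
#'   run to count.
#' @return a list of class \code{prep_config}.
#' @export
prep_config <- function(te_min_length = 80, ssr_max_fraction = 0.5,
                        window = 3000, max_period = 10,
                        repeat_min_copies = 3) {
  stopifnot(te_min_length >= 1, ssr_max_fraction >= 0, ssr_max_fraction <= 1,
            window >= 0, max_period >= 1, repeat_min_copies >= 2)
  structure(list(te_min_length = te_min_length,
                 ssr_max_fraction = ssr_max_fraction, window = window,
                 max_period = max_period,
                 repeat_min_copies = repeat_min_copies),
            class = "prep_config")
}

#' Discard TE insertions shorter than a minimum length
#'
#' @param tes TE insertion data.frame.
#' @param min_len minimum length in bp; insertions with
#'   \code{length < min_len} are removed (80 bp default upstream).
#' @return the retained rows, input order preserved.
#' @export
filter_te_length <- function(tes, min_len = 80) {
  stopifnot(min_len >= 1)
  out <- tes[tes$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of a sequence covered by perfect tandem repeats
#'
#' Exhaustively scans every period \code{1..max_period} for maximal
#' perfect tandem runs with at least \code{repeat_min_copies} unit copies,
#' merges the covered intervals across periods, and returns covered bases
#' divided by sequence length.  This is a deliberately simple stand-in for
#' alignment-based tandem repeat finders: it detects perfect runs only,
#' which is sufficient to apply an SSR-content cutoff to annotations.
#'
#' @param seq a single nucleotide string over A/C/G/T/N.
#' @param config a [prep_config()].
#' @return proportion in \[0, 1\].
#' @export
tandem_repeat_fraction <- function(seq, config = prep_config()) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("tandem_repeat_fraction: empty sequence")
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  iv_s <- numeric(0); iv_e <- numeric(0)     # 0-based half-open run spans
  for (p in seq_len(min(config$max_period, n - 1))) {
    eq <- s[seq_len(n - p) + p] == s[seq_len(n - p)]
    r <- rle(eq)
    endpos <- cumsum(r$lengths)
    startpos <- endpos - r$lengths + 1
    hit <- which(r$values & r$lengths >= p * (config$repeat_min_copies - 1))
    for (h in hit) {
      # run of k TRUEs starting at offset a covers bases [a-1, a-1+k+p)
      iv_s <- c(iv_s, startpos[h] - 1)
      iv_e <- c(iv_e, endpos[h] + p)
    }
  }
  if (!length(iv_s)) return(0)
  union_length(iv_s, pmin(iv_e, n)) / n
}

#' Discard TE insertions that are mostly simple sequence repeat
#'
#' Removes insertions whose genomic sequence has
#' \code{tandem_repeat_fraction} strictly greater than
#' \code{config$ssr_max_fraction} (an insertion at exactly the cutoff is
#' retained).
#'
#' @param tes TE insertion data.frame.
#' @param genome_sequences named character vector (or
#'   \code{Biostrings::DNAStringSet}) of contig sequences.
#' @param config a [prep_config()].
#' @return the retained rows.
#' @export
filter_te_ssr <- function(tes, genome_sequences, config = prep_config()) {
  if (!nrow(tes)) return(tes)
  seqs <- stats::setNames(as.character(genome_sequences),
                          names(genome_sequences))
  missing <- setdiff(unique(tes$contig), names(seqs))
  if (length(missing))
    stop("filter_te_ssr: contig '", missing[1], "' absent from genome (TE ",
         tes$copy_id[match(missing[1], tes$contig)], ")")
  frac <- vapply(seq_len(nrow(tes)), function(i) {
    sub <- substr(seqs[[tes$contig[i]]], tes$start[i] + 1, tes$end[i])
    tandem_repeat_fraction(sub, config)
  }, numeric(1))
  removed <- sum(frac > config$ssr_max_fraction)
  if (removed)
    message("filter_te_ssr: removed ", removed, " TE insertion(s) with SSR > ",
            config$ssr_max_fraction, " of their length")
  out <- tes[frac <= config$ssr_max_fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upstream and downstream windows of a gene
#'
#' For a plus-strand gene \code{[s, e)} the upstream window is
#' \code{[max(0, s - w), s)} and the downstream window \code{[e, min(L, e
#' + w))}; mirrored for minus-strand genes.  Windows are clamped at contig
#' edges and may be empty.
#'
#' @param gene a gene model (see [parse_gtf()]).
#' @param w window size in bp (3000 default upstream).
#' @param contig_length length of the gene's contig.
#' @return list with \code{upstream} and \code{downstream} data.frames
#'   (columns \code{start}, \code{end}; zero-width allowed).
#' @export
gene_windows <- function(gene, w = 3000, contig_length = Inf) {
  stopifnot(w >= 0)
  left <- c(max(0, gene$start - w), gene$start)
  right <- c(gene$end, min(contig_length, gene$end + w))
  mk <- function(v) data.frame(start = v[1], end = max(v[1], v[2]))
  if (gene$strand == "-") {
    list(upstream = mk(right), downstream = mk(left))
  } else {
    list(upstream = mk(left), downstream = mk(right))
  }
}

#' Classify a TE insertion relative to a gene
#'
#' Returns exactly one of \code{upstream}, \code{embedded},
#' \code{overlapped}, \code{intronic}, \code{downstream}, \code{none}.
#' A TE overlapping the gene interval is \code{embedded} when it lies
#' entirely within the gene-level exon union, \code{intronic} when it
#' overlaps no exon, and \code{overlapped} otherwise.  A TE disjoint from
#' the gene is \code{upstream}/\code{downstream} when the gap between TE
#' and gene on the respective strand-aware side is at most \code{w}
#' (inclusive: a TE exactly \code{w} bp away still counts), else
#' \code{none}.  Inside categories take precedence over window
#' categories; TE strand is ignored.
#'
#' @param te one row of a TE insertion data.frame (or list with the same
#'   fields).
#' @param gene a gene model.
#' @param w window size in bp.
#' @param contig_length contig length used to clamp windows.
#' @return single character category.
#' @export
classify_te_vs_gene <- function(te, gene, w = 3000, contig_length = Inf) {
  if (te$contig != gene$contig) return("none")
  if (overlap_bp(te$start, te$end, gene$start, gene$end) > 0) {
    ex <- gene$exons
    if (nrow(ex)) {
      ov <- overlap_bp(te$start, te$end, ex$start, ex$end)
      contained <- any(te$start >= ex$start & te$end <= ex$end)
      if (contained) return("embedded")
      if (sum(ov) == 0) return("intronic")
      return("overlapped")
    }
    return("intronic")
  }
  # window categories: the gap between TE and gene must be at most w
  # (inclusive: a TE exactly w bp away is still inside the window)
  gap_left <- gene$start - te$end
  gap_right <- te$start - gene$end
  left_in <- gap_left >= 0 && gap_left <= w
  right_in <- gap_right >= 0 && gap_right <= w
  if (gene$strand == "-") {
    if (right_in) return("upstream")
    if (left_in) return("downstream")
  } else {
    if (left_in) return("upstream")
    if (right_in) return("downstream")
  }
  "none"
}
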