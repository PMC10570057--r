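# Independent brute-force oracles.  Everything here works on explicit
# integer position sets, never reusing the package's interval machinery,
# so that agreement with the optimized implementations is informative.

# positions covered by [start, end), as an integer vector
posv <- function(start, end) {
  if (length(start) == 0) return(integer(0))
  unlist(lapply(seq_along(start), function(i)
    if (end[i] > start[i]) seq.int(start[i], end[i] - 1L) else integer(0)))
}

oracle_union_length <- function(start, end) length(unique(posv(start, end)))

# reference length consumed by a CIGAR, by direct regex accounting
oracle_ref_consumed <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  op <- substring(toks, nchar(toks))
  len <- as.integer(substring(toks, 1, nchar(toks) - 1))
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

# exhaustive perfect-tandem-run scan by direct substring comparison
oracle_tandem_fraction <- function(seq, max_period = 10, min_copies = 3) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  covered <- rep(FALSE, n)
  for (p in seq_len(min(max_period, n))) {
    for (st in seq_len(n)) {
      k <- 0                       # count repeat extension s[i] == s[i-p]
      i <- st + p
      while (i <= n && s[i] == s[i - p]) { k <- k + 1; i <- i + 1 }
      if (k + p >= p * min_copies) covered[st:(st + k + p - 1)] <- TRUE
    }
  }
  mean(covered)
}

# base-wise TE-vs-gene classification
oracle_classify <- function(te, gene, w, contig_length = Inf) {
  if (te$contig != gene$contig) return("none")
  tp <- posv(te$start, te$end)
  gp <- posv(gene$start, gene$end)
  ep <- posv(gene$exons$start, gene$exons$end)
  if (length(intersect(tp, gp))) {
    if (all(tp %in% ep)) return("embedded")
    if (!length(intersect(tp, ep))) return("intronic")
    return("overlapped")
  }
  # gap = number of bases strictly between TE and gene on each side;
  # a side is within the window when gap <= w (inclusive boundary)
  left_gap <- if (te$end <= gene$start)
    length(posv(te$end, gene$start)) else NA
  right_gap <- if (te$start >= gene$end)
    length(posv(gene$end, te$start)) else NA
  up_gap <- if (gene$strand == "+") left_gap else right_gap
  dn_gap <- if (gene$strand == "+") right_gap else left_gap
  if (!is.na(up_gap) && up_gap <= w) return("upstream")
  if (!is.na(dn_gap) && dn_gap <= w) return("downstream")
  "none"
}

# Full naive Mode 1 reference: enumerate every (pair, gene, TE) with
# base-wise overlap checks, then apply consensus arithmetic directly.
oracle_mode1 <- function(replicates, genes, tes, config, contig_lengths) {
  per_rep <- lapply(replicates, function(records) {
    rec <- records[records$mapq >= config$min_mapq & records$proper_pair &
                     records$mate_mapped, , drop = FALSE]
    total <- length(unique(rec$read_id))
    carrier <- if (config$strandedness == "rf") 2L else 1L
    pr <- rec[rec$mate == carrier & !rec$secondary, , drop = FALSE]
    pstrand <- stats::setNames(pr$strand, pr$read_id)
    raw <- list()
    for (g in genes) {
      ep <- posv(g$exons$start, g$exons$end)
      hit_reads <- character(0)
      for (i in seq_len(nrow(rec))) {
        if (rec$target[i] != g$contig) next
        bp <- posv(rec$bstart[[i]], rec$bend[[i]])
        if (length(intersect(bp, ep)) &&
            !is.na(pstrand[rec$read_id[i]]) &&
            pstrand[rec$read_id[i]] == g$strand)
          hit_reads <- c(hit_reads, rec$read_id[i])
      }
      hit_reads <- unique(hit_reads)
      fp <- if (total > 0)
        length(hit_reads) * 1e9 / (max(1, g$exon_union_length) * total)
        else 0
      if (fp < config$min_fpkm) next
      for (t in seq_len(nrow(tes))) {
        te <- tes[t, ]
        L <- contig_lengths[[g$contig]]
        cat_ <- oracle_classify(te, g, config$window,
                                if (is.null(L)) Inf else L)
        if (cat_ == "none") next
        tp <- posv(te$start, te$end)
        te_reads <- character(0)
        for (i in seq_len(nrow(rec))) {
          if (rec$target[i] != te$contig) next
          bp <- posv(rec$bstart[[i]], rec$bend[[i]])
          if (length(intersect(bp, tp)) / rec$read_length[i] >=
              config$te_overlap_fraction)
            te_reads <- c(te_reads, rec$read_id[i])
        }
        te_reads <- unique(te_reads)
        gene_reads <- hit_reads
        if (cat_ %in% c("embedded", "overlapped")) {
          pp <- setdiff(posv(g$exons$start, g$exons$end), tp)
          gene_reads <- character(0)
          for (i in seq_len(nrow(rec))) {
            if (rec$target[i] != g$contig) next
            bp <- posv(rec$bstart[[i]], rec$bend[[i]])
            if (length(intersect(bp, pp)) &&
                !is.na(pstrand[rec$read_id[i]]) &&
                pstrand[rec$read_id[i]] == g$strand)
              gene_reads <- c(gene_reads, rec$read_id[i])
          }
          gene_reads <- unique(gene_reads)
        }
        n <- length(intersect(gene_reads, te_reads))
        if (n > 0)
          raw[[length(raw) + 1L]] <- data.frame(
            gene_id = g$gene_id, te_copy_id = te$copy_id,
            category = cat_, count = n, stringsAsFactors = FALSE)
      }
    }
    if (length(raw)) do.call(rbind, raw)
    else data.frame(gene_id = character(0), te_copy_id = character(0),
                    category = character(0), count = numeric(0))
  })
  keys <- unique(do.call(rbind, per_rep)[, c("gene_id", "te_copy_id",
                                             "category")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    cnt <- vapply(per_rep, function(df) {
      m <- df$count[df$gene_id == keys$gene_id[i] &
                      df$te_copy_id == keys$te_copy_id[i] &
                      df$category == keys$category[i]]
      if (length(m)) m[1] else 0
    }, numeric(1))
    if (sum(cnt >= 1) >= config$min_replicates &&
        mean(cnt) >= config$cutoff)
      out[[length(out) + 1L]] <- cbind(keys[i, , drop = FALSE],
                                       mean_coverage = mean(cnt))
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), te_copy_id = character(0),
                      category = character(0), mean_coverage = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$te_copy_id, res$category), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# Brute-force Mode 2 mate matching over the full cross product.
oracle_mode2_match <- function(te_aln, tx_aln, te_families) {
  out <- character(0)
  ids <- unique(c(te_aln$read_id, tx_aln$read_id))
  for (id in ids) {
    for (m in 1:2) {
      te_t <- unique(te_aln$target[te_aln$read_id == id & te_aln$mate == m])
      tx_t <- unique(tx_aln$target[tx_aln$read_id == id &
                                     tx_aln$mate == (3 - m)])
      for (a in te_t) for (b in tx_t)
        out <- c(out, paste(id, b, te_families[[a]]))
    }
  }
  sort(unique(out))
}
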