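#' Parse a GTF file into gene models or TE insertions
#'
#' GTF is 1-based, closed; parsed records are converted to the package's
#' 0-based half-open convention.  Two dialects are understood:
#' \describe{
#'   \item{genes}{rows with feature \code{gene} (optional) and \code{exon}
#'     (required), carrying \code{gene_id} and \code{transcript_id}
#'     attributes.  One gene model per \code{gene_id}, with per-transcript
#'     exon lists and the gene-level exon union.}
#'   \item{tes}{one row per TE copy.  The family is taken from the
#'     \code{family_id} attribute if present, else \code{gene_id}; the copy
#'     identifier from \code{transcript_id} if present, else synthesised as
#'     \code{family:contig:start-end} with a numeric suffix on collision.}
#' }
#'
#' @param x path to a GTF file, or a character vector of GTF lines.
#' @param as \code{"genes"} or \code{"tes"}.
#' @return For \code{as = "genes"}, a named list of gene models: each a
#'   list with \code{gene_id}, \code{contig}, \code{start}, \code{end},
#'   \code{strand}, \code{transcripts} (named list of exon data.frames,
#'   each sorted, columns \code{start}/\code{end}), \code{exons} (gene
#'   level exon-union data.frame) and \code{exon_union_length}.  For
#'   \code{as = "tes"}, a data.frame of TE insertions with columns
#'   \code{copy_id}, \code{family}, \code{contig}, \code{start},
#'   \code{end}, \code{strand}, \code{length}.
#' @export
parse_gtf <- function(x, as = c("genes", "tes")) {
  as <- match.arg(as)
  lines <- read_lines_arg(x)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    if (as == "genes") return(structure(list(), names = character(0)))
    return(te_df())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 9))
    stop("GTF parse error at line ", lineno[which(n < 9)[1]],
         ": expected 9 tab-separated columns")
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  start1 <- suppressWarnings(as.numeric(m[, 4]))
  end1 <- suppressWarnings(as.numeric(m[, 5]))
  if (anyNA(start1) || anyNA(end1))
    stop("GTF parse error at line ",
         lineno[which(is.na(start1) | is.na(end1))[1]],
         ": non-numeric coordinate")
  bad <- which(start1 > end1)
  if (length(bad))
    stop("GTF parse error at line ", lineno[bad[1]], ": start > end")
  rec <- data.frame(contig = m[, 1], feature = m[, 3],
                    start = start1 - 1, end = end1,
                    strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "*"),
                    attr = m[, 9], line = lineno, stringsAsFactors = FALSE)
  if (as == "genes") build_gene_models(rec) else build_te_insertions(rec)
}

gtf_attr <- function(attr, key) {
  pat <- paste0('(^|;)\\s*', key, '\\s+"([^"]*)"')
  m <- regexec(pat, attr)
  vapply(regmatches(attr, m), function(g) if (length(g) >= 3) g[3] else NA_character_,
         character(1))
}

build_gene_models <- function(rec) {
  known <- c("gene", "exon", "transcript", "mRNA", "CDS")
  unknown <- setdiff(unique(rec$feature), known)
  if (length(unknown))
    warning("ignoring GTF rows with feature type(s): ",
            paste(unknown, collapse = ", "))
  rec <- rec[rec$feature %in% c("gene", "exon"), , drop = FALSE]
  gid <- gtf_attr(rec$attr, "gene_id")
  if (anyNA(gid))
    stop("GTF parse error at line ", rec$line[which(is.na(gid))[1]],
         ": missing gene_id attribute")
  rec$gene_id <- gid
  ex <- rec[rec$feature == "exon", , drop = FALSE]
  if (nrow(ex)) {
    tid <- gtf_attr(ex$attr, "transcript_id")
    if (anyNA(tid))
      stop("GTF parse error at line ", ex$line[which(is.na(tid))[1]],
           ": missing transcript_id attribute on exon row")
    ex$transcript_id <- tid
  }
  grows <- rec[rec$feature == "gene", , drop = FALSE]
  out <- list()
  for (g in unique(rec$gene_id)) {
    exg <- ex[ex$gene_id == g, , drop = FALSE]
    gr <- grows[grows$gene_id == g, , drop = FALSE]
    if (!nrow(exg) && !nrow(gr)) next
    contig <- c(gr$contig, exg$contig)[1]
    strand <- c(gr$strand, exg$strand)[1]
    txs <- list()
    if (nrow(exg)) {
      for (t in unique(exg$transcript_id)) {
        et <- exg[exg$transcript_id == t, c("start", "end"), drop = FALSE]
        et <- et[order(et$start, et$end), , drop = FALSE]
        rownames(et) <- NULL
        txs[[t]] <- et
      }
    }
    if (nrow(exg)) {
      mu <- merge_intervals(exg$start, exg$end)
      exons <- data.frame(start = mu[, "start"], end = mu[, "end"])
      eul <- sum(exons$end - exons$start)
    } else {
      exons <- data.frame(start = numeric(0), end = numeric(0))
      eul <- 0
    }
    gs <- if (nrow(gr)) gr$start[1] else min(exg$start)
    ge <- if (nrow(gr)) gr$end[1] else max(exg$end)
    out[[g]] <- list(gene_id = g, contig = contig, start = gs, end = ge,
                     strand = strand, transcripts = txs, exons = exons,
                     exon_union_length = eul)
  }
  out
}

te_df <- function() {
  data.frame(copy_id = character(0), family = character(0),
             contig = character(0), start = numeric(0), end = numeric(0),
             strand = character(0), length = numeric(0),
             stringsAsFactors = FALSE)
}

synthesize_copy_ids <- function(family, contig, start, end, given = NULL) {
  id <- if (is.null(given)) rep(NA_character_, length(family)) else given
  base <- paste0(family, ":", contig, ":", start + 1, "-", end)
  id[is.na(id)] <- base[is.na(id)]
  # de-duplicate with numeric suffixes, deterministically in input order
  id <- make.unique(id, sep = "_")
  id
}

build_te_insertions <- function(rec) {
  fam <- gtf_attr(rec$attr, "family_id")
  fam2 <- gtf_attr(rec$attr, "gene_id")
  fam[is.na(fam)] <- fam2[is.na(fam)]
  if (anyNA(fam))
    stop("GTF parse error at line ", rec$line[which(is.na(fam))[1]],
         ": missing family_id/gene_id attribute on TE row")
  cid <- gtf_attr(rec$attr, "transcript_id")
  df <- data.frame(copy_id = synthesize_copy_ids(fam, rec$contig, rec$start,
                                                 rec$end, cid),
                   family = fam, contig = rec$contig,
                   start = rec$start, end = rec$end,
                   strand = ifelse(rec$strand == "*", "+", rec$strand),
                   length = rec$end - rec$start, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Write gene models or TE insertions back to GTF
#'
#' Inverse of [parse_gtf()]; coordinates are re-converted to the 1-based
#' closed GTF convention, so parse/write round trips are lossless.
#'
#' @param x a gene-model list or TE data.frame as returned by [parse_gtf()].
#' @param path output file path.
#' @param source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path, source = "TEchimR") {
  lines <- character(0)
  if (is.data.frame(x)) {                      # TE insertions
    lines <- sprintf('%s\t%s\trepeat\t%d\t%d\t.\t%s\t.\tfamily_id "%s"; transcript_id "%s";',
                     x$contig, source, as.integer(x$start + 1),
                     as.integer(x$end), x$strand, x$family, x$copy_id)
  } else {
    for (g in x) {
      lines <- c(lines, sprintf('%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                                g$contig, source, as.integer(g$start + 1),
                                as.integer(g$end), g$strand, g$gene_id))
      for (t in names(g$transcripts)) {
        et <- g$transcripts[[t]]
        lines <- c(lines,
                   sprintf('%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                           g$contig, source, as.integer(et$start + 1),
                           as.integer(et$end), g$strand, g$gene_id, t))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Accept either a file path or a character vector of lines.
read_lines_arg <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) readLines(x) else x
}
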