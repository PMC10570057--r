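#' Read BLAST tabular (outfmt 6) hits
#'
#' Standard 12-column layout: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.
#'
#' @param x path or character vector of lines.
#' @return data.frame with those columns (pident as reported, 0-100).
#' @export
read_blast_tab <- function(x) {
  lines <- read_lines_arg(x)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!length(lines))
    return(stats::setNames(as.data.frame(c(rep(list(character(0)), 2),
                                           rep(list(numeric(0)), 10))), cols))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 12))
    stop("BLAST tabular parse error: fewer than 12 columns")
  df <- as.data.frame(do.call(rbind, lapply(f, `[`, 1:12)),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  for (k in cols[3:12]) df[[k]] <- as.numeric(df[[k]])
  df
}

# Local alignment of one query against one subject with the package's
# internal scoring (match +1, mismatch -1, gap open -2, gap extend -1).
# Returns matches, alignment columns, and the subject interval covered
# (0-based half-open).
local_align_stats <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(query, subject, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  s1 <- BiocGenerics::start(Biostrings::subject(aln))
  e1 <- BiocGenerics::end(Biostrings::subject(aln))
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  # identity is measured over aligned base pairs: gap columns are not
  # counted, so an internal insertion (the TE itself) does not depress
  # the identity of the flanking gene-derived alignment
  list(matches = nm, aligned = nm + nmm,
       subject_start = s1 - 1, subject_end = e1,
       subject_covered = e1 - s1 + 1)
}

#' Internal repeat matcher for assembled transcripts
#'
#' Desk-scale substitute for masking assemblies with an external repeat
#' annotator: aligns every TE library sequence locally against every
#' assembled transcript and reports hits of at least \code{min_len} bp at
#' \code{min_identity} identity or better, with the hit interval on the
#' assembled transcript (0-based half-open).
#'
#' @param assemblies named character vector of assembled transcript
#'   sequences.
#' @param te_library named character vector of TE sequences (names are
#'   families, or \code{copy#family}).
#' @param min_len minimum hit length (default 80).
#' @param min_identity minimum identity (default 0.8).
#' @return data.frame: \code{target}, \code{start}, \code{end},
#'   \code{family}.
#' @export
match_repeats <- function(assemblies, te_library, min_len = 80,
                          min_identity = 0.8) {
  out <- list()
  fam <- sub("^[^#]*#", "", names(te_library))
  for (a in names(assemblies)) {
    for (j in seq_along(te_library)) {
      st <- local_align_stats(te_library[[j]], assemblies[[a]])
      if (st$subject_covered >= min_len &&
          st$matches / st$aligned >= min_identity) {
        out[[length(out) + 1L]] <- data.frame(
          target = a, start = st$subject_start, end = st$subject_end,
          family = fam[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(target = character(0), start = numeric(0),
                      end = numeric(0), family = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
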