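#' Write a chimera call table
#'
#' Writes final calls as tab-separated text with a header.  The
#' per-replicate count list-column is flattened to a comma-separated
#' string, coordinates are reported 1-based closed
#' (\code{contig:start-end}), and rows are deterministically sorted by
#' (id, family, category) so identical runs produce byte-identical
#' files.  An empty call set yields a header-only file.
#'
#' @param calls final calls from [chimera_mode1()] or [chimera_mode2()]
#'   (optionally with location columns added by the pipeline wrappers).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chimera_table <- function(calls, path) {
  df <- calls
  if ("counts" %in% names(df)) {
    df$rep_counts <- vapply(df$counts, function(v)
      paste(format(v, trim = TRUE, scientific = FALSE), collapse = ","),
      character(1))
    df$counts <- NULL
  }
  if ("family" %in% names(df) && !"te_family" %in% names(df))
    names(df)[names(df) == "family"] <- "te_family"
  idcol <- intersect(c("gene_id", "transcript_id"), names(df))[1]
  ord <- order(df[[idcol]],
               if ("te_family" %in% names(df)) df$te_family else df[[idcol]],
               if ("category" %in% names(df)) df$category else df[[idcol]])
  df <- df[ord, , drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  for (k in names(df)[num])
    df[[k]] <- ifelse(is.na(df[[k]]), "NA",
                      format(df[[k]], trim = TRUE, scientific = FALSE,
                             digits = 6))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a chimera call table
#'
#' Inverse of [write_chimera_table()]: re-parses the comma-separated
#' per-replicate counts into the \code{counts} list-column.
#'
#' @param path file written by [write_chimera_table()].
#' @return data.frame of calls.
#' @export
read_chimera_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE)
  if ("rep_counts" %in% names(df)) {
    df$counts <- I(lapply(strsplit(as.character(df$rep_counts), ","),
                          as.numeric))
    df$rep_counts <- NULL
  }
  df
}

# 1-based closed "contig:start-end" location strings.
format_location <- function(contig, start0, end0) {
  sprintf("%s:%d-%d", contig, as.integer(start0 + 1), as.integer(end0))
}

#' Write intervals as BED
#'
#' Plain 6-column BED (0-based half-open) for genome-browser inspection
#' of called genes and TE copies.
#'
#' @param df data.frame with \code{contig}, \code{start}, \code{end},
#'   a name column (\code{copy_id} or \code{gene_id} or \code{name}) and
#'   optionally \code{strand}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  nm <- if ("name" %in% names(df)) df$name
        else if ("copy_id" %in% names(df)) df$copy_id else df$gene_id
  strand <- if ("strand" %in% names(df)) df$strand else rep(".", nrow(df))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", df$contig, as.integer(df$start),
                   as.integer(df$end), nm, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
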