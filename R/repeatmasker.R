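#' Parse RepeatMasker .out annotations into TE insertions
#'
#' Standard RepeatMasker .out layout: three header lines then one
#' whitespace-delimited row per hit.  Query coordinates are 1-based
#' closed and converted to 0-based half-open; the strand column uses
#' \code{"C"} for the minus strand.  Copy identifiers are synthesised as
#' \code{family:contig:start-end}, with a numeric suffix when two hits
#' collide on the same coordinates.
#'
#' @param x path to a RepeatMasker .out file, or its lines.
#' @return data.frame of TE insertions (see [parse_gtf()]).
#' @export
parse_repeatmasker_out <- function(x) {
  lines <- read_lines_arg(x)
  # drop the two header lines + blank separator wherever they appear
  body <- lines[!grepl("^\\s*$", lines)]
  body <- body[!grepl("^\\s*(SW|score)\\b", body)]
  if (!length(body)) return(te_df())
  toks <- strsplit(trimws(body), "\\s+")
  n <- lengths(toks)
  if (any(n < 11))
    stop("RepeatMasker parse error: row with fewer than 11 columns: ",
         body[which(n < 11)[1]])
  get <- function(i) vapply(toks, `[`, character(1), i)
  start1 <- suppressWarnings(as.numeric(get(6)))
  end1 <- suppressWarnings(as.numeric(get(7)))
  if (anyNA(start1) || anyNA(end1))
    stop("RepeatMasker parse error: non-numeric query coordinate in row: ",
         body[which(is.na(start1) | is.na(end1))[1]])
  strand <- ifelse(get(9) == "C", "-", "+")
  fam <- get(10)
  contig <- get(5)
  df <- data.frame(copy_id = synthesize_copy_ids(fam, contig, start1 - 1, end1),
                   family = fam, contig = contig,
                   start = start1 - 1, end = end1, strand = strand,
                   length = end1 - (start1 - 1), stringsAsFactors = FALSE)
  validate_intervals(df, "TE insertion")
  df
}
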