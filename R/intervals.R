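#' Genomic interval utilities
#'
#' All internal coordinates in this package are 0-based, half-open
#' (`[start, end)`), on a named contig.  1-based closed conventions (GTF,
#' RepeatMasker .out, SAM POS) are converted at parse time and converted
#' back only when writing output; nothing in between does arithmetic on
#' 1-based values.
#'
#' @param contig contig (chromosome/scaffold) name, non-empty.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded).
#' @return `gi()` returns a data.frame with columns `contig`, `start`,
#'   `end`, `strand`, one row per interval.
#' @examples
#' gi("2L", 999, 2000)
#' @export
gi <- function(contig, start, end, strand = "*") {
  df <- data.frame(contig = as.character(contig),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (any(!nzchar(df$contig)) || anyNA(df$contig))
    stop(what, ": contig must be non-empty")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(what, ": require 0 <= start < end (row ", bad[1], ": ",
         df$start[bad[1]], ", ", df$end[bad[1]], ")")
  if (any(!df$strand %in% c("+", "-", "*")))
    stop(what, ": strand must be one of +, -, *")
  invisible(df)
}

# Overlap length of interval (s1,e1) with each (s2,e2); vectorised, recycling.
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Merge possibly-overlapping intervals given as numeric starts/ends on one
# contig; returns a two-column matrix of disjoint sorted intervals.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# Total length of the union of intervals.
union_length <- function(start, end) {
  m <- merge_intervals(start, end)
  sum(m[, "end"] - m[, "start"])
}

# Subtract interval (cs,ce) from each of the disjoint intervals (start,end);
# returns the remaining pieces as a two-column matrix.
subtract_interval <- function(start, end, cs, ce) {
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)) {
    s <- start[i]; e <- end[i]
    if (ce <= s || cs >= e) {           # disjoint
      out_s <- c(out_s, s); out_e <- c(out_e, e)
    } else {
      if (cs > s) { out_s <- c(out_s, s);  out_e <- c(out_e, cs) }
      if (ce < e) { out_s <- c(out_s, ce); out_e <- c(out_e, e) }
    }
  }
  cbind(start = out_s, end = out_e)
}
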