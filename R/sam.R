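#' Reference blocks covered by a CIGAR string
#'
#' Computes the 0-based half-open reference intervals covered by an
#' alignment.  \code{M}, \code{=}, \code{X} and \code{D} consume reference
#' within the current block; \code{N} (intron skip) closes the current
#' block and opens a new one; \code{I}, \code{S} and \code{H} consume no
#' reference.  This mirrors the block semantics of
#' \command{bedtools bamtobed -split}, which is what lets a split read
#' contribute exon-side and TE-side evidence independently.
#'
#' @param pos_1based 1-based leftmost mapping position (SAM POS).
#' @param cigar CIGAR string; \code{"*"} is an error (unaligned record).
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open), one row per block.
#' @examples
#' cigar_blocks(100, "20M100N30M")
#' @export
cigar_blocks <- function(pos_1based, cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar))
    stop("cigar_blocks: record is unaligned (CIGAR '*')")
  ops <- parse_cigar(cigar)
  ref <- pos_1based - 1          # current 0-based reference cursor
  bs <- ref; out_s <- numeric(0); out_e <- numeric(0)
  open <- FALSE
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X", "D")) {
      if (!open) { bs <- ref; open <- TRUE }
      ref <- ref + len
    } else if (op == "N") {
      if (open) { out_s <- c(out_s, bs); out_e <- c(out_e, ref) }
      open <- FALSE
      ref <- ref + len
    } else if (!op %in% c("I", "S", "H", "P")) {
      stop("cigar_blocks: unknown CIGAR operator '", op, "'")
    }
  }
  if (open) { out_s <- c(out_s, bs); out_e <- c(out_e, ref) }
  data.frame(start = out_s, end = out_e)
}

parse_cigar <- function(cigar) {
  m <- gregexpr("([0-9]+)([A-Z=])", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("([0-9]+)([A-Z=])", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("cigar_blocks: malformed CIGAR '", cigar, "'")
  op <- substring(toks, nchar(toks))
  len <- as.numeric(substring(toks, 1, nchar(toks) - 1))
  bad <- setdiff(op, c("M", "I", "D", "N", "S", "H", "P", "=", "X"))
  if (length(bad))
    stop("cigar_blocks: unknown CIGAR operator '", bad[1], "'")
  data.frame(op = op, len = len, stringsAsFactors = FALSE)
}

#' Parse a SAM file into alignment records
#'
#' Reads SAM text (headers skipped) into one record per mapped line.
#' Unmapped records (FLAG 0x4) are dropped.  Secondary and supplementary
#' records are retained with their reported MAPQ: filtering is a
#' downstream policy, not a parsing one.  Read-pair identifiers are the
#' QNAME with any \code{/1}, \code{/2} mate suffix removed.
#'
#' @param x path to a SAM file, or a character vector of SAM lines.
#' @param target_space one of \code{"genome"}, \code{"transcript_set"},
#'   \code{"te_set"}, \code{"assembly"}; recorded on every record.
#' @return data.frame with one row per record: \code{read_id},
#'   \code{mate} (1 or 2), \code{target}, \code{strand}, \code{mapq},
#'   \code{proper_pair}, \code{mate_mapped}, \code{secondary},
#'   \code{read_length}, \code{target_space}, and list-columns
#'   \code{bstart}/\code{bend} holding the 0-based half-open reference
#'   blocks of each record.
#' @export
parse_sam <- function(x, target_space = c("genome", "transcript_set",
                                          "te_set", "assembly")) {
  target_space <- match.arg(target_space)
  lines <- read_lines_arg(x)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (!length(lines)) return(alignment_df(target_space))
  f <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(f)
  if (any(n < 11))
    stop("SAM parse error: line with fewer than 11 fields")
  flag <- vapply(f, function(z) as.integer(z[2]), integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  f <- f[mapped]; flag <- flag[mapped]
  if (!length(f)) return(alignment_df(target_space))
  qname <- vapply(f, `[`, character(1), 1)
  read_id <- sub("/[12]$", "", qname)
  mate <- ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)
  target <- vapply(f, `[`, character(1), 3)
  pos <- as.numeric(vapply(f, `[`, character(1), 4))
  mapq <- as.integer(vapply(f, `[`, character(1), 5))
  if (any(mapq < 0 | mapq > 255))
    stop("SAM parse error: MAPQ outside 0-255")
  cigar <- vapply(f, `[`, character(1), 6)
  seq <- vapply(f, `[`, character(1), 10)
  blocks <- mapply(cigar_blocks, pos, cigar, SIMPLIFY = FALSE)
  rl <- ifelse(seq == "*",
               vapply(cigar, read_consumed_length, numeric(1)),
               nchar(seq))
  data.frame(read_id = read_id, mate = mate, target = target,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             mapq = mapq,
             proper_pair = bitwAnd(flag, 2L) > 0L,
             mate_mapped = bitwAnd(flag, 8L) == 0L,
             secondary = bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L,
             read_length = as.numeric(rl),
             target_space = target_space,
             bstart = I(lapply(blocks, `[[`, "start")),
             bend = I(lapply(blocks, `[[`, "end")),
             stringsAsFactors = FALSE)
}

read_consumed_length <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

alignment_df <- function(target_space = "genome") {
  data.frame(read_id = character(0), mate = integer(0), target = character(0),
             strand = character(0), mapq = integer(0),
             proper_pair = logical(0), mate_mapped = logical(0),
             secondary = logical(0), read_length = numeric(0),
             target_space = character(0),
             bstart = I(list()), bend = I(list()), stringsAsFactors = FALSE)
}
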