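#' Simulate stranded paired-end fragments from the fixture isoforms
#'
#' Background coverage: each isoform of length L receives
#' \code{ceiling(depth * L / (2 * read_length))} fragments with uniform
#' start positions and Gaussian lengths.  Chimeric isoforms additionally
#' receive \code{support_depth} junction fragments per plant, whose mates
#' are placed cleanly on the TE side and the gene side of the junction
#' (with a small jitter), so every plant has at least its stated support
#' in every replicate.  With probability \code{artifact_rate}, a
#' background pair's right mate is re-drawn from a different molecule
#' (jumping-PCR / index-hopping model) and the pair is flagged as an
#' artifact in the output.
#'
#' Mate orientation follows library strandedness: for \code{rf} (dUTP)
#' libraries mate 2 is the sense read (transcript strand), for
#' \code{fwd} mate 1 is.
#'
#' @param world output of [make_genome_and_annotations()].
#' @param rep_index replicate number (seeds the replicate's RNG stream).
#' @return data.frame of reads: \code{read_id}, \code{mate},
#'   \code{isoform_id}, \code{iso_start}, \code{iso_end}, \code{sense},
#'   \code{artifact}, \code{seq}.
#' @export
simulate_fragments <- function(world, rep_index = 1) {
  config <- world$config
  set.seed((config$seed * 131 + rep_index * 7919) %% 2147483647L)
  rl <- config$read_length
  isoforms <- world$isoforms
  plants <- config$planted
  sense_mate <- if (config$strandedness == "rf") 2L else 1L
  col <- list(read_id = list(), mate = list(), isoform_id = list(),
              iso_start = list(), iso_end = list(), sense = list(),
              artifact = list(), seq = list())
  frag_no <- 0
  add_pair <- function(isoA, a1, b1, isoB, a2, b2, artifact) {
    # (a1,b1) is the left (sense) interval of its molecule
    frag_no <<- frag_no + 1
    id <- sprintf("%s:f%05d%s", isoA$id, frag_no, if (artifact) ":art" else "")
    k <- frag_no
    col$read_id[[k]] <<- c(id, id)
    col$mate[[k]] <<- c(sense_mate, 3L - sense_mate)
    col$isoform_id[[k]] <<- c(isoA$id, isoB$id)
    col$iso_start[[k]] <<- c(a1, a2)
    col$iso_end[[k]] <<- c(b1, b2)
    col$sense[[k]] <<- c(TRUE, FALSE)
    col$artifact[[k]] <<- c(artifact, artifact)
    col$seq[[k]] <<- c(substr(isoA$seq, a1 + 1, b1),
                       substr(isoB$seq, a2 + 1, b2))
  }
  for (iso in isoforms) {
    L <- iso$length
    if (config$fragment_mean > L)
      stop("simulate_fragments: fragment_length > isoform length for ",
           iso$id)
    n <- ceiling(config$depth * L / (2 * rl))
    flen <- pmin(L, pmax(rl, round(stats::rnorm(n, config$fragment_mean,
                                                config$fragment_sd))))
    starts <- floor(stats::runif(n, 0, L - flen + 1))
    art <- stats::runif(n) < config$artifact_rate
    for (i in seq_len(n)) {
      s <- starts[i]; f <- flen[i]
      if (art[i]) {
        other <- isoforms[[sample(length(isoforms), 1)]]
        s2 <- floor(stats::runif(1, 0, other$length - rl + 1))
        add_pair(iso, s, s + rl, other, s2, s2 + rl, TRUE)
      } else {
        add_pair(iso, s, s + rl, iso, s + f - rl, s + f, FALSE)
      }
    }
    # planted junction support
    if (!is.null(iso$te_copy) && length(iso$junctions) &&
        !is.null(iso$gene_id)) {
      pl <- world$truth[world$truth$gene_id %in% iso$gene_id, , drop = FALSE]
      depth_j <- if (nrow(pl)) pl$expected_min_support[1] else 0
      for (d in seq_len(depth_j)) {
        j <- iso$junctions[[(d - 1L) %% length(iso$junctions) + 1L]]
        m1 <- genome_to_iso(iso, j[1], j[2])
        m2 <- genome_to_iso(iso, j[3], j[4])
        if (m1[1] > m2[1]) { tmp <- m1; m1 <- m2; m2 <- tmp }
        jit <- sample(-10:10, 1)
        add_pair(iso, m1[1] + jit, m1[2] + jit, iso, m2[1] + jit,
                 m2[2] + jit, FALSE)
      }
    }
  }
  out <- data.frame(
    read_id = unlist(col$read_id), mate = unlist(col$mate),
    isoform_id = unlist(col$isoform_id),
    iso_start = unlist(col$iso_start), iso_end = unlist(col$iso_end),
    sense = unlist(col$sense), artifact = unlist(col$artifact),
    seq = unlist(col$seq), stringsAsFactors = FALSE)
  # antisense mates read the reverse complement of their molecule
  out$seq[!out$sense] <- revcomp_vec(out$seq[!out$sense])
  rownames(out) <- NULL
  out
}
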