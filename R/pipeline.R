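#' @title File-level pipeline entry points
#' @description
#' Thin orchestration over the module functions: read the standard
#' formats, run a detection mode, write the deterministic output tables
#' and a JSON run manifest (resolved parameters, input checksums,
#' per-stage record counts).  The \command{chimera} script under
#' \code{inst/exec/} exposes these as \code{mode1}, \code{mode2} and
#' \code{fixtures} subcommands.
#' @name pipeline
NULL

pkg_version <- function() {
  as.character(utils::packageVersion("TEchimR"))
}

write_manifest <- function(path, mode, params, inputs, stages) {
  man <- list(tool = "TEchimR", version = pkg_version(), mode = mode,
              parameters = params,
              inputs = lapply(inputs, function(f)
                list(path = f, md5 = unname(tools::md5sum(f)))),
              stages = stages)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  man
}

#' Run genome-guided detection on files
#'
#' Parses annotations and per-replicate SAM alignments, applies the TE
#' annotation filters (length; SSR content when the genome FASTA is
#' given), runs [chimera_mode1()] and writes the call table, the family
#' rollup, BED tracks of called genes/TEs, and a run manifest.
#'
#' @param gene_gtf gene annotation GTF.
#' @param te_annotation TE annotation: GTF (\code{.gtf}) or RepeatMasker
#'   \code{.out}.
#' @param sam_files character vector of per-replicate SAM paths (genome
#'   space), length >= \code{config$min_replicates}.
#' @param out_dir output directory (created if needed).
#' @param genome_fasta optional genome FASTA; enables the SSR filter and
#'   window clamping at contig edges.
#' @param config a [mode1_config()].
#' @param prep a [prep_config()].
#' @return list with \code{calls}, \code{rollup}, \code{manifest} and
#'   output \code{paths}, invisibly.
#' @export
run_mode1 <- function(gene_gtf, te_annotation, sam_files, out_dir,
                      genome_fasta = NULL, config = mode1_config(),
                      prep = prep_config()) {
  inputs <- c(gene_gtf, te_annotation, sam_files, genome_fasta)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("run_mode1: missing input file ", missing[1])
  if (length(sam_files) < config$min_replicates)
    stop("run_mode1: ", length(sam_files), " replicate(s) supplied but ",
         config$min_replicates, " required (--replicate)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- parse_gtf(gene_gtf, as = "genes")
  tes <- if (grepl("\\.out$", te_annotation))
    parse_repeatmasker_out(te_annotation)
    else parse_gtf(te_annotation, as = "tes")
  n_te_in <- nrow(tes)
  tes <- filter_te_length(tes, prep$te_min_length)
  contig_lengths <- NULL
  if (!is.null(genome_fasta)) {
    genome <- read_fasta(genome_fasta)
    contig_lengths <- nchar(genome)
    tes <- filter_te_ssr(tes, genome, prep)
  }
  reps <- lapply(sam_files, parse_sam, target_space = "genome")
  calls <- chimera_mode1(reps, genes, tes, config, contig_lengths)
  # locations for the output table
  if (nrow(calls)) {
    ti <- match(calls$te_copy_id, tes$copy_id)
    gi <- match(calls$gene_id,
                vapply(genes, `[[`, character(1), "gene_id"))
    calls$te_location <- format_location(tes$contig[ti], tes$start[ti],
                                         tes$end[ti])
    calls$gene_location <- format_location(
      vapply(genes[gi], `[[`, character(1), "contig"),
      vapply(genes[gi], `[[`, numeric(1), "start"),
      vapply(genes[gi], `[[`, numeric(1), "end"))
  } else {
    calls$te_location <- character(0)
    calls$gene_location <- character(0)
  }
  paths <- list(table = file.path(out_dir, "mode1_chimeric_transcripts.tsv"),
                rollup = file.path(out_dir, "mode1_family_rollup.tsv"),
                te_bed = file.path(out_dir, "mode1_called_tes.bed"),
                gene_bed = file.path(out_dir, "mode1_called_genes.bed"),
                manifest = file.path(out_dir, "mode1_manifest.json"))
  write_chimera_table(calls, paths$table)
  roll <- family_rollup(calls)
  utils::write.table(roll, paths$rollup, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  called_tes <- tes[tes$copy_id %in% calls$te_copy_id, , drop = FALSE]
  write_bed(called_tes[, c("contig", "start", "end", "copy_id", "strand")],
            paths$te_bed)
  gsel <- genes[vapply(genes, `[[`, character(1), "gene_id") %in%
                  calls$gene_id]
  write_bed(data.frame(contig = vapply(gsel, `[[`, character(1), "contig"),
                       start = vapply(gsel, `[[`, numeric(1), "start"),
                       end = vapply(gsel, `[[`, numeric(1), "end"),
                       gene_id = vapply(gsel, `[[`, character(1), "gene_id"),
                       strand = vapply(gsel, `[[`, character(1), "strand"),
                       stringsAsFactors = FALSE), paths$gene_bed)
  manifest <- write_manifest(
    paths$manifest, "mode1", unclass(config), inputs,
    stages = list(genes = length(genes), te_annotations_in = n_te_in,
                  te_annotations_kept = nrow(tes),
                  replicates = length(reps),
                  records = vapply(reps, nrow, integer(1)),
                  final_calls = nrow(calls)))
  invisible(list(calls = calls, rollup = roll, manifest = manifest,
                 paths = paths))
}

#' Run genome-blind detection on files
#'
#' Parses the transcript and TE FASTAs and per-replicate SAM alignments
#' against each set, runs [chimera_mode2()] (optionally with assembled
#' transcript evidence) and writes the call table plus manifest.
#'
#' @param transcripts_fasta reference transcript FASTA.
#' @param te_fasta TE insertion FASTA; headers \code{copy#family} carry
#'   the family, otherwise the whole name is the family.
#' @param tx_sam_files,te_sam_files per-replicate SAM paths for the
#'   transcript and TE alignments (same order, same length).
#' @param out_dir output directory.
#' @param config a [mode2_config()].
#' @param assembly_fasta,assembly_sam_files,repeat_out,blast_tab optional
#'   assembly-evidence inputs: assembled transcript FASTA, per-replicate
#'   SAM vs the assemblies, RepeatMasker .out on the assemblies (internal
#'   repeat matcher used when absent), precomputed BLAST outfmt-6 hits
#'   (internal aligner used when absent).
#' @param tx2gene optional 2-column TSV mapping transcript to gene IDs.
#' @return list with \code{calls}, \code{manifest}, \code{paths},
#'   invisibly.
#' @export
run_mode2 <- function(transcripts_fasta, te_fasta, tx_sam_files,
                      te_sam_files, out_dir, config = mode2_config(),
                      assembly_fasta = NULL, assembly_sam_files = NULL,
                      repeat_out = NULL, blast_tab = NULL, tx2gene = NULL) {
  inputs <- c(transcripts_fasta, te_fasta, tx_sam_files, te_sam_files,
              assembly_fasta, assembly_sam_files, repeat_out, blast_tab)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("run_mode2: missing input file ", missing[1])
  if (length(tx_sam_files) != length(te_sam_files))
    stop("run_mode2: need one TE-space SAM per transcript-space SAM")
  if (length(tx_sam_files) < config$min_replicates)
    stop("run_mode2: ", length(tx_sam_files),
         " replicate(s) supplied but ", config$min_replicates, " required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tx_seqs <- read_fasta(transcripts_fasta)
  te_seqs <- read_fasta(te_fasta)
  if (!length(te_seqs)) stop("run_mode2: empty TE FASTA")
  if (!length(tx_seqs)) stop("run_mode2: empty transcript FASTA")
  te_families <- stats::setNames(sub("^[^#]*#", "", names(te_seqs)),
                                 names(te_seqs))
  transcripts <- data.frame(feature_id = names(tx_seqs),
                            length = unname(nchar(tx_seqs)),
                            stringsAsFactors = FALSE)
  reps <- lapply(seq_along(tx_sam_files), function(r)
    list(tx = parse_sam(tx_sam_files[r], "transcript_set"),
         te = parse_sam(te_sam_files[r], "te_set")))
  assembly <- NULL
  if (isTRUE(config$assembly_enabled)) {
    if (is.null(assembly_fasta))
      stop("run_mode2: --assembly requires an assembled-transcript FASTA")
    assembly <- list(
      assemblies = read_fasta(assembly_fasta),
      alignments = lapply(assembly_sam_files, parse_sam, "assembly"),
      repeat_hits = if (!is.null(repeat_out)) {
        rm <- parse_repeatmasker_out(repeat_out)
        data.frame(target = rm$contig, start = rm$start, end = rm$end,
                   family = rm$family, stringsAsFactors = FALSE)
      } else NULL,
      te_library = te_seqs,
      blast_hits = if (!is.null(blast_tab)) read_blast_tab(blast_tab)
                   else NULL)
  }
  t2g <- NULL
  if (!is.null(tx2gene)) {
    m <- utils::read.table(tx2gene, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    t2g <- stats::setNames(m[[2]], m[[1]])
  }
  calls <- chimera_mode2(reps, transcripts, config,
                         te_families = te_families, assembly = assembly,
                         reference_seqs = tx_seqs, tx2gene = t2g)
  paths <- list(table = file.path(out_dir, "mode2_chimeric_transcripts.tsv"),
                manifest = file.path(out_dir, "mode2_manifest.json"))
  write_chimera_table(calls, paths$table)
  manifest <- write_manifest(
    paths$manifest, "mode2", unclass(config), inputs,
    stages = list(transcripts = nrow(transcripts),
                  te_sequences = length(te_seqs),
                  replicates = length(reps),
                  tx_records = vapply(reps, function(r) nrow(r$tx),
                                      integer(1)),
                  te_records = vapply(reps, function(r) nrow(r$te),
                                      integer(1)),
                  final_calls = nrow(calls)))
  invisible(list(calls = calls, manifest = manifest, paths = paths))
}

#' Generate and write a fixture bundle to disk
#'
#' Emits the full file-level bundle: genome FASTA, gene and TE GTFs,
#' reference transcript / TE-set / assembly FASTAs, per-replicate SAM
#' files for every target space, the truth table, and a manifest.
#'
#' @param out_dir output directory.
#' @param config a [fixture_config()].
#' @param n_replicates replicates to simulate.
#' @return list of written paths plus the in-memory bundle, invisibly.
#' @export
run_fixtures <- function(out_dir, config = fixture_config(),
                         n_replicates = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  b <- make_fixture_bundle(config, n_replicates)
  w <- b$world
  p <- function(...) file.path(out_dir, ...)
  write_fasta(w$genome, p("genome.fa"))
  write_gtf(w$genes, p("genes.gtf"))
  write_gtf(w$tes[, c("copy_id", "family", "contig", "start", "end",
                      "strand", "length")], p("tes.gtf"))
  write_fasta(b$m2$transcript_seqs, p("transcripts.fa"))
  write_fasta(b$m2$te_seqs, p("te_insertions.fa"))
  write_fasta(b$m2$assemblies, p("assemblies.fa"))
  m <- b$m2
  utils::write.table(
    data.frame(transcript_id = names(m$tx2gene),
               gene_id = unname(m$tx2gene)),
    p("tx2gene.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  tx_len <- stats::setNames(nchar(m$transcript_seqs),
                            names(m$transcript_seqs))
  te_len <- stats::setNames(nchar(m$te_seqs), names(m$te_seqs))
  asm_len <- stats::setNames(nchar(m$assemblies), names(m$assemblies))
  for (r in seq_len(n_replicates)) {
    write_sam(b$genome_alignments[[r]], w$contig_lengths,
              p(sprintf("rep%d.genome.sam", r)))
    write_sam(b$tx_alignments[[r]], tx_len,
              p(sprintf("rep%d.transcripts.sam", r)))
    write_sam(b$te_alignments[[r]], te_len,
              p(sprintf("rep%d.te.sam", r)))
    write_sam(b$assembly_alignments[[r]], asm_len,
              p(sprintf("rep%d.assembly.sam", r)))
  }
  utils::write.table(w$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rh <- m$repeat_hits
  out_lines <- c("   SW  perc perc perc  query      position in query",
                 "score  div. del. ins.  sequence   begin end (left)",
                 "",
                 sprintf("  225  4.0  0.0  0.0 %s %d %d (0) + %s Unknown 1 %d (0) %d",
                         rh$target, as.integer(rh$start + 1),
                         as.integer(rh$end), rh$family,
                         as.integer(rh$end - rh$start),
                         seq_len(nrow(rh))))
  writeLines(out_lines, p("assembly_repeats.out"))
  message("fixture seed: ", config$seed)
  invisible(list(dir = out_dir, bundle = b))
}
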