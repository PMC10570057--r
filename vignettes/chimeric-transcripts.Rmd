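---
title: "Detecting gene-TE chimeric transcripts: methods and design notes"
author: "TEchimR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-TE chimeric transcripts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TEchimR)
```

# The problem and the evidence model

Transposable elements (TEs) are recurrent donors of regulatory and coding
sequence to host genes.  When a TE contributes a promoter, an exonized
segment or a termination signal, the mature mRNA contains both gene- and
TE-derived sequence: a *chimeric transcript*.  Detecting these from short
paired-end RNA-seq rests on a single evidence unit, the **chimeric read**:
a read pair — or a single split read — with one part aligned to an exon
and the other to a TE copy.  One read pair contributes at most one
chimeric read to any (gene, TE) association, even when both the split
alignment and the mate independently span the junction; counting at the
pair level keeps the support threshold interpretable as junction coverage.

Chimeric reads are also produced artifactually.  Index hopping on
patterned flow cells and jumping PCR join cDNA fragments that were never
joined in the sample; up to roughly 1.5% of reads in multiplexed
libraries can be affected.  Two defenses are built in:

* only **properly paired** reads enter the genome-guided mode, which
  removes most cross-locus artifacts outright; and
* the **replicate consensus**: a chimera is only called when it is seen in
  at least `min_replicates` replicates (default 2) *and* its mean chimeric
  read count across **all** replicates (zeros included) reaches `cutoff`
  (default 2).  Independent artifacts rarely recur at the same (gene,
  family) across libraries.

Including zeros in the mean is the stricter of the two possible readings
of "average between replicates" and is the one implemented; it can only
lower the mean, never raise it past the threshold.

# Genome-guided detection (Mode 1)

Inputs: gene annotation (GTF), TE annotation (GTF or RepeatMasker `.out`),
and one genome-space SAM per replicate.  Per replicate:

1. **Alignment filter** — keep records with MAPQ ≥ `min_mapq` (default
   255, the STAR "unique" value; configurable because other aligners use
   other conventions), properly paired, mate mapped.
2. **Expression gate** — genes with FPKM < `min_fpkm` (default 1,
   inclusive boundary: FPKM = 1.0 is expressed) are removed.  FPKM is
   computed from unique fragments with the closed form
   `count * 1e9 / (exon_union_length * total_fragments)` rather than a
   probabilistic multi-mapper model: the value is only ever compared
   against the gate, where a deterministic estimate is sufficient and
   exactly testable.  Mode 1 gates per replicate; Mode 2 gates on the
   replicate-mean transcript FPKM (see below).
3. **Read lists** — a record hits a gene when any of its CIGAR-derived
   blocks overlaps the gene-level exon union by ≥ 1 bp and the pair's
   transcription strand matches the gene strand; it hits a TE copy when
   its blocks cover at least `te_overlap_fraction` (default 0.5) of the
   read length inside the copy.  TE strand is ignored; the transcription
   strand of a pair is the alignment strand of mate 2 for `rf`-stranded
   (dUTP) libraries and mate 1 for `fwd`.
4. **Chimeric pairs** — read IDs present in both lists, per (gene, copy).
5. **Positional classification** — each (TE, gene) pair receives exactly
   one category.  A TE overlapping the gene is `embedded` when entirely
   within the exon union, `intronic` when it touches no exon, else
   `overlapped`.  A disjoint TE is `upstream`/`downstream` when the gap
   to the gene on the strand-appropriate side is at most `window`
   (default 3000 bp).  The boundary is inclusive — a TE exactly 3000 bp
   away is in, 3001 bp is out.  (An interval-overlap test against the
   half-open window `[start - w, start)` would put the boundary at 2999;
   the distance rule is the reading consistent with both the "gap 3001 is
   out" convention and "3000 in" boundary behaviour, and the two rules
   differ only at that single base.)
6. **Exon-portion rule** — for `embedded` and `overlapped` TEs the exon is
   split at the TE, and the gene-side evidence of a pair must overlap at
   least 1 bp of exon-minus-TE sequence.  Pairs lying wholly within the
   TE are therefore never chimeric evidence: autonomous TE expression
   does not masquerade as exonization.
7. **Consensus** — calls keyed by (gene, TE copy, category) pass through
   the replicate consensus; the per-copy table also rolls up to
   (gene, family) via `family_rollup()`.

Exon containment is tested against the union of exons across all
transcripts of the gene, not per transcript: the read lists are gene
level, so classification must be too, and a TE inside one isoform's exon
but another's intron is still capable of exonization evidence.

# Genome-blind detection (Mode 2)

Inputs: reference transcript FASTA, TE insertion FASTA, and per-replicate
SAMs against each set.  Transcripts are gated at replicate-mean
FPKM ≥ 1.  From the two alignments four per-mate ID lists are built
(mate 1 / mate 2 × TE space / transcript space), each regardless of
whether the other mate aligned.  Chimeric evidence is the intersection
te-mate-1 ∩ tx-mate-2 and vice versa:

* **singleton** — the pair is not concordant in the transcript: the TE
  is absent from the reference sequence.  This is the signal that
  recovers *polymorphic* insertions present in the sample but missing
  from every reference.
* **concordant** — the pair is properly paired within the transcript and
  one mate also aligns in the TE space: the TE insertion is part of the
  reference transcript.

Because short reads rarely align uniquely within a TE family, a
transcript supported by several families keeps only the family with the
highest chimeric-read coverage (pooled across replicates); ties break to
the lexicographically smallest family name — an arbitrary but
deterministic rule.

**Assembly evidence** (optional): end-to-end alignment cannot place reads
that span a junction absent from every reference sequence, so a
transcriptome assembly can rescue sensitivity.  Given assembled
transcripts, a repeat annotation on them (external `.out`, or the
internal matcher: local alignment of each TE sequence against each
assembly, hits ≥ 80 bp at ≥ 80% identity), and read alignments against
the assemblies, an assembly is a candidate when ≥ `cutoff` read pairs
have aligned bases both inside a family's repeat region and outside all
repeat regions.  Candidates pass the **80/80 homology filter**: some
reference transcript must align with identity ≥ 0.8 covering ≥ 0.8 of
the *reference* length (the reference-length denominator is the reading
consistent with selecting assembled transcripts that represent a full
reference transcript plus a TE).  Assembly-path consensus is
presence-based (≥ `min_replicates` replicates; the read-count cutoff was
already applied inside the per-replicate scan).  Final evidence classes:
`chimeric_reads_only`, `assembly_only`, `double`.

*Identity definition.*  Identity is matches / aligned base pairs, with
gap columns excluded from the denominator.  With gap columns included, a
candidate consisting of a reference transcript plus an internal TE — the
canonical true positive — aligns with one long gap and its identity drops
below 0.8 even at perfect sequence agreement, which would invert the
filter's purpose.  BLAST-style per-HSP identities behave like the
gap-excluded definition; precomputed tabular hits, when supplied,
override the internal aligner entirely and are used bit for bit.  The
internal aligner also applies an exact 24-mer probe pre-screen (three
fixed positions along the reference) before committing to the quadratic
alignment; a reference with no conserved 24-mer at any probed position
cannot realistically pass 80/80, and the BLAST path bypasses the screen.

# Annotation preparation

Two hygiene filters precede Mode 1, applied in either order (they
commute):

* **Length** — insertions shorter than 80 bp are discarded (strict `<`:
  80 bp is kept).  Shorter fragments cannot be robustly attributed to a
  TE family.
* **SSR content** — insertions whose sequence is *more than* 50% simple
  sequence repeat are discarded (exactly 50% is kept).  SSR content is
  measured by an exhaustive perfect-tandem-run scan: every period
  1..`max_period` (default 10) is checked for maximal runs with at least
  `repeat_min_copies` (default 3) unit copies; run footprints are merged
  and the covered fraction reported.  This deliberately simple stand-in
  for alignment-based tandem-repeat finders detects perfect runs only; it
  is sufficient to apply a content cutoff on annotations, and parity with
  scoring-based tools is explicitly not claimed.

# The synthetic world

`make_fixture_bundle()` builds everything both modes consume, with known
truth:

* a toy genome of gene "units" spaced 8 kb apart (beyond the default
  window, so neighbours never interact), each a gene of two exons
  (800 bp) with a 400 bp intron, with a 300 bp TE copy planted in one of
  the five positional geometries; plus decoy genes, a decoy TE with no
  reads, and an autonomously transcribed TE;
* each TE copy is the family consensus with ~4% seeded substitutions —
  as real insertions diverge — which keeps exact-match alignment of its
  reads unique and the MAPQ-255 filter transparent;
* chimeric isoforms realising each plant (e.g. the upstream plant's
  isoform starts inside the TE and reads through into exon 1; the
  intronic plant exonizes the TE as a cassette);
* stranded paired-end reads: background fragments at
  `ceiling(depth * L / (2 * read_length))` per isoform (default depth
  20×, fragment length 300 ± 20 — a typical short-insert mRNA library)
  plus `support_depth` (default 4) junction pairs per plant per
  replicate, placed so the TE-side mate clears the 50% overlap rule and
  the gene-side mate lands on exon-minus-TE sequence;
* an ideal aligner: the true (possibly N-gapped) placement plus every
  other exact-match locus; unique placements get MAPQ 255, multiple
  MAPQ 0.  Mode 2 alignments are end-to-end exact matching, so junction
  reads against a TE-less reference stay unaligned — reproducing the
  sensitivity loss the assembly path exists to repair;
* cross-molecule artifact pairs at `artifact_rate` (default 0; the
  regime around 1.5% mirrors reported artifact levels), flagged in the
  read table;
* a Mode 2 re-expression in which plants flagged *polymorphic* have
  their TE excised from the reference transcript.

What a green test establishes: the detection logic — filters, list
intersection, classification, consensus — is exact on error-free,
uniquely placeable reads.  What it does not establish: robustness to
sequencing error, to diverged TE copies that multi-map into each other,
to incomplete annotations, or to aligner-specific MAPQ/pairing
behaviour.  Reads are error-free by default because the detection logic
is alignment-driven, not base-quality-driven.

# Numerical choices and edge cases

* Internal coordinates are 0-based half-open everywhere; GTF,
  RepeatMasker and SAM conventions are converted at the parse/write
  boundary only.
* All stated thresholds are boundary-inclusive on the "keep" side:
  FPKM 1.0 expressed, 80 bp kept, 50% SSR kept, 50% read overlap kept,
  3000 bp window in, identity/coverage 0.80 pass.
* Consensus means include zero-count replicates; `(3,1)` passes
  (mean 2.0), `(5,0)` fails the presence rule, `(1,1,1)` fails the mean.
* Output tables sort by (id, family, category) and flatten count vectors
  to comma strings, making identical runs byte-identical.
* RepeatMasker copy IDs are synthesized as `family:contig:start-end`
  with numeric suffixes on collision; no public convention exists for
  naming individual copies.
* Upstream/downstream calls apply no TE-gene strand-consistency
  constraint; nothing in the detection definition requires one.
* The ideal aligner marks a pair proper when both mates place uniquely
  on one contig in FR orientation within 10 fragment lengths.

# Known limitations

* FPKM from unique fragments underestimates expression of genes rich in
  multi-mapping sequence; a gene whose unique-read FPKM sits near 1 can
  flip across the gate between replicates.
* The internal homology aligner is orientation-sensitive (no
  reverse-complement search) and desk-scale; for real data, supply
  BLAST tabular hits.
* The tandem-repeat scan detects perfect runs only; diverged satellite
  arrays pass the SSR filter that a scoring-based finder would flag.
* Mode 2 cannot position a chimera (no genome coordinates) and reports
  one family per transcript by construction.
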