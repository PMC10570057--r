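# TEchimR

Detection of gene–transposable-element chimeric transcripts from stranded
paired-end RNA-seq.

Transposable elements (TEs) donate promoters, exons and terminators to host
genes, producing *chimeric transcripts*: mature mRNAs that contain both
gene-derived and TE-derived sequence.  The evidence unit for a chimera is
the **chimeric read** — a read pair (or split read) with one part aligned to
an exon and the other to a TE copy.  TEchimR implements two complementary
detection strategies around this unit:

* **Mode 1 (genome-guided)** — reads aligned to an annotated genome.  Only
  uniquely aligned, properly paired reads (MAPQ ≥ 255, the STAR unique
  convention) are used.  Genes are gated at FPKM ≥ 1, exon-read and TE-read
  lists are intersected into chimeric pairs (a read counts as TE-derived
  when ≥ 50% of its length lies in the copy), and each call is classified by
  the TE's position relative to the gene:

  | category | geometry |
  |---|---|
  | TE-initiated (`upstream`) | TE within *w* = 3 kb upstream of the gene |
  | TE-exonized `embedded` | TE entirely inside an exon |
  | TE-exonized `overlapped` | TE partially overlapping an exon |
  | TE-exonized `intronic` | TE entirely intronic |
  | TE-terminated (`downstream`) | TE within 3 kb downstream |

  For embedded/overlapped TEs the exon is split at the TE and the gene-side
  mate must overlap exon-minus-TE sequence, so autonomous TE expression is
  never counted as chimeric evidence.

* **Mode 2 (genome-blind)** — no genome needed.  Reads are aligned
  independently to a reference transcript set and a TE insertion set; a
  read pair whose mates land one in each space (singleton evidence), or
  which is concordant in a TE-containing transcript (concordant evidence),
  supports a (transcript, family) chimera.  Because singleton evidence does
  not require the TE to be in any reference sequence, Mode 2 recovers
  chimeras from **insertionally polymorphic TEs** absent from the reference
  genome.  An optional assembled-transcript path scans assemblies for
  TE/non-TE junction support and accepts candidates through the **80/80
  rule** (≥ 80% identity over ≥ 80% of the reference transcript length),
  yielding evidence classes `chimeric_reads_only`, `assembly_only` and
  `double`.

Both modes suppress library artifacts (jumping PCR, index hopping — up to
~1.5% of reads in multiplexed libraries can be artifactual chimeras) with a
**replicate consensus**: a chimera must appear in ≥ 2 replicates with a mean
of ≥ 2 chimeric reads across all replicates.

The standard TE-annotation hygiene filters are included: insertions
< 80 bp are discarded, and insertions whose sequence is > 50% simple
sequence repeat (measured by an exhaustive perfect-tandem-run scan) are
removed.

A seeded synthetic-fixture generator (`make_fixture_bundle()`) builds a toy
genome with planted chimeras of every category, simulates stranded
paired-end reads with known junction support, and aligns them with an ideal
exact-match aligner — so the whole pipeline is testable with no external
data or aligners.

## Worked example

Generate a fixture bundle (5 planted chimeras, one per category, 2
replicates) and run genome-guided detection on its files:

```r
library(TEchimR)

d <- file.path(tempdir(), "fx")
run_fixtures(d, fixture_config(seed = 1), 2)

res <- run_mode1(file.path(d, "genes.gtf"), file.path(d, "tes.gtf"),
                 file.path(d, c("rep1.genome.sam", "rep2.genome.sam")),
                 file.path(tempdir(), "out1"),
                 genome_fasta = file.path(d, "genome.fa"))
```

`out1/mode1_chimeric_transcripts.tsv` then contains:

```
gene_id te_copy_id  te_family  category    mean_coverage  replicates_present  gene_fpkm  te_location       gene_location     rep_counts
g01     roo.c01     roo        upstream    13.5           2                   68663.8    chr1:2351-2650    chr1:201-2200     15,12
g02     blood.c02   blood      embedded    62.5           2                   57378.6    chr2:1701-2000    chr2:201-2500     62,63
g03     copia.c03   copia      overlapped  38.5           2                   57424.8    chr1:11701-12000  chr1:11051-13350  38,39
g04     jockey.c04  jockey     intronic    65.0           2                   67610.3    chr2:11851-12150  chr2:10901-13100  60,70
g05     opus.c05    opus       downstream  14.5           2                   67434.6    chr1:23901-24200  chr1:21751-23750  20,9
```

One row per (gene, TE copy, category): `mean_coverage` is the mean number
of chimeric read pairs across replicates (every call here exceeds the
planted minimum of 4 junction pairs per replicate because background
coverage adds further support), `rep_counts` the per-replicate counts,
locations are 1-based closed.  All five planted chimeras are recovered
with their exact categories and there are no false calls.  The same bundle
re-expressed as transcripts + TE set drives `run_mode2()`; the embedded
plant is polymorphic (its TE is excised from the reference transcript) and
is recovered through singleton mate evidence, upgrading to `double` when
the perfect assemblies are supplied.

A thin CLI wraps the same functions:

```sh
inst/exec/chimera fixtures --out fx --seed 1
inst/exec/chimera mode1 --genes fx/genes.gtf --tes fx/tes.gtf \
    --sam fx/rep1.genome.sam,fx/rep2.genome.sam --genome fx/genome.fa \
    --out out1
```

## Acceptance script

`scripts/acceptance.R` regenerates the seeded synthetic world (30 genes,
two plants per positional category, 2 replicates), runs both modes end to
end — Mode 1 against the genome alignments, Mode 2 with the assembly
evidence path enabled — and writes the JSON target map:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/chimeric-transcripts.Rmd` documents the model and its
assumptions, every tunable threshold with its default and rationale, what
the fixture generator does and does not emulate, and the numerical corner
cases (boundary inclusivity, identity definition, tie-breaks).
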