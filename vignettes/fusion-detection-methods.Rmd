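---
title: "Detecting fusion transcripts in UMI-tagged amplicon RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fusion transcripts in UMI-tagged amplicon RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionforge)
```

## The problem

Targeted PCR-amplicon RNA-seq panels (QIAseq RNAscan and similar chemistries)
sequence a set of clinically relevant genes at high depth, using a
gene-specific primer on one side of each amplicon and a universal primer on
the partner side, so that fusions with *novel* partner genes remain
detectable. Two properties of this data shape the whole analysis:

* **PCR duplication.** Each cDNA molecule is amplified many times, so raw
  read counts wildly overstate molecular evidence. A unique molecular index
  (UMI) ligated before amplification lets duplicates be recognised and
  collapsed, and support for a fusion counted in *molecules*.
* **Short reads over a small target space.** Split alignment of individual
  short reads to the genome is noisy; assembling the (deduplicated) reads of
  each gene into longer contigs first, and split-aligning contigs, is both
  more specific and much cheaper.

fusionforge implements this workflow end to end: UMI consensus
deduplication, adapter trimming, gene-level binning, per-gene de-novo
assembly, split-contig breakpoint discovery, artifact filtering, exon/frame
annotation, and confirmation of each candidate by realigning consensus reads
to a chimeric junction construct. Confirmed events are emitted as paired VCF
breakend (BND) records with an IGV session for review.

## Bayesian UMI consensus

Reads are grouped by UMI (greedy, count-descending clustering with a hamming
tolerance of 1 by default, so a sequencing error inside the UMI does not
split a molecule). Within a cluster, every position is resolved by a
posterior over the four bases. With observed bases $b_i$ and Phred scores
$Q_i$, the per-observation error probability is $e_i = 10^{-Q_i/10}$ and

$$P(b \mid \text{obs}) \propto \pi_b \prod_i
  \begin{cases} 1 - e_i & b_i = b \\ e_i/3 & b_i \ne b \end{cases}$$

with a uniform prior $\pi_b = 1/4$. The consensus base is the posterior
argmax (ties broken $A<C<G<T$) and its quality is
$-10\log_{10}(1 - P_{\max})$, capped at 60 to keep scores in a printable
range while still exceeding any single-read input. A single-read cluster
therefore reproduces its input base and quality exactly, and every
additional agreeing read increases the posterior — both properties are
tested against a brute-force enumeration of the four hypotheses.

Reads within a cluster may differ in length after trimming; the consensus
takes the modal length and shorter members inform only the positions they
cover. UMIs containing `N` are conservatively left as singleton clusters.
An optional `split_by_prefix` key additionally separates molecules that
collided on one UMI by their first template bases; it is off by default
because at panel scale (thousands of molecules against $4^{12}$ UMIs)
collisions are negligible.

## Read reduction and per-gene assembly

Consensus reads are aligned to a reference holding one sequence per gene —
the transcript with the longest coding sequence (ties: longest transcript,
then lexicographic id) — using the internal seed-and-extend engine (exact
17-mer seeds, ungapped extension, BWA-like scoring: match +1, mismatch -4).
A pair is binned by its better-scoring mate; both mates enter the bin
oriented to the transcript strand. Within a bin, alignments sharing identical
(length, start, end) are capped at **five copies**, which bounds assembly
input without discarding any distinct locus.

Assembly is a greedy overlap-layout-consensus scheme per gene: candidate
suffix–prefix overlaps are located through shared 15-mers, the pair with the
longest overlap of at least 30 bases at $\ge 0.9$ identity merges first, and
merging repeats until no admissible overlap remains. Reverse-complement
overlaps are considered only when a pair has no admissible forward overlap
(reads are pre-oriented by their binning alignment, so forward overlaps are
the norm and this rule keeps palindromic artifacts from outcompeting real
layouts). Ties break on lexicographic contig ids, making assembly
deterministic; singletons are emitted as contigs, so every read is accounted
for in exactly one contig.

One admission rule matters when several fusions share a partner gene: an
overlap is rejected when its mismatches form a contiguous run longer than 5
bases, even if overall identity clears the threshold. Scattered mismatches
are sequencing error; a contiguous block is an incompatible branch (two
different junctions diverging from the same gene sequence), and merging
across it would silently overwrite the minority branch's junction evidence.
With the guard, such bins assemble into multi-segment chimeric contigs that
carry every junction, and each segment pair is evaluated independently
downstream.

## Breakpoint discovery

Contigs are split-aligned to the genome: seed hits are grouped into
near-diagonal bands per (chromosome, strand), each band is extended to the
best-scoring ungapped local segment, and segments of at least 25 bases at
$\ge 0.9$ identity are reported. A pair of segments becomes a breakpoint
candidate when they tile the contig (gap/overlap at most 10 bases) and come
from non-contiguous genomic regions: different chromosomes, a strand change,
or a same-chromosome gap above `min_genomic_gap` (10 kb by default — gaps
below that are intron-scale splicing, not rearrangement).

Because the aligner extends each segment as far as the score allows, the two
segments usually overlap by a few bases around the junction (genuine
microhomology, or chance matches past the junction), or leave a small gap
when consensus errors sit on the junction. Both breakpoints must be derived
from a *single* split point — otherwise the confirmation construct acquires
an indel relative to the reads and recruits no ungapped support — so the
junction is refined to the split that maximises total matches of the contig
against the two genomic continuations, with ties resolved to the smallest
offset. When both sides then lie within `boundary_tolerance` (3 bases) of
annotated exon boundaries and agree on the same shift, the breakpoints snap
to the boundaries; this resolves the residual ambiguity that true
microhomology leaves at exon–exon junctions. Redundant candidates whose
breakpoints agree within 5 bases on both sides collapse to the candidate
from the longest contig.

## Filtering and annotation

Three filters flag artifacts; each is evaluated independently on the
unfiltered candidate and the kept set is exactly the candidates with no
dropping flag:

* **MRR** — the mononucleotide repeat ratio of each 20-base junction flank,
  defined here as the longest single-nucleotide run divided by the window
  length (the statistic is configurable; this is the simplest definition
  matching its purpose). Flanks with MRR $\ge 0.6$ drop the candidate.
  Windows truncated below 4 bases by a contig edge are flagged
  `SHORT_WINDOW` and kept.
* **Blocklist** — recurrent homology-driven artifact pairs or regions,
  supplied as a TSV of gene pairs (unordered) or 1-based closed genomic
  intervals. The default blocklist is empty because its content is
  panel-specific.
* **Single-transcript** — events with both breakpoints in one gene are
  dropped unless an allowlist entry for that gene admits them; an entry is
  `(gene, min_exon_skip)` and an intragenic candidate qualifies when it
  skips at least that many annotated exons. This keeps EGFRvIII-class
  deletions callable without admitting ordinary splicing.

Annotation maps each breakpoint to a transcript (canonical first, then
longest CDS), classifies it (exon boundary within 3 bases, mid-exon, or
intronic), and reports labels in the `strand|End_Ek|gene|transcript` /
`strand|Start_Ek|gene|transcript` convention with exon numbers in
transcription order. A fusion is **In-frame** when the coding bases retained
from the 5' transcript up to the junction, modulo 3, equal the CDS phase at
the 3' acceptor exon start; junctions without CDS context on either side
(non-coding transcripts, mid-exon breaks beyond tolerance, unannotated
regions) are **Indeterminate**. Frame is computed from genomic breakpoints
only, so small insertions at the junction do not change the call.

## Confirmation and reporting

For every kept candidate a chimeric construct is built from the genome: up
to **150 bases** ending at the 5' breakpoint plus up to 150 bases starting
at the 3' breakpoint, strand-aware, truncated at chromosome ends (rejected
below 20 bases of flank). Consensus reads that match some panel transcript
end-to-end with zero mismatches are first removed — they are ordinary
transcription and cannot span a novel junction. The remaining reads are
realigned to all constructs in one pass; a read supports a construct when
its alignment covers at least **10 bases on each side** of the junction at
$\ge 0.9$ identity. Support is counted as distinct consensus read ids, so a
molecule contributes once no matter how many PCR copies or mates it had. A
**single supporting molecule** suffices by default (`min_support = 1`,
configurable); raising the threshold can only remove calls and lowering it
can only add them, which the tests assert.

Calls are written as VCF 4.2 paired BND records with mutual `MATEID`s and
INFO keys for the partner genes, exon labels, frame, supporting reads,
contig and flank MRRs. The IGV session bundles the construct FASTA (+
`.fai`), a sorted indexed BAM of supporting alignments, and a session XML
with relative paths.

## The simulator and what it does (not) model

All tests run on data from the bundled simulator. A panel of $n$ genes is
generated with one multi-exon transcript per gene on its own synthetic
chromosome, plus strand: 4–6 exons of 160–240 bases (so a 150-base construct
flank at an exon boundary stays exonic), introns of 150–400 bases, CDS
boundaries placed randomly inside the first and last exons. Fusions join an
exon end to an exon start, inter- or intragenic. Molecules receive unique
12-base UMIs; fragments of 150–260 bases are placed so the R1 insert spans a
planted junction by at least 15 bases on each side; PCR copies (1 plus a
Poisson draw with mean `duplicate_rate` − 1) carry independent substitution
errors at `error_rate` per base, including inside the UMI; R2 is the
reverse complement of the fragment's other end. The default conditions —
1% substitution error, duplicate rate 3, 50 molecules per fusion, 300
background molecules drawn uniformly from the panel — are the simulation
conditions all sensitivity/specificity statements refer to.

The simulator deliberately does **not** model FFPE RNA degradation,
ribosomal contamination, realistic expression distributions, indel
sequencing errors (the consensus model is per-position, so indels would
require alignment within clusters), chimeric PCR artifacts, or homologous
gene families. Passing tests therefore demonstrate the pipeline's internal
consistency and its behaviour under idealised amplicon noise, not clinical
performance; panel-specific blocklists exist precisely because real data
contain recurrent artifacts this generator cannot produce. Minus-strand
transcripts are exercised by hand-built fixtures in the unit tests rather
than by the generator's default panel.

## Numerical and design choices

* Ungapped extension everywhere: the dominant error mode after UMI consensus
  is substitution, and refusing gaps makes scores, coordinates and supports
  exactly reproducible. The price is insensitivity to indel-bearing reads,
  which the simulator does not produce and real amplicon data produce
  rarely.
* Seed lengths: 17 for transcript/genome alignment (specific at panel
  scale), 15 for assembly overlaps (must not exceed `min_overlap`), 13 for
  construct support (constructs are only 300 bases).
* Determinism contracts: clusters are seeded in descending (count,
  encoded-UMI) order; assembly ties break on contig ids; per-gene results
  merge in sorted gene order so thread count never changes output; the
  simulator restores the caller's RNG state.
* Degenerate inputs: empty FASTQ yields valid empty outputs and a warning;
  contigs shorter than the seed produce no segments; junctions within 4
  bases of a contig edge skip the MRR test but keep the candidate;
  constructs with under 20 bases of available flank are rejected outright.
* Benchmarking conventions: MAPE = mean(|A−F|/A) over fusions with known
  support A > 0 and detected support F; SMAPE uses the (A+F) denominator,
  which is bounded by 1 and equals exactly 1 for a caller that detects
  nothing — the same boundary value MAPE takes there, which is the
  convention the degenerate-caller identity tests pin down. A call matches a
  truth entry when the unordered gene pair agrees and both breakpoints are
  within 10 bases (sides may swap). In threshold sweeps, counts are computed
  per sample and aggregated; a truth-negative sample with no surviving call
  counts one true negative.
* Test and acceptance problem sizes: module tests use 3–5 gene panels with
  10–20 molecules per fusion; the end-to-end positive control uses a
  30-gene panel with 27 distinct fusions at 50 molecules each and 5
  negative replicates — sizes chosen so the full suite exercises deep
  coverage, shared fusion partners and empty cases while remaining
  desk-scale.

## Limitations

External aligner/assembler/trimmer engines (BWA, CAP3, BLAT, fastp) are not
shelled out to; the internal engines define the contract and keep the
package self-contained. Fusion expression quantification, allele fractions,
protein-domain annotation and genome-scale references are out of scope.
Breakpoints inside microhomology tracts longer than the snapping tolerance
remain ambiguous by construction; the reported position is then one
consistent representative of the homology window.
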