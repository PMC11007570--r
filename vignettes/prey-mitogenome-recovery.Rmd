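---
title: "Recovering prey mitogenomes from predator metagenomes"
author: "mitobait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering prey mitogenomes from predator metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-body metagenomes of small predators contain undigested prey DNA.
When the predator is a rhodopid sea slug — an interstitial gastropod that
preys on placozoans — its gut content carries enough placozoan
mitochondrial DNA that whole mitochondrial chromosomes can be fished out
of the read pool, even though the host genome dominates the library by
orders of magnitude and several prey haplotypes may be mixed in one
animal. `mitobait` implements this recovery as a reusable pipeline and
adds the comparative layer used to place the recovered genomes: codon-aware
concatenated matrices, uncorrected p-distances with pairwise deletion,
rank-wise group means, and a diagnostic-marker scan.

## The recovery procedure

The pipeline runs in fixed stages, each exposed as an ordinary function:

1. **Trimming** (`preprocess_reads`). A sliding-window trimmer (window 4,
   Phred cutoff 15) peels low-quality 3' bases and clips adapter suffixes
   at exact matches of 10 bp or more. Pairs with a mate shorter than
   50 bp are dropped whole.
2. **Baiting** (`bait_reads`). A pair is recruited when either mate
   shares at least 2 canonical 25-mers with any genome of the reference
   panel; the mate of a recruited read is always recruited too. Shared-k-mer
   counting replaces alignment-based baiting: with `k = 25` and a
   threshold of 2, a 250 bp read up to ~15% divergent from the panel is
   still recruited, while the chance that a random host read shares two
   25-mers with a 40 kb panel is negligible (verified empirically on
   10^5 random reads in the test suite).
3. **Error correction** (`preprocess_reads(correct = TRUE)`). A
   k-mer-spectrum rule repairs bases supported only by solo 21-mers when a
   single substitution lifts every covering k-mer to a count of at least
   5. The pipeline corrects the recruited pool rather than the whole
   library: the prey fraction carries its own 40-800x spectrum, and
   correcting a few thousand pairs instead of hundreds of thousands keeps
   the stage inexpensive without changing its outcome for the targeted
   genomes.
4. **Assembly and extension** (`assemble_and_extend`). Seed contigs come
   from a de Bruijn assembly over the k-mer ladder 33/55/77; the largest k
   whose graph yields unitigs of at least twice the read length wins.
   K-mers seen fewer than 3 times are excluded: the corrector, by its
   solo-k-mer rule, cannot touch an error shared by exactly two reads, and
   those doubletons are the dominant residual branch source at 40-100x
   coverage. Each contig end is then extended for up to 10 rounds by the
   consensus of reads overlapping the terminal bases at >= 98% identity,
   appending a base only while it holds >= 80% of the votes. A fork with
   no 80% majority marks a haplotype boundary and stops the extension —
   ambiguity is resolved downstream by the reference, not by branching.
   Ties break toward the alphabetically smaller base, making assembly
   deterministic.
5. **Reference scaffolding** (`anchor_contigs`, `merge_and_close`,
   `finalize_scaffold`). Contigs are anchored on each panel genome by
   shared-k-mer diagonal voting plus a banded global alignment, assigned
   to the panel genome they match best (minimum identity 0.75, permissive
   enough to anchor across inter-genus divergence), merged where
   overlapping placements agree at >= 99% over >= 30 bp, and the merge is
   repeated after recruiting reads against every residual gap plus 300 bp
   of reference context on both sides and reassembling them locally
   (33/55/77 ladder, to a fixpoint or 3 rounds). Gap recruitment is
   stricter than panel baiting (8 shared 25-mers, and when a gap attracts
   more than 500 pairs only the strongest matches are kept): in a mixed
   community, reads of a high-coverage sister haplotype graze the
   conserved rRNA windows of a low-coverage target reference and would
   otherwise flood its recruitment, while this rule stays near-fully
   sensitive to reads within ~10% of the reference. Gap-closing contigs
   must likewise anchor at >= 0.85 identity — stricter than the initial
   0.75 assignment. Remaining gaps are filled with as many N as the
   reference spans there, so reported gap lengths are reference-implied
   approximations; reference bases are never copied into a scaffold, and
   completeness is the percentage of the reference length covered by
   non-N bases.
6. **Back-mapping QC** (`backmap_qc`). The trimmed (never the corrected)
   reads are re-mapped to the final scaffolds; pairs must map to one
   scaffold in opposite orientations with an insert within 3x the library
   range. The report carries mean coverage per scaffold and library, and
   flags positions where >= 20% of spanning reads (depth >= 5) disagree
   with the consensus — the signature of chimeras or mixed haplotypes.
7. **Annotation transfer** (`transfer_annotations`, `validate_orfs`,
   `detect_rearrangements`). The scaffold is globally aligned to its
   reference (match 2, mismatch -3, gap open -5, extend -2, banded) and
   every exon projected through the alignment; transfer is refused below
   60% identity. A projected CDS that breaks frame is snapped to the
   nearest in-frame boundary within +/- 6 nt — the declared remedy for
   micro exons too short to align unambiguously. CDS are validated as
   genetic-code-4 ORFs (start ATG/GTG, no internal stops, terminal stop
   present or the feature runs into an N gap, in which case it is reported
   as incomplete rather than failed). Gene orders of two annotated
   genomes are compared as signed circular permutations rotated to COX1;
   in-place reversed blocks are called inversions and features whose
   removal restores collinearity are called translocations.

## The comparative layer

`build_matrices` assembles three matrices from annotated genomes: per-gene
codon-aware CDS alignments (translate under genetic code 4, align the
peptides, back-map the gaps onto codons) concatenated into `CDS_nt` and
`CDS_aa` (the nucleotide matrix is exactly three times as wide), and an
`rDNA` matrix concatenating the 12S alignment with an alignment of the
combined 16S parts. Multiple alignment uses a center-star strategy over
pairwise global alignments (BLOSUM62 with affine 10/1 for peptides;
match 2 / mismatch -3 with affine 5/2 for rRNA) — a deliberately simple
stand-in for a full progressive aligner that is exact whenever sequences
are unequal in length only through isolated indels, which is the regime
these mitogenomes occupy.

`pdistance_matrix` computes uncorrected p-distances under pairwise
deletion: for each pair of rows, columns where either row carries a gap or
a missing state (N for nucleotides, X for amino acids) are excluded and
the distance is the fraction of remaining sites that differ; a pair with
no usable sites is undefined and reported as missing. `percent_identity`
uses the matching convention (identical sites over both-non-gap sites), so
it equals `100 * (1 - p)` on gap-free pairs.

`rank_mean_distances` summarises the matrices across a nested taxonomy:
for orders within classes, families within orders, genera within
families, species within genera and haplotypes within clades, it averages
the distance over all taxon pairs lying in different child groups inside
each parent group, then over parent groups, then (for the grand mean)
over genes, with the concatenated matrix treated as a thirteenth gene.
Averaging is over taxon pairs within each parent — the natural estimator
when group sizes are unequal; parents with a single child yield
not-applicable rather than zero. Summaries are produced over all taxa and
restricted to one class, because a class represented by a single taxon
permits no within-class comparison.

`diagnostic_marker_scan` applies a strict criterion: a gene is diagnostic
at a rank only if its maximum within-group distance is exactly zero while
the minimum between-group distance is positive; undefined pairs
disqualify the gene. On real placozoan data this criterion selects the
NAD3 protein at the genus and clade ranks.

`nj_tree_and_export` produces a neighbor-joining tree (negative branches
clamped to zero, rooted on the chosen outgroup) as an internal check of
the panel structure, and exports relaxed PHYLIP and NEXUS matrices with
partition charsets for external maximum-likelihood or Bayesian inference,
which is out of scope here.

## The synthetic community

`build_panel_genome` generates circular mitogenomes of 32-44 kb with the
placozoan architecture: the 12 protein-coding genes (COX1-3, COB, ATP6,
NAD1-6, NAD4L), an eight-exon COX1 including one 9-20 bp micro exon, a
two-exon NAD5, 12S, a two-part 16S split over four exons, 22 tRNAs and
optionally the accessory ORFs (POLB by default, mirroring its restricted
distribution; LAG and RVT-IM available). Gene order is fixed and known,
every CDS is a clean genetic-code-4 ORF, and intergenic spacers absorb
the remaining length. `derive_haplotype` adds substitutions toward a
target divergence — structural RNAs at half the coding-region rate, to
mimic their conservation — while reverting any mutation that would break
a reading frame, and can plant an inversion or a translocation with
annotations updated. `simulate_library` draws
`round(coverage x length / (2 x read length))` fragments per genome,
uniform on the circle, with 250 bp reads, 400-800 bp inserts and a
configurable substitution error rate (0.5% by default; indels are off by
default, matching the error profile of the 250 bp paired-end chemistry
this emulates), recording every fragment's origin. The host background is
200 random linear fragments totaling 5 Mb: baiting specificity only needs
non-homologous background, not a realistic gastropod genome.

What the simulation does *not* emulate: real coverage unevenness,
adapter read-through chimeras, indel errors, conserved sequence shared
between host and prey mitochondria, and laboratory mitochondrial
enrichment protocols (enrichment is modeled simply as a per-genome
coverage multiplier). Passing tests on this community therefore demonstrate the
pipeline's arithmetic and its haplotype discrimination under the stated
library geometry, not robustness to every artifact of real libraries.

The default study conditions — a 5 Mb host at 30x, three prey mitogenomes
at 40-100x (the enriched regime), a fourth at 0.5x (the non-enriched
regime), mutual prey divergence >= 3% and at most ~10% divergence to the
nearest panel genome — are the conditions under which the acceptance
checks run; the problem sizes were chosen as the smallest community that
still exhibits every phenomenon of interest (host dominance, multiple
mixed haplotypes, coverage starvation).

## Numerical choices and degenerate inputs

* Intervals are 0-based half-open on the forward strand, with circular
  coordinates normalized to `[0, L)`; an exon whose end does not exceed
  its start wraps the origin. Minus-strand features store exons in
  ascending genome order and are reverse-complemented as a whole on
  extraction.
* Start codons ATG and GTG are accepted for table-4 CDS validation
  (common in invertebrate mitochondria); configurable.
* N is legal in genomic sequences (gap fill) but never in simulated
  reads; N codons translate to X, and X/N are missing under pairwise
  deletion.
* All stochastic stages take explicit seeds; the pipeline derives stage
  seeds from one global seed by fixed offsets, so a run is reproducible
  end to end, including FASTQ bytes.
* Empty inputs degrade gracefully: no contigs gives an all-N scaffold of
  completeness 0; a reference that recruits nothing is dropped from the
  report; an alignment pair with no usable sites is NA, never 0.
* The overlap-acceptance rule for merging (>= 99% identity over
  >= 30 bp) and the extension parameters (overlap 50, identity 0.98,
  majority 0.8) are declared defaults, not values inferred from data;
  they are exposed as arguments throughout.

## Known limitations

* The extension step is ungapped; an indel-rich library would need the
  banded aligner in the extension loop.
* tRNA annotation relies on projection through the genome alignment, not
  on secondary-structure models; at high divergence tRNA boundaries
  inherit the reference's uncertainty.
* The rearrangement detector reports in-place inversions and single-gene
  translocations — the events observed in these mitogenomes — and leaves
  more complex permutations unexplained rather than guessing.
* At 0.3% haplotype divergence the assembler cannot separate haplotypes
  with 250 bp pairs; the pipeline's contract is to flag mixed-pileup
  sites and merge conflicts rather than emit silent chimeras, and the
  acceptance suite holds it to that.
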