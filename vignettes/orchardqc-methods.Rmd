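---
title: "orchardQC: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orchardQC: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

orchardQC packages the bespoke post-assembly stages of a haplotype-resolved
plant genome project — the steps that sit between the big external tools
(assemblers, scaffolders, gene predictors, repeat annotators, orthogroup
classifiers) and the published tables. Each stage is small enough to state
precisely, and this vignette is the package's account of exactly what each
one computes, which knobs matter, and where the genuinely open design
choices were resolved.

## Coordinates and containers

All genomic intervals live in `GRanges`/`IRanges` objects, i.e. 1-based,
closed coordinates, the native Bioconductor convention. Conversions happen
only at file boundaries: GFF3 is read and written in its own 1-based closed
columns, BED in its 0-based half-open columns (rtracklayer performs that
shift). Choosing the container's native convention over a bespoke internal
one means every interval operation (`reduce`, `intersect`,
`findOverlaps`) is the battle-tested library code rather than arithmetic of
ours; the observable numbers — GFF3 columns, BED files, overlap base
counts — are identical either way.

A `GeneAnnotation` stores the gene/mRNA/exon/CDS hierarchy with gene spans
*derived* from transcripts (min start to max end). Validity enforces the
structural rules everything downstream relies on: unique ids, resolvable
parents, exons sorted and disjoint within a transcript, CDS contained in
exons, and one seqname/strand per gene. GFF3 feature types other than the
core four (UTR lines and similar) are carried as verbatim text and
re-emitted when their parent survives; they never participate in filtering,
because every curation rule below is defined on coding regions and gene
spans.

## Gene-model curation

Three error patterns recur in merged ab-initio/evidence annotations, and
each gets a rule:

**Type 1 — repeat-derived models.** A transposable element annotated as a
gene. Rule: remove a gene when at least 90% of its *coding region* lies
inside repeat regions. "Coding region" is the union of CDS intervals over
all isoforms — a gene is one locus, so the union, not any single isoform,
is what the fraction is measured on — and repeats are merged before
intersection. The threshold comparison is inclusive (a gene at exactly 0.90
is removed); the threshold is a `curationConfig()` parameter. A gene with
zero CDS bases has no defined fraction; it is logged and treated as 0
(never removed by this rule).

**Type 2 — duplicated models on one strand.** Two overlapping same-strand
gene models usually describe one gene. The rule removes the shorter of an
overlapping pair; to make chains of three or more models deterministic, the
iterative extension removes the *globally shortest* (by span length) gene
that still overlaps another same-strand gene, repeating until no overlap
remains. Ties on length are broken by the larger start, then the
lexicographically smaller id. Overlap is evaluated on gene spans (>= 1 bp):
the error being corrected is two models claiming one locus, and the span is
the locus claim.

**Type 3 — chimeric isoform sets.** Splice variants that share no sequence
are different genes. Within each gene a graph is built on transcripts, with
edges where merged exon footprints overlap by >= 1 bp; each connected
component becomes its own gene (so overlap is transitive through shared
isoforms). Components are numbered left to right and appended to the
original id (`_1`, `_2`, ...). Transcripts are moved, never dropped, so the
transcript count is conserved.

The pipeline applies the rules in the order 1, 2, 3. Splitting cannot
create same-strand overlaps among its own outputs (components of one gene
are disjoint by construction), so no re-iteration is needed and
`curateAnnotation()` is idempotent. The report object carries the count
identity `output = input - removed1 - removed2 - split + created` as a
class invariant.

## Evidence tiers

Each gene is flagged against six evidence sources: full/any RNA coverage,
full/any protein coverage, presence on a functional-annotation id list and
on an orthogroup-assignment id list (both lists are outputs of external
tools; this package never performs database search). "Full" coverage is
measured against the merged exonic footprint (RNA) or CDS footprint
(protein) — spliced evidence cannot cover introns, so footprint coverage is
the only attainable reading of "covering the entire gene" — while "any"
support is >= 1 bp overlap with the genomic span, the most permissive
reading of "covering part of the gene". A gene with no CDS bases can never
be fully protein-supported (the vacuous reading would break
full => any).

The four stringency subsets are pure set algebra on the flags: S1 = full
RNA or full protein; S2 = any RNA or any protein; S3 = S1 plus genes with
both external annotations; S4 = S1 plus genes with either. S1 ⊆ S2, and
S1 ⊆ S3 ⊆ S4; no containment holds between S2 and S3/S4 in either
direction, and none is asserted. The S3/S4 additions are literal set
unions, not restricted to genes with some evidence overlap — the stricter
alternative reading is not what the definitions say.

## Nomenclature

Identifiers follow the Rosaceae community convention
(`drMalDome.wa38.v1a1.ch10A.g00001.t1`): tree-of-life prefix, cultivar tag,
version tag, chromosome token, 5-digit zero-padded gene ordinal, transcript
ordinal. Rendering and parsing are exact inverses, and parsing rejects
malformed tokens by name. Numbering restarts at `g00001` on each
chromosome with step 1, in ascending span-start order — the published
convention shows a single example rather than a full grammar, so per-
chromosome step-1 numbering is this package's recorded choice (both width
and restart behavior are visible in the code and stable under re-running,
which makes renaming idempotent). "Longest isoform" means the largest
spliced (summed exon) length, with ties broken by CDS length and then id —
the transcript-level quantity the downstream single-isoform analyses want,
not the genomic span.

## Orthogroup gene-count QC

Gene counts per orthogroup and genome form an integer matrix; rows with
zero population standard deviation (including all-zero rows) carry no
between-genome signal and are dropped before normalization; remaining rows
are z-scored with the *population* SD (divide by n, the convention of the
common clustermap plotting tools). Row z-scores are invariant to adding a
constant to a row and to positive row scaling, which the property tests
exercise. Clustering order uses average-linkage hierarchical clustering on
Euclidean distances, rows and columns — again the plotting-tool default —
and is deterministic for a fixed input order. UpSet counts classify every
orthogroup by its exact membership pattern, so the categories partition the
union of the sets; "unique to a focal group" means present in every focal
genome and absent from all others.

## Haplome binning by canonical k-mers

Chromosome-scale scaffolds of an F1 individual are assigned to their
parental haplomes by k-mer containment. K-mers are canonicalized
(lexicographic minimum of a window and its reverse complement, k = 21 as
in standard genome k-mer analyses) and stored as exact base-4 numeric
codes — collision-free for k <= 26 and considerably faster to set-operate
on than strings; the string and numeric paths are cross-checked against a
brute-force oracle in the tests.

Two operating modes exist because the published procedure (one parent
sequenced, the other inferred) underdetermines the statistic:

* **two-parent marker mode** (the testable default): scaffolds are scored
  against parent-specific marker sets A∖B and B∖A. Scores are normalized
  by the scaffold's *informative* k-mers — those found in either marker
  set: `score_A = |q ∩ (A∖B)| / |q ∩ ((A∖B) ∪ (B∖A))|`. Plain containment
  of all scaffold k-mers would be bounded by the fraction of windows
  overlapping a variant site (about `1 − (1−d)^k`, only ~25% at d = 1.35%,
  k = 21) and could never produce a decisive margin; normalizing by
  informative k-mers makes a scaffold inherited from parent A score near 1
  at any divergence.
* **single-reference mode**: plain containment against the one available
  parent set, with the call made by thresholding that score.

A call is `ambiguous` exactly when the score margin falls below
`minMargin` (default 0.02) or the informative k-mer count below `minCount`
(default 1000) — both reported per scaffold, so a borderline call is
visible rather than silent.

Chromosome renaming and orientation against a published reference consume
PAF alignment summaries: aligned bases are summed per reference
chromosome, the scaffold is assigned to the argmax if its share reaches
`minAssignFraction` (default 0.5, otherwise unplaced), and orientation is
reversed when minus-strand aligned bases outnumber plus-strand on the
assigned chromosome (ties forward).

## Assembly statistics and telomere scanning

N50/L50 follow the standard definition (sort descending, accumulate to
half the total); GC excludes ambiguous bases from the denominator.
Coverage folds divide total bases by the haploid genome size, with the
printed integer form rounded half away from zero. One caution the tests
document: N50 is *not* monotone under lengthening an arbitrary sequence
(lengths {8,7,1} have N50 8, but growing the 1 to 7 gives {8,7,7} and
N50 7, because the half-total threshold moves too); the property test
asserts a true variant instead.

The telomere scanner examines a terminal window (default 50 kb) at each
end of each sequence and counts, for every unit length from 2 to 20 and
every phase, the maximal run of identical consecutive non-overlapping
words; the best unit per end is reported when it reaches `minCopies`
(default 50). Units are reported as a canonical rotation class — the
lexicographically minimal rotation over the unit and its reverse
complement — so the plant telomere unit is one class whether it is read
as `AAACCCT`, a rotation of it, or its reverse complement on the other
strand. The maximal-tandem-run statistic (rather than a total occurrence
count) is what makes the random-sequence null clean: the expected longest
run of identical adjacent words in random sequence is a few copies, far
below the 50-copy default, while a real telomere array is hundreds. The
published search tool's internal enrichment score is not documented, so
this scheme is the package's own, stated stand-in.

## Plastome quadripartite structure

The canonical plastome layout is LSC–IRb–SSC–IRa with IRa the exact
reverse complement of IRb, so `total = LSC + SSC + 2·IR`.
`detectQuadripartite()` finds the longest pair of exact reverse-complement
repeats at least `minIr` long with non-overlapping placements on the
circle: seed k-mers (default 21) are matched between the forward sequence
and its reverse complement, seed hits are grouped along anti-diagonals
(where `i + j` is constant for a true inverted pair), maximal runs give
the repeat at seed resolution, and character-level extension makes it
maximal. Circularity is handled by doubling the sequence and reducing
coordinates modulo its length, which also makes detection
rotation-invariant; ambiguity symbols terminate extension. Only exact
repeats are sought — the published structures report identical-length IR
arms — and approximate-repeat detection is out of scope. Gene tallies
count per category with a choice of counting every copy (the organelle
convention for multi-copy genes, and the default) or unique names only;
both are exposed because published unique-gene counts and per-category
sums can legitimately differ.

## The synthetic-data generator

The generators define the study conditions; their defaults are fixed, not
tuned:

* background sequence at 38% GC, the GC content typical of pome fruit
  sequencing reads;
* parental divergence 1.35% — the heterozygosity expected of an outbred
  apple cultivar — with substitution-only mutation; the child haplomes
  copy one parent each with a 0.1% residual error rate emulating assembly
  error. Ten chromosomes of 200 kb keep a binning experiment around ten
  seconds while leaving tens of thousands of informative k-mers per
  chromosome;
* the annotated-genome fixture plants, among 20 genes on 2 × 100 kb
  chromosomes by default: three type-1 genes (CDS fully inside a planted
  repeat, fraction 1.0), two near-misses at fraction 0.8004 (which must
  survive the filter), two type-2 pairs (a 901 bp model overlapping a
  2001 bp same-strand model) and one type-3 gene (two isoform clusters
  1.4 kb apart). Gene slots are pitched 4.5 kb apart so planted features
  cannot interact;
* evidence support proportions (default 60% full / 30% partial-only /
  10% none) are realized *exactly* via rounded counts; roles are assigned
  per slot so that the two genes of a type-2 pair share a role and one
  gene's evidence can never leak support onto a differently-labeled
  neighbor;
* telomere arrays (`AAACCCT` × 100) at the 5' end and their reverse
  complement at the 3' end of every chromosome;
* a plastome of LSC 10 kb / SSC 4 kb / IR 1.5 kb with single fixed bases
  at the single-copy region flanks so the planted repeat is maximal and
  its coordinates are recovered exactly rather than within a base or two
  of chance extension.

Every generator runs under a temporary RNG state (`.Random.seed` is saved
and restored), so outputs are byte-identical for a fixed seed and the
callers' RNG is untouched.

What the fixtures deliberately do not model: indels and recombination in
the cross (sufficient for k-mer binning; alignment-level validation would
need them), nested or fragmented repeats, alternative splicing beyond the
planted disjoint clusters, sequencing reads, and Hi-C contacts. Passing
the planted-truth tests therefore demonstrates that the *rules* are
implemented exactly as stated, not that the rules are robust to every
artifact of real annotations.

## Scale of the shipped checks

The test suite and acceptance script run everything at desk scale: oracle
comparisons use 100 random instances per operation, the binning experiment
uses 25 seeds at the 10 × 200 kb condition (about four minutes), and all
other fixtures are sub-second. These sizes are the package's chosen
trade-off between statistical force and a suite a developer will actually
run; all of them are parameters of the public generators, so heavier runs
are one argument away.
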