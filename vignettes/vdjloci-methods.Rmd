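---
title: "Methods and design of vdjloci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of vdjloci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vdjloci` annotates and analyzes somatically recombining T cell
receptor loci: it scans genomic sequence for recombination signal
sequences (RSS), assembles them into typed V/D/J/C gene segment calls,
clusters V segments into families, classifies the completeness and
productivity of V(D)J-recombined transcripts, examines constant-region
transmembrane charge patterns, and builds neighbor-joining trees. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not
emulate.

## Coordinates and sequence conventions

All coordinates are 1-based inclusive, the IRanges/GFF3 convention, so
exported annotations need no conversion. Sequences are plain uppercase
strings over `A/C/G/T/N`; collections are named character vectors.
Minus-strand features are reported in forward coordinates with a strand
flag, and their `sequence` field always holds the coding-strand
(reverse-complemented) sequence.

## Pairwise alignment

Global (Needleman–Wunsch), fit (free end gaps on the reference) and
local (Smith–Waterman) alignments share one affine-gap dynamic program
implemented in C++ (Gotoh's three-state formulation). A gap of length
$L$ costs `gap_open + (L - 1) * gap_extend`. Defaults are match $+2$,
mismatch $-1$, `gap_open` $-4$, `gap_extend` $-1$ — ordinary nucleotide
scoring, exposed as arguments everywhere. Percent identity is defined
as matches over columns where *both* rows are non-gap, and `N` never
counts as a match (a conservative choice that keeps the 80% family
threshold interpretable). Traceback prefers substitution over gap
states on ties, and fit/local end-cell ties resolve to the leftmost
coordinate, making all outputs deterministic.

Fit alignment (full query against the best substring of the reference)
places known constant regions on a locus. Transcript-to-germline
mapping instead uses local alignment, because both ends of a germline
segment may be absent from a transcript (exonuclease trimming at the
junction, 5' truncation of incomplete cDNA); the aligned block's
coordinates on both sequences feed the downstream frame arithmetic.

## RSS model and scanning

The published analyses this package parallels used an external RSS
information-content web tool. Here the scorer is a transparent
position-frequency model: a candidate heptamer/nonamer pair scores
$\sum_i \log_2 (f_i(b_i) / q(b_i))$ bits over the 7 + 9 positions, with
a uniform background $q$ by default and `N` contributing 0. The default
model concentrates mass on the canonical consensus `CACAGTG` /
`ACAAAAACC` (0.85 on the consensus base; 0.94 at the first three
heptamer positions `CAC`, which are functionally the most constrained).
Models can be trained from example sites with pseudocount smoothing, so
rank behavior — consensus above variants above background — is the
contract, not numeric parity with any external tool.

Scanning slides over both strands for every spacer length within
`spacer_class ± spacer_tolerance` (default ±1 around 12 or 23). The
default threshold is 60% of the model's maximum score: high enough
that a 10-kb random sequence yields essentially no hits, low enough to
pass the functional non-canonical heptamer `CACAGCA` with a canonical
nonamer (20.5 bits against a 17.2-bit threshold under the default
model). All overlapping hits are reported; deduplication is the
annotator's job.

## Segment calling

RSS orientation is informative: the signal reads heptamer-then-nonamer
pointing *away* from its coding segment. The caller therefore builds
candidates as:

- **V**: a codon-aligned window of 270–330 nt immediately 5' (coding
  orientation) of a 23-RSS heptamer whose frame-0 translation is stop
  free; the longest qualifying window wins. Reading the "open reading
  window" criterion as frame-0 (codon-aligned at the window start)
  makes the boundary a deterministic function of the sequence, which a
  weaker any-frame reading does not.
- **J**: a window of 30–70 nt immediately 3' of a 12-RSS, ending just
  before the first splice-donor `GT` at a plausible length, and
  containing the F-G-x-G anchor in some reading frame.
- **D**: a window of 8–25 nt between a 12-RSS and a 23-RSS whose away
  sides face each other (12 on the V-proximal side fixes the strand).

Candidates are resolved greedily by descending combined RSS score with
a leftmost tie-break; each heptamer is consumed at most once and
accepted segments never overlap. Because D candidates carry two RSS,
they always outrank single-RSS candidates built from the same hits,
which prevents a D's flanks from being mis-consumed as a spurious V or
J. Dropped conflicts are logged, never silent.

C regions are placed by fit-aligning known C sequences (or transcript
evidence) rather than de novo exon prediction; V segments are modeled
as single exons without leader parts — a documented simplification.
Names follow IMGT style: non-V kinds numbered 5'→3' (`TRBD1`, `TRBJ3`;
a unique C is unnumbered), V segments `TRBV<family>.<member>` with
members numbered 5'→3' within each family. Inversion counting compares
each V's strand with the majority strand of the C segments.

## Families

The percent-identity matrix is computed over all V pairs with the
global aligner on untrimmed nucleotide sequences (no codon-aware
alignment). Families are single-linkage connected components of the
graph with edges at identity ≥ 80% — the weakest reading of "sharing at
least 80% identity", chosen deliberately so that family membership can
only grow as the threshold is relaxed; complete linkage is available
via `method = "complete"`. Labels are canonical: families are numbered
by their 5'-most member's coordinate. Because no external aligner's
guide-tree quirks are reproduced, the contract is the internal identity
definition; the synthetic generator keeps within-family identity well
above and between-family identity well below the threshold, so the test
conditions are insensitive to the exact denominator convention.

## Repertoire classification

Per transcript, the best-scoring local alignment per germline kind at
≥90% identity is assigned (ties keep the first-listed germline entry,
with a note). V/J/C matches must appear in 5'→3' order on the
transcript; trailing trimmed query ends may legitimately overrun a few
nucleotides into the junction when the junction happens to continue the
germline sequence, so the order test compares span order rather than
demanding strict non-overlap, and the junction boundary inherits that
few-nt ambiguity (segment calls and frame arithmetic do not).

Definitions: *complete at the 5' end* means the V alignment starts at
germline position 1 and covers ≥95% of the germline V (the qualitative
"complete enough" criterion made operational; note this requires
junction trims to stay below ~5% of V length, which the default trim
maxima respect). *In frame* means the V and C "virtual starts" (the
transcript coordinate of germline position 1, extrapolated from the
alignment anchors) differ by a multiple of 3 — this is robust to 5'
truncation, which shifts both anchors equally. *Has stop* scans the
V-frame translation from the V alignment start through the end of the
J alignment; stops inside C are not evaluated, and D evidence (longest
exact junction substring ≥8 nt) never affects productivity.
*Productive* requires complete ∧ in frame ∧ no stop; this implication
is asserted on every output. Percentages are rounded half-up to one
decimal.

## Chain features

Transmembrane detection is a Kyte–Doolittle sliding window, not a
reimplementation of any neural predictor: the 19-residue window with
maximal mean hydropathy (leftmost on ties) is called a TM if its mean
is ≥1.5, then extended one residue at a time on whichever side has the
higher positive hydropathy, up to 25 residues. Chains are classified by
the charged residues inside the TM: both Arg and Lys → `RK`, Lys only →
`K_only`, otherwise `none`; heterodimer pairing is predicted compatible
exactly for the asymmetric `{RK, K_only}` pattern. Classification is by
presence within the detected TM, not by absolute alignment position,
since the published alignment coordinate for the conserved Lys is not
reconstructible here.

## Phylogenetics

p-distances use pairwise gap deletion (a pair with no comparable
columns is an error), with no substitution-model correction by default
— a deliberate choice given that the downstream use is topology and
support, not branch-length interpretation. Neighbor joining is the
classic Saitou–Nei agglomeration with the standard branch-length
formulas, negative lengths clamped to zero, and ties in the Q criterion
broken by lexicographic order of the joined clusters' smallest taxon
labels, so results are reproducible across input orderings. Bootstrap
resamples alignment columns with replacement; supports are the
percentage of replicate trees containing each internal bipartition of
the full-data tree (replicates that produce an incomparable pair are
redrawn). Trees are ape `phylo` objects; the Newick writer emits full-
precision branch lengths, supports as internal labels, and quotes
labels containing spaces or metacharacters.

Reproducing published clade placements for real V-segment sets would
require the underlying sequence downloads and is inherently
topology-fragile; the correctness contract is exact recovery on
additive matrices (verified against exhaustive topology enumeration in
the test suite) and deterministic, well-calibrated bootstrap behavior
on planted clades.

## Synteny

Flanking-gene comparison matches genes by case-insensitive name with a
user-supplied alias table (for cross-species naming variants); no
sequence-homology matching is attempted. Distances between designated
flankers are boundary-based — end of the upstream gene to start of the
downstream gene, orientation-normalized — since midpoint-based
conventions are not obviously better and boundary-based is the
conservative reading.

## The synthetic-data generator

The generator emits the canonical locus architecture — V(23-RSS) ×
families, D(12-RSS/23-RSS), J(12-RSS, splice-donor `GT`), C with a
planted transmembrane exon carrying a single Lys, optional inverted V
segments 3' of C — with i.i.d. uniform intergenic sequence (no repeat
structure), uniform gaps of 150–400 bp, and byte-reproducible output
given (config, seed). Defaults mirror a skink-like TRB locus: 15 V in
8 families with one inverted, 3 D (the first carrying the conserved
`GGGACAGGGGGC` core), 6 J, one C.

Three constructions make planted boundaries sequence-identifiable, so
the annotator can be held to exact-coordinate recovery:

- each V is a codon-aligned stop-free reading frame preceded by an
  11-nt all-frame stop guard (`TAAATAAATAA`), which closes every longer
  candidate window;
- each J is built from GT-free codons with the F-G-x-G anchor encoded
  near its 3' end, so the first plausible splice donor is the planted
  one;
- family members are derived from prototypes by substitution-only
  mutation (no indels), with the substitution count set to hit the
  within-family pairwise identity target (±3 points, verified) and
  prototypes regenerated until below the between-family ceiling —
  infeasible targets fail loudly rather than silently degrade.

The repertoire simulator draws V/D/J uniformly (a D is always used when
present, per the 12/23 rule; direct V–J joins are opt-in), trims each
coding end uniformly up to the configured maxima, and inserts uniform
N additions. The configured completeness and productive fractions are
realized *exactly* (up to rounding) by stratified allocation over
transcripts rather than independent coin flips: frame-preserving
junctions are additionally resampled until stop free, so
`target_frame_fraction` *is* the productive-of-complete fraction, and
estimator checks are not confounded by binomial noise in the generator
itself. Incomplete transcripts are truncated within V (15–50% of its
length). Truth flags are computed by construction and cross-checked in
the test suite by an independent frame-arithmetic and stop-scan
implementation.

What the generator does not emulate: sequencing error or read-level
artifacts (inputs model assembled transcripts), leader exons and
introns, pseudogene decay, repeat-rich intergenic DNA, biased trim or
N-addition distributions (real junction diversity parameters for
squamates are unreported; the uniform defaults are placeholders), and
ClustalW/MUSCLE-specific alignment behavior. Passing tests therefore
demonstrate the pipeline's internal correctness and its behavior under
the stated statistical structure, not performance on raw genome
assemblies.

## Problem sizes and determinism

The shipped test and acceptance conditions use: 20 loci spanning 2–20 V
(0–5 inverted), 0–3 D, 1–6 J, 1 C; family recovery on 50 V segments in
10 families across 10 seeds; 5 × 500 simulated transcripts at the
52.6% / 80% composition; neighbor-joining recovery on additive matrices
of 4–6 taxa against exhaustive topology enumeration; bootstrap with
100–1000 replicates. Every stochastic step takes an explicit seed
(`withr::with_seed` isolates generator RNG from the session), and the
pipeline writes a manifest with parameters, seed and input/output
checksums so a run can be reproduced byte for byte.

## Known limitations

- V segments are single exons; loci with leader exons will need
  transcript evidence for exact 5' boundaries.
- The completeness criterion ties V-alignment coverage to the germline
  V's first nucleotide; heavily 5'-degraded but recombined transcripts
  are conservatively called incomplete.
- The RSS scorer contracts rank behavior, not parity with any external
  information-content tool.
- `align_progressive()` is a simple anchor-based stacking aligner,
  adequate for closely related segment sets; it is not a general MSA
  and amino-acid columns are scored with the nucleotide match/mismatch
  scheme.
- Haplotype reconciliation (e.g. segment-count differences between
  pseudohaplotypes) is out of scope.
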