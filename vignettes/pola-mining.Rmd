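---
title: "Mining and classifying Family A DNA polymerases with polascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and classifying Family A DNA polymerases with polascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polascreen)
```

## The scientific problem

Family A DNA polymerase (PolA) is the primary replication enzyme of many
double-stranded DNA phages. Mutagenesis work on the *E. coli* and T7
enzymes established that the O-helix residue at position 762 (*E. coli*
numbering) tunes the polymerase's kinetics: the wild-type phenylalanine,
a faster and more processive tyrosine variant, and a slower but more
accurate leucine variant. In viral metagenomes all three variants are
abundant, and the variant a phage carries correlates with its replication
ecology — Tyr762 PolAs co-occur with fast ring-shaped gp4 helicases on
lytic-type genomes, while Leu762 PolAs travel with SNF2/UvrD/RecB-D-type
helicase genes typical of temperate phages.

`polascreen` implements the mining side of that research program as a
reusable, fully tested pipeline: find PolA candidates in protein
collections, validate their active sites, classify them at position 762,
reduce redundancy, place them on a residue-annotated phylogeny, and
quantify their helicase gene neighborhoods. Every stage that a production
study would delegate to a large external tool (MMseqs2, Clustal
Omega/MAFFT, FastTree/IQ-Tree) is replaced here by a small, deterministic,
oracle-testable equivalent; the substitutions are named in every pipeline
report and discussed below.

## Signature validation

A candidate is validated against a packaged 928-residue PolA reference by
global affine-gap alignment. The residues aligned to the reference's
positions 688, 705, 758 and 762 are extracted; the candidate passes when
688 = R, 705 = D, 758 = K and 762 ∈ {F, L, Y}. Two deliberate design
choices:

* **A gap at any anchor fails validation.** A missing catalytic residue
  cannot validate an active site, so `"gap"` is recorded and the sequence
  is rejected (its 762 class is still reported for diagnostics).
* **A score floor (default 0) guards against coincidence.** An unrelated
  sequence can, in principle, present the four anchor letters by chance;
  requiring a positive global alignment score against the reference
  removes such decoys. The floor is configurable in
  `signature_scheme()`.

Because classification is per-sequence (pairwise to the reference, not
through a joint MSA), the partition of a batch is independent of input
order — a property the tests assert directly.

The packaged reference is a **synthetic stand-in**: a random protein of
the correct length with the canonical anchors planted at the correct
positions and the Klenow-like polymerase domain defined as residues
324–928 (the 5'→3' exonuclease domain of the genuine enzyme occupies the
first 323 residues). The genuine UniProt entry is not redistributed with
the package. For classification of real data, supply the genuine
reference to `signature_scheme(reference = ...)`; all numbering
conventions are identical.

## Alignment engine

Global (Needleman–Wunsch) and local (Smith–Waterman) alignment are
implemented once, in compiled code, with Gotoh's three-state affine-gap
recursion. Scoring uses Biostrings' packaged substitution matrices
(default BLOSUM62) with gap open −11 and extend −1, a gap of length *k*
costing `open + (k−1)·ext`. Numerical/determinism choices:

* Terminal gaps are scored in global mode (true global alignment); the
  coverage fields capture end effects instead.
* Traceback ties are broken deterministically: diagonal over gap-in-query
  over gap-in-reference.
* `identity` divides identical pairs by *all* alignment columns (gaps
  included); `coverage` of each side is the aligned span over that
  sequence's full length. These are the "75% identity over 80% coverage
  of query and target" semantics used by the clustering stage, and the
  denominator choice is recorded in every pipeline report header.

The implementation is checked against an exhaustive-recursion oracle on
short sequences (≤ 12 residues, every run of the test suite) and against
the forced-structure and symmetry properties of the algorithm.

## Filtering, clustering, subsampling

Thresholds are inclusive (`≥ 400` aa length, hit span `≥ 325` aa, e-value
`≤ 1e-10`, model `cl02626`), matching their "at least / greater than or
equal to" definitions. E-values are consumed metadata from the hit table,
never computed. When several significant hits cover a sequence, trimming
keeps the longest (ties to the smaller start coordinate).

Clustering is single-pass greedy (CD-HIT style): records sorted by
decreasing length then id; each joins the first representative (creation
order) it matches at 75% identity / 80% two-sided coverage by local
alignment, else founds a cluster. A production study would use cascaded
MMseqs2 clustering with reassignment; the greedy variant is deterministic,
desk-scale and is verified against a brute-force oracle at n ≤ 10.
Sorting first makes the partition invariant under permutation of the
input.

Subsampling draws `min(n, stratum size)` representatives per
(source, 762-class) stratum, default n = 225. Strata are processed in
lexicographic order and ids sorted before sampling, so one seed yields
one sample on any platform.

The pipeline applies stages in the order classify → length → domain →
trim → cluster → subsample. Length/domain filtering before clustering
(rather than annotating cluster representatives afterwards) keeps every
stage's ledger attribution exact; on data where filters remove whole
sequences rather than cluster structure the two orders retain the same
final set.

## Phylogeny

The MSA is *reference-anchored*: each trimmed sequence is pairwise-aligned
to the reference domain and projected onto its columns, discarding
insertions relative to the reference. This fixes the column space to
*E. coli* numbering — the same convention as the anchor screen — at the
cost of ignoring insertion-borne signal, which is acceptable for the
within-family divergences the pipeline targets.

Distances are p-distances (mismatches over shared non-gap columns); pairs
sharing fewer than `min_shared_columns` (default 100) columns raise an
error rather than emitting a noisy distance. Trees are built with
neighbor joining (Saitou–Nei, via ape), which is exact on additive
matrices — a property the suite verifies by round-tripping random 4–8
taxon trees through their cophenetic distances. Negative NJ branch
lengths are clamped to zero and the clamped deficit kept as an attribute.
Approximate-ML inference (FastTree/IQ-Tree) is deliberately not
reproduced; clade-level conclusions in this package are only ever
asserted on synthetic data, where the planted truth is known.

Rooting places the root at the midpoint of the reference's pendant edge;
the unrooted bipartition set is unchanged (asserted in tests). Bootstrap
support is a plain column bootstrap: resample columns with replacement,
rebuild the NJ tree, report the fraction of replicates containing each
bipartition — a lightweight stand-in for ultrafast-bootstrap/SH-aLRT
statistics.

Monophyly of each 762 class is reported as: MRCA clade size, intruder
count, verdict (monophyletic ⇔ zero intruders), and the number of maximal
all-intruder subtrees (how many clade excisions would restore
monophyly). Classes with fewer than two leaves are monophyletic by
convention and flagged. The checker is verified against exhaustive clade
enumeration on trees with ≤ 10 leaves. Groups observed paraphyletic in
real data are thus described by their intruder metrics rather than by a
categorical para/polyphyly label.

## Gene neighborhoods and replication rates

Helicase classification is a fixed case-insensitive keyword lexicon
(gp4, DnaB, SNF2, UvrD, RecB/D) over free-text product annotations —
deliberately not homology-based. "Association" is operationalized as
same-contig presence, with the signed ORF offset of the nearest helicase
reported (ties broken upstream); metagenomic contig fragmentation makes
any fixed window arbitrary, so none is imposed. Percentages are integers
rounded half-up, the convention that reproduces printed association and
production-success percentages exactly from their fractions (7/9 → 78%,
9/14 → 64%, 20/26 → 77%, 13/16 → 81%, 15/17 → 88%).

The replication-rate operation is closed-form arithmetic:
`genome_bp × burst / (latent_min × fraction) / 1000` kb/min, with
`fraction = 0.8` modelling replication consuming 80% of the latent period
(every rate then scales by exactly 1.25). `replication_rate_report()`
computes the canonical T7 / lambda / *E. coli* comparison; where a
computed value disagrees with the conventionally quoted one (T7 computes
to ≈ 422.9 kb/min against the quoted ~425, a 0.5% gap; the T7:lambda
ratio computes to ≈ 2.6 against the quoted 2.5×) the report **flags** the
row and keeps the computed value.

## The synthetic-data generator

`generate_family()` evolves the reference domain along a hierarchical
guide tree: reference → class ancestor (between-clade divergence, default
0.35 substitutions/site) → clade ancestor (one third of that, within the
class) → member (within-clade divergence, default 0.02). Substitutions
are uniform over the 19 alternative residues; anchors are protected
unless `anchor_mutation_prob` fires; indels (default rate 0.005/site,
mean length 3) never touch a ±5 window around the anchors. The default
clade layout — two Phe clades (13 + 13), two Leu clades (7 + 7), one Tyr
clade (9) — plants the 26/14/9 class composition of a realistic
synthesis panel while exercising the multi-clade-per-class case, and the
hierarchical nesting makes every 762 class monophyletic in the planted
truth. Decoys violate exactly one stage each: a < 400 aa fragment still
containing the anchors (length filter), an intact sequence whose hit row
carries e-value 1e-5 (domain filter), a broken catalytic anchor, or a
fully random sequence (signature screen). Synthetic e-values are fixed
constants (1e-50 pass / 1e-5 fail) because e-values are consumed, not
modelled.

`generate_contigs()` plants one 11-ORF contig per polA locus with the
polA central and, per a row-stochastic association matrix (defaults set
to the observed per-class helicase frequencies: Tyr → gp4 7/9,
Leu → SNF2 9/14 and RecB/D 1/14, Phe split SNF2 9/25 / DnaB 7/25), a
helicase ORF at a random offset of ±1–5. An explicit assignment vector
overrides the randomness for exact fixtures.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: realistic substitution processes (no
rate matrix, no site heterogeneity), insertion-borne phylogenetic
signal, homologous-but-non-PolA families near the domain-model boundary,
contig fragmentation and annotation noise, or genuine e-value behavior.
The pipeline's recovery guarantees are statements about its internal
consistency under planted truth, not about sensitivity/specificity on
viromes.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on
families of ~50–60 sequences (five clades plus eight decoys), clustering
oracles at n = 10, NJ consistency at 4–8 taxa, monophyly enumeration at
10 leaves, and bootstrap at 100 replicates over a 16 × 300 alignment —
sizes chosen so the whole battery completes in well under a minute while
exercising every code path at full depth. All randomness flows through
explicit seeds; generators save and restore the global RNG state, and
identical seeds produce byte-identical outputs (asserted in tests).

## Known limitations

* The signature screen is pairwise, not MSA-based; on real data a
  profile-based screen will be more sensitive at high divergence.
* p-distance NJ underestimates deep divergences (no multiple-hit
  correction); the tree stage is intended for desk-scale structure, not
  publication phylogenetics.
* Non-canonical residues (B, Z, J, U, O) are accepted as X with a
  warning, since their treatment in upstream screens is generally
  unspecified.
* The helicase lexicon matches annotation text only; unannotated or
  renamed helicases count as absent, so association percentages are
  lower bounds on real data.
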