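---
title: "Methods: RIP scanning, orthology, phylogenomics and expression quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RIP scanning, orthology, phylogenomics and expression quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures the package implements,
the parameters that matter, what the synthetic-data generators emulate (and
what they do not), and the numerical and design choices made where the
design was genuinely open.

## RIP relic detection

Repeat-induced point mutation (RIP) is a genome-defense process of
filamentous ascomycetes that hypermutates duplicated sequence, converting C
to T preferentially in CpA context on either strand (a CpA on the reverse
strand appears as TpG on the forward strand). Because the mutation converts
CpA substrates into TpA products, its relic is compositional and can be read
from dinucleotide ratios long after the event:

* product index = TpA/ApT — rises as TpA is produced; ApT normalizes for AT
  richness;
* substrate index = (CpA+TpG)/(ApC+GpT) — falls as substrates are consumed.

Both index numerators and denominators are reverse-complement-closed sets
({TA}/{AT}; {CA,TG}/{AC,GT}), so the indices are strand-symmetric; strand is
therefore ignored everywhere in the scanner, and the property is asserted in
the test suite.

**Windows and thresholds.** Indices are computed over whole sequences and in
sliding windows of 500 bp and 200 bp with 100 bp shifts. RIP regions are
called in the 200/100 windows with product index ≥ 0.89 and substrate index
≤ 1.03 — the conventional calibration for these indices, with both bounds
inclusive (verified exactly at 0.89 and 1.03 on constructed sequences).
These thresholds were calibrated on real fungal genomes; on i.i.d. random
sequence near 50% GC the expected product index is ~1 and the substrate
index ~1, so an appreciable background window rate is expected on synthetic
genomes (see "What the generators emulate" below).

**Numerical choices.**

* Trailing partial windows are dropped: only full-length windows are scored,
  because index variance explodes as windows shrink and fixed window sizes
  keep rows comparable.
* Dinucleotide pairs containing N are excluded from numerator and
  denominator alike (positions still advance), so ratios are not biased next
  to assembly gaps; AT content likewise excludes N from its denominator.
* A zero denominator makes the ratio *undefined* (`NA`), never 0, and an
  undefined index can never satisfy a threshold: a window of, say, pure CG
  repeat carries no evidence either way.
* The per-genome RIP fraction is the union of RIP-positive windows in
  covered bases divided by total sequence length, aggregated over contigs
  before dividing (length weighting). Counting positive *windows* instead is
  exposed as an option (`mode = "windows"`), since either reading of a
  "fraction of the genome RIP-positive" statement is defensible.
* Per-class summaries pool dinucleotide *counts* across a class's extracted
  intervals rather than concatenating sequences, so no artificial junction
  dinucleotides are counted. Pooling counts (rather than averaging
  per-sequence indices) weights each interval by its length, which matches a
  whole-class ratio.

**Feature classes.** The scanner is reported over whole genome, coding
regions, non-coding regions, exons, introns, multigene-family spans, and
repeats. Two interpretation choices were open: "coding" is taken as the CDS
union (not whole transcripts), and "non-coding" as the complement of gene
spans (i.e. intergenic sequence) — the class list names introns separately,
which implies non-coding means intergenic. Internal coordinates are 0-based
half-open everywhere; GFF3 (1-based closed) is converted at the boundary and
BED passes through unshifted.

## Homology filtering, BBH orthology, families and categories

All-vs-all protein search results enter as the standard 12-column tabular
format extended with query/subject lengths. A hit is *homologous* when
E ≤ 1e−5, identity ≥ 30%, and the alignment length covers ≥ 60% of **both**
protein lengths; all bounds inclusive. Coverage uses the reported alignment
length including gap columns — the only reproducible choice given tabular
input. Self-hits are dropped and reciprocal presentations of one alignment
collapse to an unordered pair keeping the best-scoring record.

*Orthologs* are bidirectional best hits (BBHs) per genome pair: each gene's
best cross-genome homolog by bitscore, ties broken by lower E-value, then
higher identity, then lexicographically smaller partner id — a fully
deterministic rule, so output is invariant to row order and to how each
alignment is presented.

*Multigene families* are single-linkage transitive closures: connected
components of the filtered homology graph, components of size ≥ 2 counting
as families, ids assigned by smallest member id. Closure-based expansion
from a seed set (union of the components touched by any seed) supports
growing a candidate gene list, e.g. pathogenicity candidates identified by
best-hit annotation against a reference database.

*Categories.* With genomes labeled focal/pathogen/non-pathogen, each focal
gene is classified from its BBH presence pattern: orthologs in ≥ 1 pathogen
and ≥ 1 non-pathogen genome → `shared_both_groups`; only pathogen →
`with_pathogen`; only non-pathogen → `with_nonpathogen`; none → `specific`.
"Found in all genomes" is deliberately read as "present in both groups"
rather than literally all genomes — only that reading makes the four
categories a partition of the proteome, and the partition identity
(category counts summing to proteome size) is asserted structurally on
every input. Category membership uses BBH orthologs, not arbitrary filtered
homologs.

## Phylogenomics

Universal single-copy ortholog groups are selected by the *clique*
criterion: one gene per genome such that every pair of members is a BBH in
its genome pair. The clique rule is stricter than connected components and
guards against paralog chaining; the relaxed component criterion remains
available behind `clique = FALSE`.

Per-group alignments are consumed pre-aligned (alignment itself is out of
scope) and concatenated in sorted group order into a supermatrix with
recorded group boundaries. Distances are p-distances — mismatches over
compared columns — with *pairwise deletion* of columns containing a gap or
ambiguity in either row (complete deletion available as an option); this is
the simplest defensible choice absent guidance, and a pair with zero
comparable columns is an error rather than a fabricated distance.

Neighbor joining follows the classic Saitou–Nei agglomeration on the
Q-criterion. Ties on Q are broken by the lexicographically smallest sorted
pair of representative labels (the smallest leaf label under each active
node), making degenerate inputs deterministic. Branch lengths use the
standard two-point formulas; negative estimates — a routine artifact of
distance noise — are clamped to zero with a warning. The tree is emitted as
Newick text (17 significant digits, so the 1e-9 additive-recovery guarantee
in the tests is unaffected) and materialized as an `ape` `phylo` object. On
additive matrices NJ is consistent: the test suite checks exact topology
recovery and path-length reproduction on random trees of 4–8 taxa, plus
agreement with an independent NJ implementation.

## Expression quantification

qPCR fold changes use 2^−ΔΔCt with an internal reference gene (18S rDNA in
the original assays): ΔCt = mean Ct(target) − mean Ct(reference) within each
condition, ΔΔCt = ΔCt(treatment) − ΔCt(control). Replicate Ct values are
averaged *before* differencing (the formula is written on Ct means); a
per-replicate mode that averages ΔΔCt over replicate pairings is available
and agrees with the mean form on balanced designs. Two identities pin the
implementation: swapping condition labels returns the reciprocal fold
exactly, and shifting all Ct values of one condition (both genes together)
leaves the fold unchanged — the reference-gene normalization property.

Differential protein spots: fold = mean(treatment)/mean(control) per spot,
called `up` at fold ≥ 1.5 and *P* < α, `down` at fold ≤ 1/1.5 and *P* < α
(α = 0.05). The original spot analysis does not name its test; a two-sided
Welch (unequal-variance) t-test on log intensities is used as a documented
stand-in, and log-scale testing makes calls invariant to global intensity
rescaling. No multiple-testing correction is applied by default, mirroring
raw *P* < 0.05 reporting; a `p_adjust` argument exists for stricter use.

## What the synthetic generators emulate — and what they do not

All generators are pure functions of their parameters plus a mandatory seed.

* `random_genome` draws i.i.d. residues at a chosen GC content.
* `plant_repeats` writes one random master sequence over non-overlapping
  positions (a slack-placement scheme guarantees non-overlap
  deterministically), returning ground-truth intervals.
* `simulate_rip` mutates C→T at forward-strand CpA sites and G→A at
  forward-strand TpG sites (CpA on the reverse strand) with a common
  per-site rate, inside target intervals only. Sites are evaluated against
  the pre-mutation sequence in a single pass, so overlapping contexts do not
  cascade and the result is order-independent. This is a deliberately
  minimal model — CpA context only, no iteration over sexual cycles, no
  other mutation classes — sufficient to validate the detector's direction
  of response (product index up, substrate index down, monotone in the
  rate).
* `simulate_hit_table` plants ortholog sets with chosen presence patterns
  (emitted as full hit cliques above all filter thresholds), family chains
  within the focal proteome, and decoy hits that each violate *exactly one*
  filter, so every filter branch is exercised independently.
* `simulate_ct` inverts the ΔΔCt formula (reference gene fixed, target
  shifted by −log2(fold) in the treatment) plus Gaussian cycle noise;
  `simulate_spots` draws log-normal intensities around condition means.

The generators do **not** emulate real genome evolution: no indels,
transposons, codon structure, GC heterogeneity or alignment error, and the
i.i.d. background means absolute RIP-positive rates on synthetic genomes are
higher than on real fungal genomes (where the 0.89/1.03 calibration was
set). Passing tests therefore demonstrate correctness of the computations
and recovery of planted signal against the generator's background — not
that any particular real genome is one-third RIP-positive, which depends on
the genome and on unpinned external resources.

## Problem sizes and defaults

The analyses and checks run at desk scale by choice: 100 kb genomes with
five 2 kb repeat copies for RIP recovery (20 replicate genomes, mutation
rates 0.3/0.5); five genomes (one focal, two pathogen, two non-pathogen)
with 40 category-planted genes, four planted families and twelve decoys for
the orthology stages; 100 random additive matrices of 4–8 taxa for NJ;
100-spot tables with ten planted 4-fold spots and 3–4 replicates for the
expression stage. Defaults throughout equal the printed analysis settings:
windows 500/200 bp with 100 bp shifts, thresholds 0.89/1.03, filter
1e−5/30%/60%, fold threshold 1.5, α 0.05.

## Known limitations

* p-distance only; model-based corrections (Poisson, JTT) are an extension
  point, as are ML/MP trees and bootstrap support, which belong to external
  tools.
* The sequence search producing hit tables, multiple alignment, gene
  prediction and repeat discovery are consumed, not produced.
* Reference-database annotation is a generic best-hit operation; database
  content and versioning are the user's concern.
* The spot-calling P-value is a stand-in test on log intensities; with ~3
  replicates its power is limited and the Monte-Carlo recovery check sets
  expectations accordingly.
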