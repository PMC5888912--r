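---
title: "Methods: tree-based orthology identification and the duplication census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree-based orthology identification and the duplication census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrthoCensus)
```

## The problem

Given a gene family sampled across many genomes, we want to know (i) which
genes form a reliable orthogroup — a clade of homologous genes descending
from a single ancestral gene — and (ii) where on the species phylogeny the
gene duplications that expanded the family took place. OrthoCensus
implements a semiautomated two-step procedure for this task, oriented
towards deuterostome comparative genomics: candidate homologs are screened
from precomputed similarity hits, a codon alignment is assembled and
filtered, a neighbor-joining (NJ) gene tree with bootstrap supports is
built, the tree is rooted and its weakly supported regions are rearranged
against a reference species tree under duplication–loss parsimony, the
orthogroup is accepted or rejected by the bootstrap support of a *key node*
(the separation of ingroup from outgroup genes), and finally orthologs and
duplications are counted per species and per species-tree branch.

The packaged reference tree (`speciesTreeFixture()`) covers thirteen
deuterostome genomes from all five major lineages — two hemichordates,
three echinoderm assemblies, two cephalochordates, four urochordates, two
vertebrates — plus a protostome outgroup clade (*Drosophila*,
*Caenorhabditis*). The exact outgroup genome set behind the transcribed
ortholog table is not recoverable from the published material, so the two
classical protostome model organisms stand in; the outgroup set is a
constructor argument.

## Stage by stage

### Similarity screen

`filterHits()` retains subjects with an E-value **strictly below**
`eCutoff` (default `1e-3`; the strict comparison mirrors the printed
"<10^-3" convention). Where several transcript variants exist for a locus,
`selectLongestVariant()` keeps the longest CDS, breaking ties by the
lexicographically smaller transcript id (the tie-break is our choice; the
selection rule itself only says "longest"). A hit-count cap (`maxHits`) is
available but off by default: whether a top-N cut preceded the E-value
screen in the original protocol is unknowable from the text, so the
E-value screen alone is the default behaviour.

`kmerSimilaritySearch()` is a deliberately simple shared-k-mer ranking
whose emitted E-value is a monotone transform (`10^-shared`) of the number
of distinct shared k-mers. It is *synthetic*: it exists so that end-to-end
runs on simulated data need no external search binary, and it is labelled
as such throughout. Real analyses should import BLAST `outfmt 6` tables
via `readHits()`.

### Codon alignment preparation

Protein alignments are inputs (from any aligner); the simulator produces
gap-free true alignments, so the aligner is not needed for testing.
`backtranslate()` forces each CDS onto its aligned protein row, codon by
codon, trimming one trailing stop codon and flagging (not discarding)
sequences with internal stops — simulated sequences evolve unconstrained
by the genetic code, so occasional in-frame stops are expected and benign.

`trimGappyColumns()` works at whole-codon granularity so that codon
structure survives trimming. The default heuristic is gappyout-style: codon
columns are scored by gap fraction, the distinct gap fractions define the
gap-score distribution, and the cut is placed at the steepest slope of
that distribution (largest drop in gap fraction per column mass); columns
above the cut are dropped. Because the decision is recomputed from all
columns, trimming is idempotent. Whether the original protocol trimmed
protein or nucleotide columns is unstated; codon-column granularity is our
documented choice, with a plain `maxgap` fraction cutoff as a configurable
fallback. "Unambiguously aligned sites" are interpreted as the retained
(post-trim) columns.

`applyLengthFilter()` removes sequences whose residue coverage over
retained columns is strictly below `lengthFraction` (default 0.55) of the
query's coverage: a sequence at exactly 55% survives. The query always
survives. `selectCodonPositions()` yields the `Exc3rd` (positions 1+2,
the default) or `Inc3rd` site matrices; `Inc3rd` is a manual switch meant
for short queries or within-lineage analyses.

### NJ trees and bootstrap

`tn93Matrix()` evaluates the Tamura–Nei (1993) closed-form distance per
pair, with **pairwise deletion** of sites containing a gap or ambiguity in
either sequence and with the empirical base frequencies of the pair. Two
numerical guards: a non-positive logarithm argument (saturation) caps the
distance at 5.0 and flags the pair invalid rather than returning NaN, and
pairs with fewer than 20 comparable sites are flagged invalid. `njTree()`
(backed by `ape::nj`, the implementation the original analysis itself
used) refuses invalid pairs by name; negative branch lengths are clamped
to zero with the deficit added to a sibling branch, a standard cosmetic
repair that never changes the topology.

`bootstrapSupport()` resamples **whole codons** with replacement by
default (single sites via `resampleUnit = "site"`): the alignments are
codon-structured and resampling the codon preserves within-codon rate
structure. Each internal edge of the point-estimate tree is scored by the
percentage of replicates containing its bipartition
(`ape::prop.clades`). Degenerate replicates (all sequences identical, or
saturated pairs) are skipped with a warning and the denominator adjusted.
Everything is deterministic given `rngSeed`.

### Reconciliation, rooting, rearrangement

`lcaReconcile()` maps each gene-tree node to the species-tree MRCA of its
descendants' species. A node mapping onto the mapping of one of its
children is a duplication; losses accrue on the species branches skipped
along each gene-tree edge (one extra at the duplication node itself, since
the second copy must be lost on the off-path side). With
`dupCost = lossCost = 1` — equal parsimony weights, the package default —
the reported cost is exactly `D + L`, and the LCA reconciliation is the
parsimony optimum over event histories for the given rooted topology. The
test suite verifies this against an explicit enumeration of all event
histories on hundreds of random instances.

NJ trees are unrooted, and no rooting convention is stated in the protocol
this pipeline reproduces; `rootByDL()` therefore evaluates every edge as a
root position and keeps the duplication–loss-minimal rooting. Ties are
broken deterministically: higher support on the root-adjacent edge first,
then the lexicographically smallest leaf-label string of the smaller root
child.

`rearrangeWeakNodes()` rearranges only where the data are weak: internal
edges with support below `supportThreshold` (default 70; edges at exactly
70 are fixed) form maximal connected weak regions. All resolutions of each
region's boundary subtrees are explored — exhaustively up to
`exhaustiveLimit = 7` boundary subtrees ((2k−3)!! = 10,395 topologies at
k = 7), by seeded greedy nearest-neighbor-interchange hill climbing with
random restarts beyond that. Strongly supported edges are never altered,
the returned tree never costs more than the input, and among cost optima
the tree of minimal Robinson–Foulds distance to the input (then the
lexicographically smallest) is chosen, so rearrangement is conservative
and deterministic. Edges created by rearrangement carry a `rearranged`
flag and no support value. The exhaustive/greedy split trades completeness
for desk-scale runtime; the exhaustive regime is pinned against an
independent enumeration oracle in the tests.

### Orthogroup acceptance and the census

`keyNodeSupport()` finds the smallest clade containing every ingroup gene
and no outgroup gene (for the packaged fixture: deuterostome vs protostome
genes) and returns its subtending-edge support; paraphyly yields 0, as
does a key edge whose support was consumed by rearrangement.
`acceptOrthogroup()` accepts at support ≥ 70 — the boundary is inclusive,
consistent with the rearrangement threshold's semantics, and
configurable.

`countOrthologs()` tallies members per species (zero-filled);
`placeDuplications()` adds one count to the species-tree branch
immediately above each duplication node's mapping, so branch counts sum
to D. `lineageAggregate()` reports per-lineage ortholog averages
(arithmetic means of member-species totals) and splits duplication counts
into *peripheral* (branches strictly inside a lineage crown group,
terminals included) and *ancestral* (lineage stems; deeper branches are
reported under the label of the lineages they span). Because the
aggregation convention behind published per-lineage duplication figures
is not recoverable, both the plain sum and the per-family average are
reported. The two *Acanthaster* assemblies are two census rows and both
enter the echinoderm average, as in the transcribed table.

The packaged `muscleOrthologTable()` is a transcription of a published
family-by-species ortholog count matrix (16 paraxial-muscle gene families
by 13 deuterostome genomes); regenerating it from genome data is
explicitly not part of this package. Its row sums and all seven lineage
averages reproduce the printed values exactly, which is what the
acceptance suite asserts.

## The simulator: what it emulates, and what it does not

`simulateGeneFamily()` runs a birth–death process down the species tree:
one ancestral copy enters at the root, and every extant copy acquires
duplications (rate λ) and losses (rate μ) as a Poisson process per unit
branch length, duplicated copies evolving independently thereafter. Event
times are branch-uniform by construction of the exponential waiting
times. The full event log is retained, so the true number of duplication
events is always known, including those later hidden by losses.

`simulateSequences()` evolves codon-structured sequences along the gene
tree under the TN93 rate matrix with per-codon-position rate multipliers
(defaults 1 : 0.5 : 2.5 — second positions slowest, third fastest, the
qualitative pattern of coding sequence). Branch lengths are expected
substitutions per site at the position-averaged rate. The root sequence is
drawn from the stationary frequencies.

Defaults are the study conditions: uniform species-tree branch lengths of
0.1 substitutions/site (placeholder lengths — divergence-time calibration
is out of scope — chosen to keep pairwise distances well below TN93
saturation while giving resolvable internal edges), λ = 0.7 per copy per
unit length so that a family expects ≈ 2 duplications on the fixture
(total length 2.8, within the 1–3 band of the recovery study), μ = 0 for
the recovery study and μ > 0 only for the bias-direction check,
3,000-codon sequences, 100 bootstrap replicates.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: no indels (true alignments are gap-free, so
alignment error is absent; an optional gap-injection path exercises the
trimming and length-filter code but not aligner behaviour), no
dN/dS-style codon models or selection, no rate variation beyond the three
position multipliers, no gene conversion or horizontal transfer, no
assembly or annotation artefacts. Recovery rates on simulated families are
therefore an upper bound on what identical settings would achieve on real
genomes.

## Numerical choices and degenerate inputs

* TN93 saturation: capped at 5.0 substitutions/site and flagged, so
  failures surface in `njTree()` error messages instead of NaN trees.
* Fewer than 20 comparable sites make a pair invalid — below that the
  closed form is noise.
* The relative-length filter compares with a 1e-9 slack so that a ratio
  exactly at the boundary survives binary floating point
  (0.55 × 100 > 55 in doubles).
* Empty leaf sets, unknown labels, unmapped genes, non-binary gene trees
  (pointed at `resolvePolytomies()`, which builds lexicographically
  ordered caterpillars with support-0, i.e. rearrangeable, edges), and
  alignments fully removed by trimming all raise immediate errors.
* All stochastic steps (bootstrap, simulation, greedy restarts) save and
  restore the RNG state and are reproducible from `rngSeed`; per-family
  seeds are derived from the master seed with a fixed stride.

## Sizes used by the automated studies

The acceptance suite and `scripts/acceptance.R` run, per invocation:
exact arithmetic on the 13 × 16 count table; 200 random
reconciliation-plus-rooting instances (gene trees ≤ 7 leaves, species
trees ≤ 5) against a brute-force enumeration of rootings × event
histories; 100 single-weak-region rearrangement instances (≤ 5 boundary
subtrees) against exhaustive resolution enumeration; 100 random 8–16-leaf
additive matrices for NJ recovery plus TN93 agreement with an independent
implementation at 1e-12; and an end-to-end study of 200 simulated
families at the default study conditions, requiring ≥ 90% exact
per-family duplication-count recovery, plus a 40-family μ = 0.3 study for
the bias direction (losses can only deflate the census). These sizes are
the package's chosen study design and are stated here so results are
interpretable and reproducible.

## Known limitations

* Only duplication and loss events are modelled: no transfers, and the
  species tree must be binary and rooted.
* The weak-region search is exhaustive only up to 7 boundary subtrees;
  beyond that the greedy NNI search can in principle return a local
  optimum (never worse than the input tree).
* The key-node criterion presumes at least one outgroup and one ingroup
  gene survive screening and filtering; families that lose all outgroup
  genes are reported as stage errors, not silently accepted.
* Genome-scale results obtained with external BLAST/MAFFT/RAxML runs on
  real genome data are out of the package's computational scope: the
  published per-lineage duplication totals for the muscle-gene study
  cannot be recomputed here, and only the transcribed count-table
  arithmetic and the simulation studies above are asserted by tests.
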