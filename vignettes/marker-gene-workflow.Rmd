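---
title: "Degenerate-primer marker-gene workflows with ampliPhy"
author: "ampliPhy authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degenerate-primer marker-gene workflows with ampliPhy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliPhy)
```

## The problem

16S rRNA sequences separate many bacterial genera cleanly but leave closely
related species -- and especially subspecies -- of *Bifidobacterium* poorly
resolved, because the gene is too conserved at that depth. Protein-coding
marker genes evolve faster. The bile salt hydrolase gene (*bsh*), present in
gut-adapted bifidobacteria and absent from some environmental relatives, is
such a marker: a single degenerate primer pair can amplify a partial *bsh*
fragment across the genus, and the amplified sequences carry enough variation
to separate species, and in favorable cases subspecies.

ampliPhy implements the complete in-silico side of that workflow: finding
conserved blocks in an alignment of known *bsh* genes, deriving degenerate
primers from them, predicting PCR products on template sequences, comparing
amplified fragments by percent identity, and building neighbor-joining trees
with bootstrap supports. A simulator generates marker-gene families with
known truth so every stage can be validated offline.

## Primer design from conserved blocks

`columnProfiles()` summarizes every alignment column: base counts, gap
fraction, the minimal IUPAC code covering all observed bases, and whether the
column is strictly identical across rows (the "asterisk" columns of a Clustal
display). `findConservedBlocks()` then scans left to right for maximal
windows in which

* every column's gap fraction is at most `maxGapFraction` (default 0), and
* the cumulative degeneracy -- the product of per-column IUPAC code sizes --
  stays within `maxBlockDegeneracy` (default 64).

Extension is greedy and maximal with ties broken leftmost. Published primer
sets of this kind were designed by eye; what matters for a reimplementation
is that the procedure is deterministic and its constraints are explicit. The
defaults are choices, not measurements: `minLen = 17` equals the shortest
primer in the packaged panel, and a degeneracy budget of 64 keeps a primer
pool at most 64-fold mixed, a practical ceiling for ordinary PCR. Both are
exposed as arguments (and as `design` flags on the command line). Note that a
cumulative budget this size can legally absorb a weakly variable column
adjacent to a truly conserved window; callers who want strictly invariant
blocks should set `maxBlockDegeneracy = 1`.

Block coordinates are reported twice: as 1-based inclusive alignment columns
and projected onto a reference row (`referenceStart`), counting the non-gap
reference characters up to the block start. A block starting in a
reference-gap column reports the next reference position, with a message.
This projection is what lets primer anchors be quoted in the ungapped
coordinate system of a reference gene.

`blockToPrimer()` emits the consensus as-is for forward primers and its
IUPAC reverse complement for reverse primers (the strand of synthesis, the
convention in which primer tables are printed). Melting temperatures use the
Wallace rule, 2(A+T) + 4(G+C), evaluated over the AT-richest and GC-richest
expansions of the degenerate sequence; this is deliberately the crudest
defensible estimate, used as a plausibility window rather than a
thermodynamic prediction -- nearest-neighbor models are out of scope.

### The packaged panel

`bshPrimerPanel()` returns the six-primer *bsh* screening panel with anchors
on the reference gene: two sequencing primers spanning positions 1-524
(Bif-bshA-1F at anchor 1, Bif-bshD-2R whose footprint starts at 505), an
internal screening pair (Bif-bshB-2F at 46, Bif-bshC-1R at 448, product 419
bp), and an RT-PCR pair (Bif-bshE-3F / Bif-bshF-3R) sharing those internal
anchors. One published rendering of the B-2F sequence contains a
typographical space; the panel stores the contiguous 23-mer. Published
descriptions of this panel attribute the 524 bp screening product
inconsistently to the internal pair, but the printed anchors admit only one
arithmetic: 505 + 20 - 1 = 524 for A-1F/D-2R and 448 + 17 - 1 - 46 + 1 = 419
for B-2F/C-1R. ampliPhy treats 524 bp as the A-1F/D-2R product and 419 bp as
the internal fragment (consistent with the "~415 bp" RT-PCR product quoted
for the near-identical E/F pair); the discrepancy is documented rather than
resolved.

## In-silico PCR

`findBindingSites()` matches a primer position-by-position against every
template window on both strands. A position is compatible when the primer
code's base set and the template code's base set intersect -- degenerate
template symbols (sequencing ambiguities) are therefore handled symmetrically
with degenerate primer positions. A footprint is a site when

* total incompatible positions <= `maxMismatch` (default 2), and
* incompatible positions within the 3'-terminal `threePrimeWindow` (default
  3) <= `threePrimeMaxMismatch` (default 0).

The clamped 3' end mirrors polymerase extension requirements: mismatches at
the extending terminus abort amplification in practice, while internal
mismatches are tolerated at the permissive annealing temperatures degenerate
pools are run at. No thermodynamic annealing model is attempted; mismatch
counting is the whole stringency model.

`predictAmplicons()` pairs every plus-strand forward site with every
downstream minus-strand reverse site and keeps products of 50-5000 bp
(configurable). Product length counts both primer footprints inclusively --
the convention that makes a forward footprint at 1-20 and a reverse footprint
at 505-524 a 524 bp product. Templates with no compatible site pair return an
empty result; that, and nothing more dramatic, is the marker-negative
behavior. `virtualGel()` condenses the predictions into one row per template
with sorted unique band lengths, a tabular stand-in for an electrophoresis
photo.

## Percent identity

Pairwise comparison is an end-to-end global alignment
(`Biostrings::pairwiseAlignment`) under +1 match, -1 mismatch, and affine gap
costs of 2 (open) + 1 per position -- values chosen to mimic Clustal-like
behavior on near-homologous DNA, and all exposed as arguments. Identity is
then computed from the gapped strings as 100 x matches / columns, where the
counted columns run from the first to the last column in which both rows are
aligned: terminal-gap overhangs are excluded (a shorter fragment is not
penalized for missing ends), internal gaps count against identity, and
matches require identical symbols. Values are reported to one decimal place,
the precision at which such similarities are conventionally quoted.
"Similarity" statistics in the literature rarely state their exact
definition; because local-alignment (BLAST-style) and global (Clustal-style)
identities can differ by a few tenths of a percent on near-identical
sequences, comparisons against published percentages should allow a tolerance
of about half a percentage point.

## Trees and supports

`toDistance()` converts identities to p-distances (p = 1 - identity/100), or
to Jukes-Cantor distances d = -(3/4) ln(1 - 4p/3) on request; the correction
is undefined at p >= 0.75 and errors there. `njTree()` is Saitou-Nei
neighbor joining; negative branch lengths, which NJ produces on non-additive
input, are clamped to zero with a message. Uncorrected p-distance is the
default because distance-matrix tools of the MEGA 4 era defaulted to simple
models and the published tree this workflow mirrors does not state its model;
the correction matters only when divergences are deep (see below).

`bootstrapSupports()` resamples alignment columns with replacement, rebuilds
the NJ tree per replicate from row-wise p-distances, and maps onto each
internal edge of the full-data tree the percentage of replicates containing
the same leaf bipartition -- the standard way supports are attached to a
published distance tree. Resampling is seeded and reproducible; supports
travel as internal node labels through `writeNewickTree()` /
`readNewickTree()` (branch lengths at 6 significant digits; malformed input
is rejected with the character offset of the first unbalanced parenthesis).

## The simulator, and what it does and does not emulate

`generateDataset()` evolves a uniform-random root sequence (default 950 bp,
the scale of a *bsh* gene) down a supplied phylogeny under JC69 -- each site
substitutes with probability (3/4)(1 - exp(-4t/3)) per branch of length t --
then overwrites the planted primer footprints in every leaf with an
independently sampled concrete expansion of each footprint's IUPAC pattern.
Planting after evolution keeps truth coordinates exact and guarantees the
panel amplifies every leaf, while the flanks diverge according to the tree.
The default planted blocks are the four panel footprints at reference anchors
1, 46, 448 and 505; the two co-anchored primer pairs are merged position-wise
into IUPAC unions so all six primers bind within the default mismatch budget.
Indels default to off; when enabled they are flank-only events with geometric
lengths, and the truth record shifts downstream anchors accordingly.

The simulator reproduces the features the toolkit needs to be tested
against -- known topology, known footprint coordinates, JC-distributed flank
divergence -- and nothing else. Real *bsh* data violate it in known ways:
substitution is codon-structured and selection-constrained rather than iid;
real conserved regions are conserved because of purifying selection, not
overwriting, so their flanking boundaries are soft; base composition is far
from uniform (bifidobacterial genomes are GC-rich); and real amplicon
collections contain sequencing ambiguities. Passing the simulation-based
tests therefore demonstrates correctness of the algorithms, not field
performance of the primer panel.

One consequence of the planting model is worth knowing: footprint positions
carry primer-determined, not template-determined, sequence -- exactly as in
real PCR products, where the primer overwrites template variation at its
binding site. Degenerate footprint positions are therefore iid noise across
leaves and carry no phylogenetic signal.

## Numerical and validation choices

* **Coordinates** are 1-based inclusive everywhere, matching the convention
  in which primer anchors are published.
* **Tie-breaking**: block extension is leftmost-greedy; NJ joins follow the
  deterministic order of the underlying implementation; alignment
  tie-breaking is delegated to the dynamic-programming engine. Identical
  inputs and seeds give byte-identical outputs.
* **Degenerate expansion** is capped (default 65,536 variants) and refuses
  with the computed cardinality rather than exhausting memory.
* **Validation sizes**: the shipped test-suite exercises templates of 200-
  1200 bp, families of 3-10 taxa, 20-replicate recovery loops and 200-
  replicate bootstraps -- sizes at which the exhaustive oracles (expansion
  scans, alignment-path enumeration for lengths <= 8, four-point checks on
  additive matrices) stay exact and the whole suite runs in a few minutes.
* **Distance model in the end-to-end check**: recovery of an 8-taxon
  topology from 524 bp amplicons is tested with the Jukes-Cantor correction,
  because leaf-to-leaf paths in those simulations reach ~0.6 substitutions
  per site, deep enough for multiple hits to bend raw p-distances away from
  additivity. With the correction the generating topology is recovered
  exactly across the tested seeds; without it, occasional short internal
  edges flip. On such short fragments the shortest internal edges (~0.02
  subst/site, about ten expected substitutions across the amplicon) sit near
  the information limit of the data, and no distance method recovers them in
  every random replicate -- the package reports this honestly rather than
  presenting topology recovery as unconditional.

## Limitations

* Tm estimation is Wallace-rule only; no nearest-neighbor thermodynamics,
  primer-dimer or hairpin screening, and no multiplex compatibility scoring.
* In-silico PCR predicts presence and size of products, not yield; weak or
  inefficient amplification cannot be represented.
* No multiple-sequence-alignment engine is bundled: pairwise identity is
  alignment-based, but `bootstrapSupports()` expects equal-length rows
  (amplicons of a common primer pair, or an externally computed MSA).
* Maximum-likelihood and Bayesian inference are out of scope; the tree module
  is deliberately the distance workflow it mirrors.
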