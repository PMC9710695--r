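---
title: "Multiple spliced alignment of gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple spliced alignment of gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspa)
```

## The problem

Alternative splicing lets one gene produce several coding sequences (CDSs)
built from overlapping subsets of its exons. Comparing the transcript sets of
a gene family therefore needs an alignment that respects exon-intron
structure. A *pairwise spliced alignment* (PSpA) aligns one CDS to one gene as
an ordered chain of blocks: a *conserved* block pairs a CDS segment with a
gene segment (and carries the percent identity, PID, of that segment
alignment); a *deleted* block has no gene counterpart. This package
generalizes that to a *multiple spliced alignment* (MSpA) of a CDS set $C$ and
a gene set $G$: an ordered chain $A = A[1], \dots, A[n]$ of *multiblocks*,
each mapping a subset of $C \cup G$ to one segment per sequence. A valid MSpA
satisfies four conditions:

1. every multiblock is non-empty;
2. for a sequence present in two multiblocks, the earlier segment ends
   strictly before the later one starts;
3. the segments of every CDS cover it entirely;
4. a multiblock holding a CDS also holds its source gene, with the CDS
   segment's coordinate projection (`gpos`) contained in the gene segment.

A multiblock is one column-group of the alignment: a set of putatively
homologous exon segments. The MSpA is a single superstructure of the family
from which three products are derived: a multiple CDS alignment,
splicing-orthology groups, and homology-predicted gene models.

## The assembly procedure

Given one PSpA per pair of $C \times G$ (from `align_pair()`/
`compute_pspa_set()`, or any external spliced aligner via the TSV format),
`build_mspa()` runs four steps.

**1. Spliced alignment graph** (`build_graph`). Each conserved block of a
CDS $c$ (of gene $g$) against gene $h$ contributes three segment vertices —
the CDS segment, the gene segment on $h$, and the projection
$(\mathrm{gpos}(s), \mathrm{gpos}(e))$ on $g$ — a *block edge* between the CDS
segment and the $h$ segment, and a *CDS edge* between the CDS segment and its
projection. When $h = g$ the block contributes a single CDS edge. Deleted
blocks contribute nothing.

**2. Confidence weights** (`weight_edges`). Each edge carries `pid` (the PID
of the segment alignment it represents; 1 for CDS edges, which are exact by
construction) and `connect`, the strength of connectivity between its
endpoints. We define `connect` as the Jaccard index of the endpoints'
neighbor sets, excluding the endpoints themselves; an isolated edge scores 1.
This is one reasonable proxy for connection strength; the definition is a
function argument so alternatives can be swapped in.

**3. Conflict splitting** (`split_components`). A connected component cannot
become a multiblock if it contains two non-overlapping segments of one
sequence. Conflicting pairs are disconnected, one pair at a time in a fixed
deterministic order, by a minimum-capacity edge cut under capacity
$\mathrm{pid}(e) \cdot \mathrm{connect}(e)$. CDS edges get effectively
infinite capacity: a CDS segment is never separated from its own projection,
and a conflict bridged only by CDS edges cannot arise because a CDS has one
source gene.

**4. Greedy chaining** (`components_to_candidates`, `assemble`). Each
post-split component becomes a candidate multiblock (same-sequence segments,
which now pairwise overlap, are interval-unioned). Candidates are sorted by
decreasing size — a large candidate is supported by many pairwise blocks and
is less likely to be an artifact — and inserted into a growing chain when
consistent with it. A candidate whose relation to exactly one chain member is
"overlap on all shared keys" is merged into it when the union keeps one
contiguous segment per sequence; candidates overlapping several members, or
relating inconsistently, are skipped (and logged). Afterwards, any CDS
stretch still uncovered (condition 3) is patched in: positions whose gene
projection falls inside an existing multiblock's gene segment join that
multiblock, the rest form new `{CDS segment, own-gene projection}`
multiblocks. The result is validated against all four conditions before it is
returned; `assemble()` refuses to return an invalid chain.

Chain position for a free candidate (no shared keys with part of the chain)
follows the smallest gene coordinate of its lexicographically smallest gene.
All tie-breaks are lexicographic/coordinate-based, so identical inputs give
identical chains.

## Derived products

**Multiple CDS alignment** (`mspa_to_cds_msa`). Per multiblock, the gene
segments are aligned with a center-star strategy (center = longest segment;
global pairwise alignment at match +1, mismatch −1, gap −2; "once a gap,
always a gap" merging). Each CDS row is then *forced* onto its own gene's
row: every CDS position lands in the column of its `gpos` projection, which
guarantees each row ungaps to exactly its CDS sequence. Multiblocks lacking a
CDS contribute all-gap columns; per-multiblock alignments are concatenated in
chain order and reduced to the CDS rows. MSA quality inside short conserved
exon blocks is insensitive to the per-multiblock aligner choice, which is why
a simple center-star suffices here.

**Splicing-orthology groups** (`orthology_groups`). Two CDSs of *distinct*
genes are splicing orthologs when they occupy exactly the same multiblocks
and, per shared multiblock, their segment lengths are congruent modulo 3 —
same splicing structure, same reading frame. The pairwise relation is closed
into an equivalence relation (union-find), so two isoforms of one gene can
end up in the same group through an intermediate in another gene.

**Gene-model prediction** (`predict_cds`). A source CDS projects onto a
distinct target gene when every multiblock holding the source also holds the
target gene with frame-congruent segment lengths. The target segments,
concatenated in chain order, form the putative CDS; it is rejected if it
duplicates an annotated CDS of the target or contains an internal in-frame
STOP codon (TAA/TAG/TGA read in frame 1 — a terminal STOP is allowed, since a
complete CDS naturally ends in one). The prediction condition is deliberately
one-directional (source ⇒ target): the target gene legitimately occupies
additional multiblocks for its other exons, so requiring the converse would
make almost every prediction impossible, including the package's own worked
example.

## The baseline pairwise aligner

PSpA computation is an input to the method, not its substance; the bundled
aligner exists so the pipeline runs from bare FASTA/GFF3. For each CDS exon
it searches the target's gene-structure segments (falling back to the
remaining gene suffix) for the best local alignment at match +2, mismatch −3,
gap open −5, gap extend −2. A hit becomes a conserved block when its PID
reaches `min_pid` (default 0.5) **and** it spans at least `min_cover`
(default 0.5) of its exon, with an absolute floor of `min_len` (3 nt). The
coverage rule matters: a 6/7-match local hit inside an unrelated exon passes
any identity threshold while aligning almost none of its exon, and calling an
exon conserved should mean most of it aligns. Hits are chained monotonically
(each must start after the previous hit's gene end), adjacent blocks
contiguous on both sequences are merged, and uncovered CDS stretches become
deleted blocks. A CDS aligned to its own gene returns the gene model itself.

## The family simulator

`simulate_family()` generates toy gene families with exact ground truth. An
ancestral gene is drawn — 4–8 exons of 12–60 nt (multiples of 3, so segment
lengths stay frame-compatible), introns and flanks of 20–60 nt — together
with 1–3 ancestral transcripts: the first uses all exons, the others are
distinct random exon subsets (each exon dropped with probability 0.3, a fixed
generator choice giving root isoform diversity independent of the
evolutionary parameters). Along each branch of a rooted newick tree (default:
five leaves, unit-ish branch lengths), every site substitutes with
probability $1 - e^{-\mathrm{rate} \cdot \ell}$ and every transcript suffers
at most one exon-skipping event at rate `skip_prob` per branch-length unit;
a skip moves the transcript's descendants into a new splicing-ortholog
group.

Exons and introns mutate by substitution only — no indels — so all leaf genes
share one coordinate system and the true alignment is column-exact; that is
what makes the truth MSA and per-exon homology map trivially correct, at the
price of not exercising indel tolerance. The default substitution rates used
in testing, 0 / 0.05 / 0.2 per site per branch-length unit, span roughly
70–100% down to ~40% pairwise exon identity on the default tree — i.e. from
easy to genuinely hard families. Passing tests on these families shows the
pipeline recovers structure under substitution noise and isoform divergence;
it says nothing about exon boundary drift, indels inside exons, duplicated
exons, or unequal gene coordinate systems, all of which real families have.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere; GFF3 needs no shift.
  Reverse-strand annotations are rejected rather than silently flipped.
* `gene_structure()` merges exons sharing at least one position; abutting
  exons stay separate.
* Multiblocks with disjoint key sets are mutually consistent ("freely
  placeable"); their order is fixed at assembly time by gene coordinate.
* Condition 4 is enforced for conserved content; a CDS-only block inside a
  PSpA *is* the deleted block of the formalism.
* A candidate overlapping two chain members sharing a key can never satisfy
  condition 2 and is treated as having no chain position.
* `prediction_scores(..., "rbh90")` uses standard Needleman–Wunsch PID
  (matches / alignment columns) with reciprocal best hits, ties broken by
  lexicographic id. Alignment-pair metrics count only CDS rows.
* Degenerate conventions: an alignment with no aligned pairs has precision 1;
  F is 0 when precision and recall are both 0; partitions with fewer than two
  elements have Rand index 1; empty predictions are rejected.

## Problem sizes used in validation

The test suite validates on simulated families of 5 genes and 5–15 CDSs
(gene length a few hundred nt): 20 seed-fixed low-rate families for chain
validity, 20 divergence-free families for exact orthology recovery, and
3 seeds × 3 substitution rates for the monotone-degradation check; the
metric oracles are exhaustive up to 6-element partitions. These sizes were
chosen to be the smallest that still exercise every code path several times
over.

## Known limitations

* The assembly is a greedy heuristic; it maximizes included pairwise blocks
  only locally (the test suite documents greedy versus exhaustive subset
  search on the worked example).
* The `connect` weight and the splitting procedure are reasonable choices
  among several; both are parameterized.
* No support for trans-splicing, genes sharing exons, minus-strand input,
  splice-signal (GT–AG) validation of predicted introns, or protein-level
  scoring.
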