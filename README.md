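# mspa — multiple spliced alignment of gene families

Eukaryotic genes produce alternative transcripts by splicing different exon
subsets; comparing the transcript repertoires of homologous genes requires an
alignment that respects exon–intron structure. `mspa` is for researchers
studying transcript evolution, splicing-ortholog inference, and
homology-based genome annotation. It assembles the pairwise spliced
alignments (PSpAs) of all CDSs and genes of a family into one **multiple
spliced alignment (MSpA)**: an ordered chain of *multiblocks*
A = A[1], …, A[n], each mapping a subset of the CDS set C and gene set G to
one segment per sequence, such that (1) multiblocks are non-empty, (2) per
sequence the segments are strictly increasing along the chain, (3) every CDS
is covered entirely, and (4) a multiblock holding a CDS c of gene g also
holds g, with (gpos(s), gpos(e)) of c's segment inside g's segment. A
multiblock is a set of putatively homologous exon segments.

The assembly is a greedy multiblock algorithm over a **spliced alignment
graph**: conserved PSpA blocks become segment vertices joined by *block
edges* (cross-gene alignments) and *CDS edges* (a CDS segment tied to its
own-gene projection); edges carry confidence weights PID(e) and connect(e);
components holding two non-overlapping segments of one sequence are split by
a minimum-capacity cut (capacity PID·connect, CDS edges uncuttable); the
surviving components, ordered by decreasing size, are chained greedily into a
valid MSpA. From the MSpA the package derives the multiple CDS alignment,
CDS splicing-orthology groups (identical multiblock membership with segment
lengths congruent modulo 3, closed into an equivalence relation) and
homology-predicted gene models (projection of a source CDS onto a target
gene, rejected on frame conflicts, duplicates or internal in-frame STOPs).

A toy family simulator with exact ground truth (true alignment, true
splicing-ortholog groups) and the evaluation metrics used for validation
(alignment precision/recall/F-score over aligned nucleotide pairs, Rand
index, prediction scores with strict and reciprocal-best-hit matching) are
included. See `vignette("multiple-spliced-alignment")` for the method and its
assumptions.

## Worked example

A two-gene family ships with the package: gene `g` (62 nt, CDSs `c1`, `c2`)
and gene `h` (60 nt, CDSs `c3`, `c4`), with four cross-gene PSpAs.

```r
library(mspa)
models <- example_gene_models()
gene_structure(models$g)
#>   start end
#> 1     4  12
#> 2    25  36
#> 3    41  46
#> 4    51  59

A <- build_mspa(example_pspa_set(), models)
A
#> MSpA: 4 CDSs, 2 genes, 5 multiblocks
#>   A[1] c2:(1,5) g:(4,8)
#>   A[2] c1:(1,4) c2:(6,9) c3:(1,4) g:(9,12) h:(7,10)
#>   A[3] c1:(5,16) c2:(10,15) c3:(5,16) c4:(1,12) g:(25,36) h:(23,40)
#>   A[4] c2:(16,21) g:(41,46) h:(43,48)
#>   A[5] c1:(17,21) c2:(22,30) c3:(17,21) c4:(13,21) g:(51,59) h:(51,59)
```

The five multiblocks are the family's superstructure: A[3], for instance,
says that c1, c2, c3 and c4 all use exon material homologous to g:(25,36).
The derivations read off the biology:

```r
orthology_groups(A, models)
#> [[1]] "c1" "c3"    # same multiblocks, frame-congruent: splicing orthologs
#> [[2]] "c2"
#> [[3]] "c4"

predict_cds(A, "c4", "g", models)
#> predicted CDS on g from c4: AAGCAGGTCTGGGGTGATTGA (2 exon(s))

mspa_to_cds_msa(A, models)
#> multiple alignment: 4 rows x 42 columns
#>   c1           -----ATGCAAGCAGGT------CTGG------GGTGA----
#>   c2           ATGGCATGCAAGCAG------------CCAGAAGGTGATTGA
#>   c3           -----ATGCAAGCAG------GTCTGG------GGTGA----
#>   c4           ---------AAGCAG------GTCTGG------GGTGATTGA
```

The predicted CDS is a new two-exon gene model for `g` — an unannotated
isoform homologous to `h`'s `c4`, ending in a legitimate terminal STOP
(`TGA`).

A command-line wrapper covers the same pipeline
(`simulate`, `pspa`, `build`, `derive-msa`, `orthologs`, `predict`,
`evaluate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mspa.R", package="mspa"))')" \
  build --pspas pspas.tsv --genes genes.fa --models models.gff3 --out mspa.json
```

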