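## A small worked-example family of two genes and four CDSs, used throughout
## the documentation and tests. Gene g (62 nt) carries CDSs c1 and c2; gene h
## (60 nt) carries c3 and c4. The exon architectures overlap partially, h has
## an unannotated exonic region homologous to g's third structure segment,
## and c1/c3 are splicing orthologs.

#' Worked-example gene models
#'
#' Two genes: \code{g} (62 nt) with CDSs \code{c1} = \{(9,12),(25,36),(51,55)\}
#' and \code{c2} = \{(4,12),(25,30),(41,46),(51,59)\}; \code{h} (60 nt) with
#' \code{c3} = \{(7,10),(23,28),(35,40),(51,55)\} and
#' \code{c4} = \{(23,28),(35,40),(51,59)\}. The gene structure of \code{g} is
#' \{(4,12),(25,36),(41,46),(51,59)\} and \code{g[c1]} =
#' \code{ATGCAAGCAGGTCTGGGGTGA} (21 nt).
#'
#' @return Named list of \code{gene_model} objects.
#' @export
example_gene_models <- function() {
  g_seq <- paste0("CTT", "ATGGCATGC", "GTAAGTTTTCAG", "AAGCAGGTCTGG",
                  "GTAG", "CCAGAA", "GTAG", "GGTGATTGA", "TTT")
  h_seq <- paste0("CTTCTT", "ATGC", "GTAAGTTTTCAG", "AAGCAG", "GTATAG",
                  "GTCTGG", "GT", "CCAGAA", "AG", "GGTGATTGA", "T")
  list(
    g = gene_model("g", g_seq, list(
      c1 = rbind(c(9, 12), c(25, 36), c(51, 55)),
      c2 = rbind(c(4, 12), c(25, 30), c(41, 46), c(51, 59)))),
    h = gene_model("h", h_seq, list(
      c3 = rbind(c(7, 10), c(23, 28), c(35, 40), c(51, 55)),
      c4 = rbind(c(23, 28), c(35, 40), c(51, 59)))))
}

#' Worked-example pairwise spliced alignments
#'
#' The four cross-gene PSpAs of the example family: \code{W} (c3 vs g,
#' 3 blocks), \code{X} (c4 vs g, 2 blocks), \code{Y} (c1 vs h, 4 blocks) and
#' \code{Z} (c2 vs h, 4 blocks, the first deleted). All conserved blocks are
#' exact matches (PID 1).
#'
#' @return A \code{\link{pspa_set}} of the four PSpAs.
#' @export
example_pspa_set <- function() {
  blk <- function(cs, ce, gs, ge, pid)
    data.frame(cds_start = cs, cds_end = ce, gene_start = gs, gene_end = ge,
               pid = pid)
  pspa_set(list(
    pspa("c3", "g", rbind(blk(1, 4, 9, 12, 1), blk(5, 16, 25, 36, 1),
                          blk(17, 21, 51, 55, 1))),
    pspa("c4", "g", rbind(blk(1, 12, 25, 36, 1), blk(13, 21, 51, 59, 1))),
    pspa("c1", "h", rbind(blk(1, 4, 7, 10, 1), blk(5, 10, 23, 28, 1),
                          blk(11, 16, 35, 40, 1), blk(17, 21, 51, 55, 1))),
    pspa("c2", "h", rbind(blk(1, 9, NA, NA, NA), blk(10, 15, 23, 28, 1),
                          blk(16, 21, 43, 48, 1), blk(22, 30, 51, 59, 1)))))
}

#' Worked-example MSpA
#'
#' The five-multiblock MSpA of the example family, as produced by the
#' multiblock pipeline from \code{\link{example_pspa_set}}.
#'
#' @return An \code{\link{mspa}}.
#' @export
example_mspa <- function() {
  mspa(c("c1", "c2", "c3", "c4"), c("g", "h"), list(
    multiblock(c2 = c(1, 5), g = c(4, 8)),
    multiblock(c1 = c(1, 4), c2 = c(6, 9), c3 = c(1, 4), g = c(9, 12),
               h = c(7, 10)),
    multiblock(c1 = c(5, 16), c2 = c(10, 15), c3 = c(5, 16), c4 = c(1, 12),
               g = c(25, 36), h = c(23, 40)),
    multiblock(c2 = c(16, 21), g = c(41, 46), h = c(43, 48)),
    multiblock(c1 = c(17, 21), c2 = c(22, 30), c3 = c(17, 21),
               c4 = c(13, 21), g = c(51, 59), h = c(51, 59))))
}

#' Path to the bundled worked-example files
#'
#' The same family as \code{\link{example_gene_models}}, shipped as plain
#' files: \code{genes.fa}, \code{models.gff3}, \code{pspas.tsv},
#' \code{mspa.json}.
#'
#' @param file File name within the fixture directory ("" for the directory).
#' @return Path.
#' @export
example_family_path <- function(file = "") {
  system.file("extdata", "toy_family", file, package = "mspa", mustWork = TRUE)
}
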