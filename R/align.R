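## Baseline pairwise spliced aligner. The assembly pipeline treats PSpAs as
## given inputs; this aligner provides them when only sequences and gene
## models are at hand. Scoring: match +2, mismatch -3, gap open -5,
## gap extend -2; conserved blocks require a percent identity >= min_pid.

.align_env <- new.env(parent = emptyenv())

align_scoring <- function() {
  if (is.null(.align_env$scoring))
    .align_env$scoring <- list(
      mat = Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = TRUE),
      gap_opening = 5, gap_extension = 2)
  .align_env$scoring
}

## memoized local alignment of an exon against a gene region; exons repeat
## across the transcripts of a gene, so the hit rate is high
local_hit <- function(exseq, subseq, cache = NULL) {
  key <- paste0(exseq, "\r", subseq)
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(if (identical(hit, "none")) NULL else hit)
  }
  sc <- align_scoring()
  aln <- Biostrings::pairwiseAlignment(
    exseq, subseq, type = "local", substitutionMatrix = sc$mat,
    gapOpening = sc$gap_opening, gapExtension = sc$gap_extension)
  res <- if (Biostrings::nmatch(aln) == 0L) NULL else list(
    score = Biostrings::score(aln), pid = aln_pid(aln), ncol = aln_ncol(aln),
    pstart = Biostrings::start(Biostrings::pattern(aln)),
    pend = Biostrings::end(Biostrings::pattern(aln)),
    sstart = Biostrings::start(Biostrings::subject(aln)),
    send = Biostrings::end(Biostrings::subject(aln)))
  if (!is.null(cache)) cache[[key]] <- if (is.null(res)) "none" else res
  res
}

## alignment columns and PID (matches / columns) of a PairwiseAlignments
aln_ncol <- function(aln) {
  ni <- Biostrings::nindel(aln)
  Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
    sum(Biostrings::insertion(ni)[, "WidthSum"]) +
    sum(Biostrings::deletion(ni)[, "WidthSum"])
}
aln_pid <- function(aln) Biostrings::nmatch(aln) / aln_ncol(aln)

#' Global-alignment percent identity of two sequences
#'
#' Needleman-Wunsch alignment under the package's default nucleotide scoring;
#' PID is matches divided by alignment columns, in \code{[0,1]}.
#'
#' @param a,b Character DNA sequences.
#' @return Numeric scalar in \code{[0,1]}.
#' @export
global_pid <- function(a, b) {
  sc <- align_scoring()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sc$mat, gapOpening = sc$gap_opening,
    gapExtension = sc$gap_extension)
  aln_pid(aln)
}

#' Baseline pairwise spliced alignment of a CDS against a gene
#'
#' For each CDS exon, the gene's structure segments (and, as a fallback, the
#' remaining unaligned gene suffix) are searched for the best-scoring local
#' alignment; a conserved block is emitted when its percent identity reaches
#' \code{min_pid} and it spans at least \code{min_len} CDS positions.
#' Uncovered CDS stretches become deleted blocks, and adjacent conserved
#' blocks contiguous on both sequences are merged. Aligning a CDS against its
#' own source gene returns the gene model itself as conserved blocks with
#' PID 1.
#'
#' A local hit is only accepted when it covers at least \code{min_cover} of
#' its exon: short local matches inside unrelated exons otherwise pass any
#' identity threshold (a 6/7-match hit is 86\% identical but aligns almost
#' none of its exon), and an exon is only called conserved when most of it
#' aligns.
#'
#' @param source \code{gene_model} carrying the CDS.
#' @param cds_id CDS identifier within \code{source}.
#' @param target \code{gene_model} to align against.
#' @param min_pid Conserved-block percent-identity threshold (default 0.5).
#' @param min_len Minimum conserved-block length on the CDS (default 3).
#' @param min_cover Minimum fraction of the CDS exon a hit must span
#'   (default 0.5).
#' @param cache Optional environment memoizing exon-region alignments across
#'   calls (transcripts of one gene share exons).
#' @return A \code{\link{pspa}} of \code{cds_id} and \code{target$gene_id}.
#' @export
align_pair <- function(source, cds_id, target, min_pid = 0.5, min_len = 3L,
                       min_cover = 0.5, cache = NULL) {
  cs <- cds_sequence(source, cds_id)
  m <- nchar(cs$sequence)
  if (identical(source$gene_id, target$gene_id))
    return(self_pspa(source, cds_id))
  segs <- gene_structure(target)
  n <- nchar(target$sequence)
  hits <- list()
  prev_gene_end <- 0L
  for (i in seq_len(nrow(cs$exons))) {
    ex <- c(cs$exons$start[i], cs$exons$end[i])
    exseq <- substr(cs$sequence, ex[1], ex[2])
    regions <- list()
    for (j in seq_len(nrow(segs))) {
      if (segs$end[j] <= prev_gene_end) next
      regions[[length(regions) + 1L]] <-
        c(max(segs$start[j], prev_gene_end + 1L), segs$end[j])
    }
    if (length(regions) == 0L && prev_gene_end < n)
      regions[[1L]] <- c(prev_gene_end + 1L, n)
    best <- NULL
    for (reg in regions) {
      sub <- substr(target$sequence, reg[1], reg[2])
      h <- local_hit(exseq, sub, cache)
      if (is.null(h)) next
      cand <- list(score = h$score, pid = h$pid, ncol = h$ncol,
                   cds = c(ex[1] + h$pstart - 1L, ex[1] + h$pend - 1L),
                   gene = c(reg[1] + h$sstart - 1L, reg[1] + h$send - 1L))
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$gene[1] < best$gene[1]))
        best <- cand
    }
    need <- max(min_len, ceiling(min_cover * seg_len(ex)))
    if (is.null(best) || best$pid < min_pid || seg_len(best$cds) < need)
      next
    hits[[length(hits) + 1L]] <- best
    prev_gene_end <- best$gene[2]
  }
  hits_to_pspa(cds_id, target$gene_id, hits, m)
}

## a CDS aligned to its own gene: emit the gene model, merging exons that
## abut on the gene
self_pspa <- function(model, cds_id) {
  ch <- cds_chain(model, cds_id)
  cs <- cds_sequence(model, cds_id)
  hits <- lapply(seq_len(nrow(ch)), function(i) list(
    pid = 1, ncol = ch$end[i] - ch$start[i] + 1L,
    cds = c(cs$exons$start[i], cs$exons$end[i]),
    gene = c(ch$start[i], ch$end[i])))
  hits_to_pspa(cds_id, model$gene_id, hits, nchar(cs$sequence))
}

## merge contiguous hits and interleave deleted blocks to cover the CDS
hits_to_pspa <- function(cds_id, gene_id, hits, cds_length) {
  merged <- list()
  for (h in hits) {
    k <- length(merged)
    if (k > 0L && merged[[k]]$cds[2] + 1L == h$cds[1] &&
        merged[[k]]$gene[2] + 1L == h$gene[1]) {
      prev <- merged[[k]]
      w <- prev$ncol + h$ncol
      merged[[k]] <- list(pid = (prev$pid * prev$ncol + h$pid * h$ncol) / w,
                          ncol = w, cds = c(prev$cds[1], h$cds[2]),
                          gene = c(prev$gene[1], h$gene[2]))
    } else merged[[length(merged) + 1L]] <- h
  }
  rows <- list(); pos <- 1L
  for (h in merged) {
    if (h$cds[1] > pos)
      rows[[length(rows) + 1L]] <- data.frame(
        cds_start = pos, cds_end = h$cds[1] - 1L, gene_start = NA_integer_,
        gene_end = NA_integer_, pid = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      cds_start = h$cds[1], cds_end = h$cds[2], gene_start = h$gene[1],
      gene_end = h$gene[2], pid = h$pid)
    pos <- h$cds[2] + 1L
  }
  if (pos <= cds_length)
    rows[[length(rows) + 1L]] <- data.frame(
      cds_start = pos, cds_end = cds_length, gene_start = NA_integer_,
      gene_end = NA_integer_, pid = NA_real_)
  blocks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cds_start = integer(0), cds_end = integer(0),
               gene_start = integer(0), gene_end = integer(0), pid = numeric(0))
  pspa(cds_id, gene_id, blocks, cds_length = cds_length)
}

#' Compute the full PSpA set of a gene family
#'
#' Runs \code{\link{align_pair}} over every (CDS, gene) pair of C x G,
#' including self pairs (which reproduce the gene models).
#'
#' @param models Named list of \code{gene_model} objects.
#' @param min_pid,min_len,min_cover Passed to \code{\link{align_pair}}.
#' @return A \code{\link{pspa_set}} complete over C x G.
#' @export
compute_pspa_set <- function(models, min_pid = 0.5, min_len = 3L,
                             min_cover = 0.5) {
  idx <- cds_index(models)
  cache <- new.env(parent = emptyenv())
  pspas <- list()
  for (cid in names(idx)) for (m in models)
    pspas[[length(pspas) + 1L]] <-
      align_pair(models[[idx[[cid]]]], cid, m, min_pid = min_pid,
                 min_len = min_len, min_cover = min_cover, cache = cache)
  pspa_set(pspas)
}
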