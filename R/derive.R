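## Consumers of an MSpA: multiple CDS alignment, CDS splicing-orthology
## groups, and homology-based gene-model prediction.

#' Multiple alignment container
#'
#' @param rows Named character vector of equal-length gapped strings.
#' @return Object of class \code{multiple_alignment}.
#' @export
multiple_alignment <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  if (length(unique(nchar(rows))) > 1L)
    stop("alignment rows must have equal length")
  structure(rows, class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("multiple alignment: %d rows x %d columns\n", length(x),
              if (length(x)) nchar(x[1]) else 0L))
  for (nm in names(x)) cat(sprintf("  %-12s %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Remove gaps from an alignment row
#' @param row Gapped string.
#' @return Ungapped string.
#' @export
ungap <- function(row) gsub("-", "", row, fixed = TRUE)

## center-star alignment of a few short sequences (match +1, mismatch -1,
## gap -2); returns rows and a per-sequence position -> column map
star_align <- function(seqs) {
  nms <- names(seqs)
  if (length(seqs) == 1L)
    return(list(ncol = nchar(seqs[[1]]),
                rows = stats::setNames(as.character(seqs), nms),
                poscol = stats::setNames(list(seq_len(nchar(seqs[[1]]))), nms)))
  lens <- nchar(seqs)
  center <- nms[order(-lens, nms)][1]
  others <- setdiff(nms, center)
  nc <- nchar(seqs[[center]])
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aligned <- list()
  ins_max <- integer(nc + 1L)  # insertions after center position 0..nc
  for (s in others) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[[center]]), Biostrings::DNAString(seqs[[s]]),
      type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2)
    pc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    po <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    aligned[[s]] <- list(pc = pc, po = po)
    cpos <- 0L; run <- 0L
    for (i in seq_along(pc)) {
      if (pc[i] == "-") {
        run <- run + 1L
        ins_max[cpos + 1L] <- max(ins_max[cpos + 1L], run)
      } else { cpos <- cpos + 1L; run <- 0L }
    }
  }
  colof <- cumsum(ins_max[seq_len(nc)] + 1L)  # column of center position j
  total <- nc + sum(ins_max)
  rows <- list(); poscol <- list()
  r <- rep("-", total)
  r[colof] <- strsplit(seqs[[center]], "")[[1]]
  rows[[center]] <- paste(r, collapse = "")
  poscol[[center]] <- colof
  base_of <- c(0L, colof)  # column after which insertions at slot c start
  for (s in others) {
    pc <- aligned[[s]]$pc; po <- aligned[[s]]$po
    r <- rep("-", total)
    pmap <- integer(nchar(seqs[[s]]))
    cpos <- 0L; run <- 0L; op <- 0L
    for (i in seq_along(pc)) {
      if (pc[i] == "-") {
        run <- run + 1L
        col <- base_of[cpos + 1L] + run
      } else {
        cpos <- cpos + 1L; run <- 0L
        col <- colof[cpos]
      }
      if (po[i] != "-") {
        op <- op + 1L
        r[col] <- po[i]
        pmap[op] <- col
      }
    }
    rows[[s]] <- paste(r, collapse = "")
    poscol[[s]] <- pmap
  }
  list(ncol = total, rows = rows[nms], poscol = poscol[nms])
}

#' Derive the multiple CDS alignment of an MSpA
#'
#' Per multiblock, the gene segments are aligned (center-star with global
#' pairwise alignment, match +1, mismatch -1, gap -2); each CDS row is forced
#' onto its own gene's row: every CDS position is placed in the column of its
#' gene-coordinate projection. Multiblocks lacking a CDS contribute all-gap
#' columns for it. Per-multiblock alignments are concatenated in chain order,
#' restricted to the CDS rows.
#'
#' @param A A valid \code{\link{mspa}}.
#' @param models Named list of \code{gene_model} objects.
#' @return A \code{\link{multiple_alignment}} over the CDS set; each row
#'   ungaps to its CDS sequence.
#' @export
mspa_to_cds_msa <- function(A, models) {
  viol <- validate_mspa(A, models)
  if (nrow(viol) > 0L) stop("invalid MSpA; run validate_mspa for details")
  idx <- cds_index(models)
  cds_ids <- A$cds_ids
  pieces <- stats::setNames(vector("list", length(cds_ids)), cds_ids)
  for (mb in A$multiblocks) {
    gids <- intersect(mb_keys(mb), A$gene_ids)
    gseqs <- stats::setNames(lapply(gids, function(g)
      substr(models[[g]]$sequence, mb[[g]][1], mb[[g]][2])), gids)
    sa <- star_align(gseqs)
    for (cid in cds_ids) {
      if (!cid %in% mb_keys(mb)) {
        pieces[[cid]] <- c(pieces[[cid]], strrep("-", sa$ncol))
        next
      }
      gid <- idx[[cid]]
      s <- mb[[cid]]
      ks <- s[1]:s[2]
      ps <- gpos(models[[gid]], cid, ks)
      cols <- sa$poscol[[gid]][ps - mb[[gid]][1] + 1L]
      chars <- strsplit(substr(cds_sequence(models[[gid]], cid)$sequence,
                               s[1], s[2]), "")[[1]]
      r <- rep("-", sa$ncol)
      r[cols] <- chars
      pieces[[cid]] <- c(pieces[[cid]], paste(r, collapse = ""))
    }
  }
  rows <- vapply(pieces, function(p) paste(p, collapse = ""), "")
  if (length(rows) == 0L || nchar(rows[1]) == 0L)
    rows <- stats::setNames(rep("", length(cds_ids)), cds_ids)
  multiple_alignment(rows)
}

#' Infer CDS splicing-orthology groups from an MSpA
#'
#' Two CDSs of distinct genes are splicing orthologs when they occupy exactly
#' the same multiblocks and, in every shared multiblock, their segment
#' lengths are congruent modulo 3 (same splicing structure, same reading
#' frame). The pairwise relation is closed into an equivalence relation and
#' the classes returned as groups.
#'
#' @param A A valid \code{\link{mspa}}.
#' @param models Named list of \code{gene_model} objects.
#' @return List of character vectors partitioning the CDS set, each sorted,
#'   ordered by first member.
#' @export
orthology_groups <- function(A, models) {
  idx <- cds_index(models)
  cds_ids <- sort(A$cds_ids)
  membership <- lapply(cds_ids, function(cid)
    which(vapply(A$multiblocks, function(mb) cid %in% mb_keys(mb), TRUE)))
  names(membership) <- cds_ids
  n <- length(cds_ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1L, 0L))) for (j in seq(i + 1L, length.out = n - i)) {
    ci <- cds_ids[i]; cj <- cds_ids[j]
    if (identical(idx[[ci]], idx[[cj]])) next  # same gene: never base-related
    if (!identical(membership[[ci]], membership[[cj]])) next
    ok <- all(vapply(membership[[ci]], function(k) {
      a <- A$multiblocks[[k]][[ci]]; b <- A$multiblocks[[k]][[cj]]
      ((a[2] - a[1]) - (b[2] - b[1])) %% 3L == 0L
    }, TRUE))
    if (ok) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- lapply(split(cds_ids, roots), sort)
  groups <- unname(groups[order(vapply(groups, `[`, "", 1))])
  groups
}

#' Predict a gene model by homology through an MSpA
#'
#' Projects a source CDS onto a distinct target gene: every multiblock
#' holding the source must also hold the target gene, with segment lengths
#' congruent modulo 3. The target segments are concatenated in chain order
#' into a putative CDS, rejected if it duplicates an annotated CDS of the
#' target gene or contains an internal in-frame STOP codon (TAA/TAG/TGA read
#' in frame 1; a terminal STOP is allowed). A successful prediction is a
#' splicing ortholog of its source by construction.
#'
#' @param A A valid \code{\link{mspa}}.
#' @param source_cds CDS identifier in \code{A$cds_ids}.
#' @param target_gene Gene identifier, distinct from the source's gene.
#' @param models Named list of \code{gene_model} objects.
#' @return A list of class \code{cds_prediction} with \code{status}
#'   (\code{"predicted"} or \code{"rejected"}); when predicted, fields
#'   \code{gene_id}, \code{exons}, \code{sequence}, \code{source_cds_id};
#'   when rejected, a \code{reason}.
#' @export
predict_cds <- function(A, source_cds, target_gene, models) {
  idx <- cds_index(models)
  if (!source_cds %in% A$cds_ids) stop("unknown source CDS: ", source_cds)
  if (!target_gene %in% A$gene_ids) stop("unknown target gene: ", target_gene)
  if (identical(idx[[source_cds]], target_gene))
    stop("target gene must differ from the source CDS's gene")
  reject <- function(reason)
    structure(list(status = "rejected", reason = reason,
                   source_cds_id = source_cds, gene_id = target_gene),
              class = "cds_prediction")
  ks <- which(vapply(A$multiblocks, function(mb) source_cds %in% mb_keys(mb),
                     TRUE))
  if (length(ks) == 0L) return(reject("source CDS occupies no multiblock"))
  segs <- list()
  for (k in ks) {
    mb <- A$multiblocks[[k]]
    if (!target_gene %in% mb_keys(mb))
      return(reject(sprintf(
        "multiblock %d holds the source CDS but not gene %s", k, target_gene)))
    a <- mb[[source_cds]]; b <- mb[[target_gene]]
    if (((a[2] - a[1]) - (b[2] - b[1])) %% 3L != 0L)
      return(reject(sprintf(
        "segment lengths in multiblock %d are not congruent modulo 3", k)))
    segs[[length(segs) + 1L]] <- b
  }
  exons <- data.frame(start = vapply(segs, `[`, 0L, 1),
                      end = vapply(segs, `[`, 0L, 2))
  sequence <- paste(substring(models[[target_gene]]$sequence,
                              exons$start, exons$end), collapse = "")
  if (nchar(sequence) == 0L) return(reject("empty prediction"))
  for (cid in names(models[[target_gene]]$cds))
    if (identical(cds_sequence(models[[target_gene]], cid)$sequence, sequence))
      return(reject(sprintf("sequence already annotated as CDS %s", cid)))
  ncod <- nchar(sequence) %/% 3L
  if (ncod > 1L) {
    codons <- substring(sequence, 3L * seq_len(ncod - 1L) - 2L,
                        3L * seq_len(ncod - 1L))
    if (any(codons %in% c("TAA", "TAG", "TGA")))
      return(reject("internal in-frame STOP codon"))
  }
  structure(list(status = "predicted", gene_id = target_gene, exons = exons,
                 sequence = sequence, source_cds_id = source_cds),
            class = "cds_prediction")
}

#' @export
print.cds_prediction <- function(x, ...) {
  if (x$status == "predicted")
    cat(sprintf("predicted CDS on %s from %s: %s (%d exon(s))\n", x$gene_id,
                x$source_cds_id, x$sequence, nrow(x$exons)))
  else
    cat(sprintf("prediction on %s from %s rejected: %s\n", x$gene_id,
                x$source_cds_id, x$reason))
  invisible(x)
}

#' Write a multiple alignment to gapped FASTA or CLUSTAL
#'
#' @param msa A \code{\link{multiple_alignment}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_msa_fasta <- function(msa, path) {
  x <- Biostrings::DNAStringSet(as.character(msa))
  names(x) <- names(msa)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_msa_fasta
#' @export
write_msa_clustal <- function(msa, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("CLUSTAL multiple sequence alignment (mspa)", ""), con)
  width <- 60L
  n <- if (length(msa)) nchar(msa[[1]]) else 0L
  nm <- formatC(names(msa), width = max(nchar(names(msa))) + 2L, flag = "-")
  for (off in seq(1L, max(n, 1L), by = width)) {
    for (i in seq_along(msa))
      writeLines(paste0(nm[i], substr(msa[[i]], off, min(off + width - 1L, n))),
                 con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write orthology groups as TSV (group_id, cds_id)
#'
#' @param groups List of character vectors (a partition of the CDS set).
#' @param path Output path.
#' @return Invisibly, the path. \code{read_orthology_groups} reads it back.
#' @export
write_orthology_groups <- function(groups, path) {
  tab <- data.frame(
    group_id = rep(seq_along(groups), lengths(groups)),
    cds_id = unlist(groups))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_orthology_groups
#' @export
read_orthology_groups <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  groups <- lapply(split(tab$cds_id, tab$group_id), sort)
  unname(groups[order(vapply(groups, `[`, "", 1))])
}
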