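#' Construct a gene model
#'
#' A gene model couples a gene sequence with the exon chains of its annotated
#' CDSs. Coordinates are 1-based and inclusive throughout: an exon \code{(a, b)}
#' covers positions \code{a..b} of the gene, with \code{1 <= a <= b <= n}.
#' Within a CDS chain successive exons must be strictly increasing and
#' non-overlapping (\code{b_i < a_{i+1}}). All annotations are expected on the
#' coding strand.
#'
#' @param gene_id Gene identifier.
#' @param sequence Gene DNA sequence (character scalar over A,C,G,T).
#' @param cds Named list mapping CDS identifiers to exon chains, each either a
#'   two-column matrix/data.frame of (start, end) rows or a list of
#'   length-2 vectors.
#' @return An object of class \code{gene_model}.
#' @examples
#' gm <- gene_model("g", "AAACCCGGG", list(t1 = rbind(c(1, 3), c(7, 9))))
#' cds_sequence(gm, "t1")$sequence
#' @export
gene_model <- function(gene_id, sequence, cds = list()) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("gene sequence must be non-empty")
  if (grepl("[^ACGT]", sequence)) stop("gene sequence must be over {A,C,G,T}")
  n <- nchar(sequence)
  if (length(cds) > 0L && is.null(names(cds))) stop("cds must be a named list")
  chains <- lapply(cds, function(x) {
    if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
    x <- as.data.frame(x)
    if (ncol(x) < 2L) stop("exon chain needs start and end columns")
    ch <- exon_chain(x[[1]], x[[2]])
    if (nrow(ch) == 0L) stop("a CDS must have at least one exon")
    if (ch$start[1] < 1L || ch$end[nrow(ch)] > n)
      stop("exon outside [1, gene length] for gene ", gene_id)
    ch
  })
  structure(list(gene_id = gene_id, sequence = sequence, cds = chains),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene model '%s': %d nt, %d CDS(s)\n", x$gene_id,
              nchar(x$sequence), length(x$cds)))
  for (id in names(x$cds)) {
    ch <- x$cds[[id]]
    cat(sprintf("  %s: %s\n", id,
                paste(sprintf("(%d,%d)", ch$start, ch$end), collapse = " ")))
  }
  invisible(x)
}

#' Gene structure: merged overlapping exons
#'
#' Computes the gene structure S(g), the ordered chain of segments obtained by
#' merging all overlapping exons of the gene's CDSs. Only exons sharing at
#' least one position are merged; abutting exons (\code{b_i + 1 == a_j}) remain
#' separate segments.
#'
#' @param model A \code{gene_model}.
#' @return Data frame with columns \code{start}, \code{end}, sorted by start.
#' @export
gene_structure <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  if (length(model$cds) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  ex <- do.call(rbind, model$cds)
  r <- IRanges::IRanges(start = ex$start, end = ex$end)
  m <- IRanges::reduce(r, min.gapwidth = 0L)  # merge overlap only, not abutting
  data.frame(start = IRanges::start(m), end = IRanges::end(m))
}

#' CDS sequence and CDS-coordinate exon chart
#'
#' The sequence of a CDS is the concatenation of the sequences of the gene
#' exons composing it. The exon chart gives the exons in CDS coordinates,
#' e.g. gene exons of lengths 4, 12, 5 chart as (1,4), (5,16), (17,21).
#'
#' @param model A \code{gene_model}.
#' @param cds_id CDS identifier present in the model.
#' @return List with \code{sequence} (character) and \code{exons} (data frame
#'   of CDS-coordinate start/end).
#' @export
cds_sequence <- function(model, cds_id) {
  ch <- cds_chain(model, cds_id)
  parts <- substring(model$sequence, ch$start, ch$end)
  lens <- ch$end - ch$start + 1L
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  list(sequence = paste(parts, collapse = ""),
       exons = data.frame(start = starts, end = ends))
}

cds_chain <- function(model, cds_id) {
  stopifnot(inherits(model, "gene_model"))
  ch <- model$cds[[cds_id]]
  if (is.null(ch)) stop("unknown CDS id '", cds_id, "' in gene ", model$gene_id)
  ch
}

#' Map CDS positions onto the gene
#'
#' \code{gpos} is the coordinate map from a position on a CDS to the matching
#' position on its source gene. It is strictly increasing and maps each CDS
#' exon bijectively onto its gene exon.
#'
#' @param model A \code{gene_model}.
#' @param cds_id CDS identifier.
#' @param k Integer vector of CDS positions, each in \code{1..|CDS|}.
#' @return Integer vector of gene positions.
#' @export
gpos <- function(model, cds_id, k) {
  ch <- cds_chain(model, cds_id)
  k <- as.integer(k)
  lens <- ch$end - ch$start + 1L
  cum_end <- cumsum(lens)
  m <- cum_end[length(cum_end)]
  if (any(is.na(k)) || any(k < 1L) || any(k > m))
    stop("CDS position out of range 1..", m)
  idx <- findInterval(k - 1L, cum_end) + 1L
  offset <- k - c(0L, cum_end)[idx] - 1L
  ch$start[idx] + offset
}

#' Read gene models from GFF3 and FASTA
#'
#' CDS features (column \code{type == "CDS"}) are grouped by their
#' \code{Parent} attribute into exon chains; the seqname of each feature names
#' the gene, whose sequence is looked up in the FASTA file. Coordinates are
#' taken as-is (GFF3 is 1-based inclusive). Features on the minus strand are
#' rejected: inputs must be pre-normalized to the coding strand.
#'
#' @param gff_path Path to a GFF3 file.
#' @param fasta_path Path to a FASTA file with one record per gene.
#' @return Named list of \code{gene_model} objects.
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  if (any(as.character(GenomicRanges::strand(gr)) == "-"))
    stop("minus-strand CDS features are not supported; pre-normalize to the coding strand")
  parent <- as.character(S4Vectors::mcols(gr)$Parent)
  gene <- as.character(GenomicRanges::seqnames(gr))
  models <- list()
  for (gid in unique(gene)) {
    if (!gid %in% names(seqs)) stop("no FASTA record for gene ", gid)
    sel <- gene == gid
    cds <- split(data.frame(start = GenomicRanges::start(gr)[sel],
                            end = GenomicRanges::end(gr)[sel]),
                 parent[sel])
    cds <- lapply(cds, function(df) df[order(df$start), , drop = FALSE])
    models[[gid]] <- gene_model(gid, as.character(seqs[[gid]]), cds)
  }
  models
}

#' Write gene models to GFF3 and FASTA
#'
#' @param models Named list of \code{gene_model} objects.
#' @param gff_path,fasta_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_gene_models <- function(models, gff_path, fasta_path) {
  rows <- list()
  for (m in models) {
    rows[[length(rows) + 1L]] <- data.frame(
      seq = m$gene_id, type = "gene", start = 1L, end = nchar(m$sequence),
      id = m$gene_id, parent = NA_character_)
    for (cid in names(m$cds)) {
      ch <- m$cds[[cid]]
      rows[[length(rows) + 1L]] <- data.frame(
        seq = m$gene_id, type = "mRNA", start = ch$start[1], end = ch$end[nrow(ch)],
        id = cid, parent = m$gene_id)
      rows[[length(rows) + 1L]] <- data.frame(
        seq = m$gene_id, type = "CDS", start = ch$start, end = ch$end,
        id = paste0(cid, ".cds", seq_len(nrow(ch))), parent = cid)
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(tab$seq, IRanges::IRanges(tab$start, tab$end),
                               strand = "+")
  S4Vectors::mcols(gr)$source <- "mspa"
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$phase <- ifelse(tab$type == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$ID <- tab$id
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(tab$parent), "", tab$parent)
  rtracklayer::export(gr, gff_path, format = "gff3")
  seqs <- Biostrings::DNAStringSet(vapply(models, function(m) m$sequence, ""))
  names(seqs) <- vapply(models, function(m) m$gene_id, "")
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(c(gff_path, fasta_path))
}

#' Read gene models from a JSON dialect
#'
#' Format: \code{{"gene_id": ..., "sequence": ..., "cds": {"id": [[a,b], ...]}}},
#' one object or a list of objects.
#'
#' @param path JSON file path.
#' @return Named list of \code{gene_model} objects.
#' @export
read_gene_models_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(x$gene_id)) x <- list(x)
  models <- list()
  for (g in x) {
    cds <- lapply(g$cds, function(ex)
      do.call(rbind, lapply(ex, function(ab) c(ab[[1]], ab[[2]]))))
    models[[g$gene_id]] <- gene_model(g$gene_id, g$sequence, cds)
  }
  models
}

## cds_id -> gene_id lookup across a model set; ids must be globally unique
cds_index <- function(models) {
  out <- list()
  for (m in models) for (cid in names(m$cds)) {
    if (!is.null(out[[cid]]))
      stop("CDS id '", cid, "' appears in more than one gene")
    out[[cid]] <- m$gene_id
  }
  out
}
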