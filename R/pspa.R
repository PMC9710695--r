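#' Construct a pairwise spliced alignment (PSpA)
#'
#' A PSpA aligns one CDS to one gene as an ordered chain of blocks. A
#' conserved block pairs a CDS segment with a gene segment and carries the
#' percent identity (in \code{[0,1]}) of the underlying segment alignment; a
#' deleted block has no gene counterpart (\code{NA} gene columns). CDS
#' segments must be strictly increasing and, unless \code{check_coverage} is
#' disabled, cover the CDS completely; gene segments of successive conserved
#' blocks must be strictly increasing.
#'
#' @param cds_id,gene_id Sequence identifiers.
#' @param blocks Data frame with columns \code{cds_start}, \code{cds_end},
#'   \code{gene_start}, \code{gene_end}, \code{pid}.
#' @param cds_length Optional CDS length to verify full coverage.
#' @param check_coverage Verify that CDS segments are gap-free from position 1.
#' @param require_pid Require a pid on every conserved block (disabled for
#'   alignments induced from an MSpA, which carry none).
#' @return Object of class \code{pspa}.
#' @export
pspa <- function(cds_id, gene_id, blocks, cds_length = NULL,
                 check_coverage = TRUE, require_pid = TRUE) {
  need <- c("cds_start", "cds_end", "gene_start", "gene_end", "pid")
  if (!all(need %in% names(blocks))) stop("missing block columns")
  blocks <- as.data.frame(blocks)[need]
  rownames(blocks) <- NULL
  blocks$cds_start <- as.integer(blocks$cds_start)
  blocks$cds_end <- as.integer(blocks$cds_end)
  blocks$gene_start <- as.integer(blocks$gene_start)
  blocks$gene_end <- as.integer(blocks$gene_end)
  blocks$pid <- as.numeric(blocks$pid)
  n <- nrow(blocks)
  if (n > 0L) {
    if (any(is.na(blocks$cds_start)) || any(is.na(blocks$cds_end)))
      stop("CDS coordinates must be present in every block")
    if (any(blocks$cds_end < blocks$cds_start)) stop("block cds_end < cds_start")
    if (any(is.na(blocks$gene_start) != is.na(blocks$gene_end)))
      stop("gene_start and gene_end must be both present or both absent")
    cons <- !is.na(blocks$gene_start)
    if (require_pid && any(cons & is.na(blocks$pid)))
      stop("conserved blocks must carry a pid")
    if (any(blocks$pid[cons] < 0 | blocks$pid[cons] > 1, na.rm = TRUE))
      stop("pid must lie in [0,1]")
    if (n > 1L && any(blocks$cds_start[-1L] <= blocks$cds_end[-n]))
      stop("CDS segments of successive blocks must be strictly increasing")
    gs <- blocks$gene_start[cons]; ge <- blocks$gene_end[cons]
    if (length(gs) > 1L && any(gs[-1L] <= ge[-length(ge)]))
      stop("gene segments of successive conserved blocks must be strictly increasing")
    if (any(ge < gs)) stop("block gene_end < gene_start")
    if (check_coverage) {
      if (blocks$cds_start[1] != 1L ||
          (n > 1L && any(blocks$cds_start[-1L] != blocks$cds_end[-n] + 1L)))
        stop("blocks must cover the CDS without gaps")
      if (!is.null(cds_length) && blocks$cds_end[n] != cds_length)
        stop("blocks do not reach the CDS end")
    }
  }
  structure(list(cds_id = cds_id, gene_id = gene_id, blocks = blocks),
            class = "pspa")
}

#' @export
print.pspa <- function(x, ...) {
  cat(sprintf("PSpA %s vs %s: %d block(s)\n", x$cds_id, x$gene_id,
              nrow(x$blocks)))
  print(x$blocks)
  invisible(x)
}

n_conserved_blocks <- function(p) sum(!is.na(p$blocks$gene_start))

#' Construct a PSpA set
#'
#' A PSpA set holds one PSpA per (CDS, gene) pair of C x G. Pairs without any
#' conserved homology are represented by deletion-only PSpAs.
#'
#' @param pspas List of \code{pspa} objects (at most one per pair).
#' @return Object of class \code{pspa_set}.
#' @export
pspa_set <- function(pspas = list()) {
  keys <- vapply(pspas, function(p) pspa_key(p$cds_id, p$gene_id), "")
  if (anyDuplicated(keys)) stop("duplicate (cds, gene) pair in PSpA set")
  names(pspas) <- keys
  structure(list(pspas = pspas), class = "pspa_set")
}

pspa_key <- function(cds_id, gene_id) paste0(cds_id, "\r", gene_id)

#' Look up the PSpA of a pair
#' @param X A \code{pspa_set}.
#' @param cds_id,gene_id Pair identifiers.
#' @return A \code{pspa} or \code{NULL}.
#' @export
pspa_for <- function(X, cds_id, gene_id) X$pspas[[pspa_key(cds_id, gene_id)]]

## one deleted block spanning the whole CDS
deletion_only_pspa <- function(cds_id, gene_id, cds_length) {
  pspa(cds_id, gene_id,
       data.frame(cds_start = 1L, cds_end = as.integer(cds_length),
                  gene_start = NA_integer_, gene_end = NA_integer_,
                  pid = NA_real_))
}

## ensure the set is complete over C x G, filling missing pairs
complete_pspa_set <- function(X, models, warn = TRUE) {
  idx <- cds_index(models)
  gene_ids <- vapply(models, function(m) m$gene_id, "")
  missing <- character(0)
  for (cid in names(idx)) for (gid in gene_ids) {
    if (is.null(pspa_for(X, cid, gid))) {
      m <- chain_length(models[[idx[[cid]]]]$cds[[cid]])
      X$pspas[[pspa_key(cid, gid)]] <- deletion_only_pspa(cid, gid, m)
      missing <- c(missing, paste0(cid, "/", gid))
    }
  }
  if (warn && length(missing) > 0L)
    warning("PSpA set missing pairs filled with deletion-only alignments: ",
            paste(missing, collapse = ", "))
  X
}

#' Read / write a PSpA set as TSV
#'
#' Columns: \code{cds_id}, \code{gene_id}, \code{block_index},
#' \code{cds_start}, \code{cds_end}, \code{gene_start}, \code{gene_end},
#' \code{pid}; empty gene columns mark deleted blocks. On read, each chain is
#' re-validated; when gene models are supplied, missing pairs of C x G are
#' filled with deletion-only PSpAs (with a warning).
#'
#' @param path TSV file path.
#' @param models Optional named list of \code{gene_model}s for completeness.
#' @return \code{read_pspa_set} returns a \code{pspa_set}.
#' @export
read_pspa_set <- function(path, models = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("cds_id", "gene_id", "block_index", "cds_start", "cds_end",
            "gene_start", "gene_end", "pid")
  if (!all(need %in% names(tab))) stop("malformed PSpA TSV: missing columns")
  pair <- paste0(tab$cds_id, "\r", tab$gene_id)
  pspas <- lapply(unique(pair), function(k) {
    rows <- tab[pair == k, , drop = FALSE]
    rows <- rows[order(rows$block_index), , drop = FALSE]
    if (!identical(as.integer(rows$block_index), seq_len(nrow(rows))))
      stop("block_index must run 1..n per pair")
    pspa(rows$cds_id[1], rows$gene_id[1], rows)
  })
  X <- pspa_set(pspas)
  if (!is.null(models)) X <- complete_pspa_set(X, models)
  X
}

#' @rdname read_pspa_set
#' @param X A \code{pspa_set}.
#' @export
write_pspa_set <- function(X, path) {
  rows <- lapply(X$pspas, function(p) {
    if (nrow(p$blocks) == 0L) return(NULL)
    cbind(data.frame(cds_id = p$cds_id, gene_id = p$gene_id,
                     block_index = seq_len(nrow(p$blocks))), p$blocks)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
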