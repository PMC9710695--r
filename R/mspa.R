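#' Construct a multiblock
#'
#' A multiblock maps sequence identifiers (CDSs or genes) to one segment each;
#' it represents a set of putatively homologous exon segments, at most one per
#' sequence.
#'
#' @param ... Named arguments, each a length-2 vector \code{c(start, end)}.
#' @return Named list of integer segments, class \code{multiblock}.
#' @examples
#' multiblock(g = c(4, 12), c1 = c(1, 4))
#' @export
multiblock <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.null(names(entries)) && is.list(entries[[1]]))
    entries <- entries[[1]]
  if (length(entries) == 0L) stop("a multiblock must be non-empty")
  if (is.null(names(entries)) || any(names(entries) == ""))
    stop("multiblock entries must be named by sequence id")
  if (anyDuplicated(names(entries)))
    stop("at most one segment per sequence id")
  entries <- lapply(entries, function(s) seg(s[1], s[2]))
  structure(entries[order(names(entries))], class = "multiblock")
}

mb_keys <- function(mb) names(mb)

#' Construct a multiple spliced alignment (MSpA)
#'
#' An MSpA is an ordered chain of multiblocks over a set of CDSs C and a set
#' of genes G. Validity (the four chain conditions) is checked separately by
#' \code{\link{validate_mspa}} because it needs the gene models.
#'
#' @param cds_ids Character vector of CDS identifiers C.
#' @param gene_ids Character vector of gene identifiers G.
#' @param multiblocks List of \code{multiblock} objects in chain order.
#' @return Object of class \code{mspa}.
#' @export
mspa <- function(cds_ids, gene_ids, multiblocks = list()) {
  multiblocks <- lapply(multiblocks, function(mb)
    if (inherits(mb, "multiblock")) mb else multiblock(mb))
  known <- c(cds_ids, gene_ids)
  for (mb in multiblocks)
    if (!all(mb_keys(mb) %in% known))
      stop("multiblock names a sequence outside C and G: ",
           paste(setdiff(mb_keys(mb), known), collapse = ", "))
  structure(list(cds_ids = sort(cds_ids), gene_ids = sort(gene_ids),
                 multiblocks = multiblocks), class = "mspa")
}

#' @export
print.mspa <- function(x, ...) {
  cat(sprintf("MSpA: %d CDSs, %d genes, %d multiblocks\n",
              length(x$cds_ids), length(x$gene_ids), length(x$multiblocks)))
  for (i in seq_along(x$multiblocks)) {
    mb <- x$multiblocks[[i]]
    cat(sprintf("  A[%d] %s\n", i, paste(
      sprintf("%s:(%d,%d)", mb_keys(mb),
              vapply(mb, `[`, 0L, 1), vapply(mb, `[`, 0L, 2)), collapse = " ")))
  }
  invisible(x)
}

#' Pairwise consistency of two multiblocks
#'
#' Classifies the relation of multiblock \code{a} to \code{b} over their
#' shared keys: \code{"before"} if every shared segment of \code{a} ends
#' before \code{b}'s starts, \code{"after"} for the converse, \code{"overlaps"}
#' if every shared pair of segments overlaps, and \code{"inconsistent"} if the
#' shared keys disagree. Multiblocks with disjoint key sets are freely
#' placeable and classified \code{"before"} by convention.
#'
#' @param a,b \code{multiblock} objects.
#' @return One of \code{"before"}, \code{"after"}, \code{"overlaps"},
#'   \code{"inconsistent"}.
#' @export
blocks_consistent <- function(a, b) {
  shared <- intersect(mb_keys(a), mb_keys(b))
  if (length(shared) == 0L) return("before")
  rel <- vapply(shared, function(x) {
    sa <- a[[x]]; sb <- b[[x]]
    if (seg_before(sa, sb)) "before"
    else if (seg_before(sb, sa)) "after"
    else "overlaps"
  }, "")
  u <- unique(rel)
  if (length(u) == 1L) u else "inconsistent"
}

## relation of a candidate against each multiblock of a chain, with disjoint
## key sets reported as "free" (placeable anywhere) rather than "before"
chain_relations <- function(a, chain) {
  vapply(chain, function(mb) {
    if (length(intersect(mb_keys(a), mb_keys(mb))) == 0L) "free"
    else blocks_consistent(a, mb)
  }, "")
}

## do the non-free relations, in chain order, admit a chain position?
## valid pattern: after*, at most one overlap (a multiblock overlapping two
## chain members sharing keys could never satisfy cond 2), then before*
relations_admit_position <- function(rel) {
  r <- rel[rel != "free"]
  if (any(r == "inconsistent")) return(FALSE)
  if (sum(r == "overlaps") > 1L) return(FALSE)
  state <- 1L  # 1 = afters, 2 = overlaps, 3 = befores
  for (x in r) {
    if (x == "after") { if (state > 1L) return(FALSE) }
    else if (x == "overlaps") { if (state > 2L) return(FALSE); state <- 2L }
    else state <- 3L
  }
  TRUE
}

#' Consistency of a multiblock with an MSpA
#'
#' A multiblock is consistent with an MSpA if it is pairwise consistent with
#' every multiblock of the chain and its before/after relations admit a
#' position in the chain (no ordering cycle).
#'
#' @param a A \code{multiblock}.
#' @param A An \code{mspa}.
#' @return Logical.
#' @export
consistent_with_mspa <- function(a, A) {
  stopifnot(inherits(A, "mspa"))
  relations_admit_position(chain_relations(a, A$multiblocks))
}

#' Induce a pairwise spliced alignment from an MSpA
#'
#' Reduces the MSpA to the multiblocks containing \code{cds_id}, then drops
#' all entries except \code{cds_id} and \code{gene_id}. Multiblocks lacking
#' the gene become deleted blocks (no gene segment). Block percent identities
#' are not defined for induced alignments and are reported as \code{NA}.
#'
#' @param A An \code{mspa}.
#' @param cds_id CDS in \code{A$cds_ids}.
#' @param gene_id Gene in \code{A$gene_ids}.
#' @return A \code{\link{pspa}}.
#' @export
induce_pspa <- function(A, cds_id, gene_id) {
  stopifnot(inherits(A, "mspa"))
  if (!cds_id %in% A$cds_ids) stop("unknown CDS id: ", cds_id)
  if (!gene_id %in% A$gene_ids) stop("unknown gene id: ", gene_id)
  keep <- Filter(function(mb) cds_id %in% mb_keys(mb), A$multiblocks)
  blocks <- do.call(rbind, lapply(keep, function(mb) {
    cs <- mb[[cds_id]]
    gs <- mb[[gene_id]]
    data.frame(cds_start = cs[1], cds_end = cs[2],
               gene_start = if (is.null(gs)) NA_integer_ else gs[1],
               gene_end = if (is.null(gs)) NA_integer_ else gs[2],
               pid = NA_real_)
  }))
  if (is.null(blocks))
    blocks <- data.frame(cds_start = integer(0), cds_end = integer(0),
                         gene_start = integer(0), gene_end = integer(0),
                         pid = numeric(0))
  pspa(cds_id, gene_id, blocks, check_coverage = FALSE, require_pid = FALSE)
}

#' Validate an MSpA against its gene models
#'
#' Checks the four chain conditions: (1) every multiblock is non-empty;
#' (2) for any sequence in two multiblocks the earlier segment ends strictly
#' before the later one starts; (3) the segments induced for every CDS cover
#' it entirely; (4) every multiblock containing a CDS also contains its source
#' gene, with the CDS segment's coordinate projection contained in the gene
#' segment (enforced for conserved content).
#'
#' @param A An \code{mspa}.
#' @param models Named list of \code{gene_model} objects covering all genes.
#' @return Data frame of violations (empty when valid) with columns
#'   \code{cond}, \code{index}, \code{seq_id}, \code{message}.
#' @export
validate_mspa <- function(A, models) {
  stopifnot(inherits(A, "mspa"))
  idx <- cds_index(models)
  v <- list()
  bad <- function(cond, index, seq_id, msg)
    data.frame(cond = cond, index = index, seq_id = seq_id, message = msg)
  mbs <- A$multiblocks
  for (i in seq_along(mbs))
    if (length(mbs[[i]]) == 0L)
      v[[length(v) + 1L]] <- bad(1L, i, NA_character_, "empty multiblock")
  ## cond 2
  for (x in c(A$cds_ids, A$gene_ids)) {
    prev_end <- -Inf; prev_i <- NA_integer_
    for (i in seq_along(mbs)) {
      s <- mbs[[i]][[x]]
      if (is.null(s)) next
      if (s[1] <= prev_end)
        v[[length(v) + 1L]] <- bad(2L, i, x, sprintf(
          "segment (%d,%d) does not start after end %d of multiblock %d",
          s[1], s[2], as.integer(prev_end), prev_i))
      prev_end <- s[2]; prev_i <- i
    }
  }
  ## cond 3
  for (cid in A$cds_ids) {
    gid <- idx[[cid]]
    if (is.null(gid)) {
      v[[length(v) + 1L]] <- bad(3L, NA_integer_, cid, "CDS absent from models")
      next
    }
    m <- chain_length(models[[gid]]$cds[[cid]])
    covered <- logical(m)
    for (i in seq_along(mbs)) {
      s <- mbs[[i]][[cid]]
      if (is.null(s)) next
      if (s[2] > m) {
        v[[length(v) + 1L]] <- bad(3L, i, cid, "segment beyond CDS length")
        next
      }
      covered[s[1]:s[2]] <- TRUE
    }
    if (!all(covered))
      v[[length(v) + 1L]] <- bad(3L, NA_integer_, cid, sprintf(
        "positions not covered: %s", paste(which(!covered), collapse = ",")))
  }
  ## cond 4
  for (i in seq_along(mbs)) {
    mb <- mbs[[i]]
    for (cid in intersect(mb_keys(mb), A$cds_ids)) {
      gid <- idx[[cid]]
      if (is.null(gid)) next
      s <- mb[[cid]]
      m <- chain_length(models[[gid]]$cds[[cid]])
      if (s[2] > m) next  # already reported under cond 3
      if (is.null(mb[[gid]])) {
        v[[length(v) + 1L]] <- bad(4L, i, cid,
          sprintf("source gene %s absent from multiblock", gid))
        next
      }
      proj <- c(gpos(models[[gid]], cid, s[1]), gpos(models[[gid]], cid, s[2]))
      if (!seg_contains(mb[[gid]], proj))
        v[[length(v) + 1L]] <- bad(4L, i, cid, sprintf(
          "projection (%d,%d) not inside gene segment (%d,%d)",
          proj[1], proj[2], mb[[gid]][1], mb[[gid]][2]))
    }
  }
  if (length(v) == 0L)
    return(data.frame(cond = integer(0), index = integer(0),
                      seq_id = character(0), message = character(0)))
  do.call(rbind, v)
}

#' Write / read an MSpA as JSON
#'
#' Serialization: \code{{"cds_ids": [...], "gene_ids": [...],
#' "multiblocks": [{"seq": [start, end], ...}, ...]}} in chain order.
#'
#' @param A An \code{mspa}.
#' @param path File path.
#' @return \code{read_mspa} returns an \code{mspa}; \code{write_mspa} the path,
#'   invisibly.
#' @export
write_mspa <- function(A, path) {
  stopifnot(inherits(A, "mspa"))
  x <- list(cds_ids = A$cds_ids, gene_ids = A$gene_ids,
            multiblocks = lapply(A$multiblocks, function(mb)
              lapply(mb, function(s) c(s[1], s[2]))))
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_mspa
#' @export
read_mspa <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mbs <- lapply(x$multiblocks, function(mb)
    multiblock(lapply(mb, function(s) c(s[[1]], s[[2]]))))
  mspa(unlist(x$cds_ids), unlist(x$gene_ids), mbs)
}
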