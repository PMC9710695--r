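## Greedy multiblock assembly: post-split graph components become candidate
## multiblocks, inserted by decreasing size into a growing consistent chain,
## followed by coverage patching so every CDS is covered entirely.

#' Turn post-split components into candidate multiblocks
#'
#' Each connected component yields one candidate: for every sequence with
#' vertices in the component, the interval union of its (pairwise
#' overlapping) segments. Candidates are sorted by decreasing size (number of
#' sequences), ties broken by the smallest gene start of the
#' lexicographically smallest gene id, then by the full entry signature.
#'
#' @param G Graph after \code{\link{split_components}}.
#' @return List of \code{multiblock}s in insertion order, with component
#'   labels in attribute \code{component}.
#' @export
components_to_candidates <- function(G) {
  if (igraph::vcount(G) == 0L)
    return(structure(list(), component = integer(0)))
  memb <- ordered_components(G)
  vt <- data.frame(seq_id = igraph::V(G)$seq_id, start = igraph::V(G)$start,
                   end = igraph::V(G)$end, kind = igraph::V(G)$kind,
                   component = memb)
  comp_ids <- sort(unique(memb))
  cands <- list(); genes_of <- list()
  for (ci in comp_ids) {
    sub <- vt[vt$component == ci, , drop = FALSE]
    entries <- list()
    for (sid in sort(unique(sub$seq_id))) {
      ss <- sub[sub$seq_id == sid, , drop = FALSE]
      s <- c(min(ss$start), max(ss$end))
      ## same-sequence segments in one component must pairwise overlap
      ss <- ss[order(ss$start), , drop = FALSE]
      if (nrow(ss) > 1L && any(ss$start[-1L] > cummax(ss$end[-nrow(ss)]) + 0L))
        stop("component ", ci, " still holds non-overlapping segments of ", sid)
      entries[[sid]] <- s
    }
    cands[[length(cands) + 1L]] <- multiblock(entries)
    genes_of[[length(cands)]] <- sort(unique(sub$seq_id[sub$kind == "gene"]))
  }
  key <- vapply(seq_along(cands), function(i) {
    mb <- cands[[i]]; g <- genes_of[[i]]
    g0 <- if (length(g)) g[1] else sort(mb_keys(mb))[1]
    sig <- paste(sprintf("%s:%d-%d", mb_keys(mb),
                         vapply(mb, `[`, 0L, 1), vapply(mb, `[`, 0L, 2)),
                 collapse = ";")
    sprintf("%06d\r%s\r%020d\r%020d\r%s", 999999L - length(mb), g0,
            mb[[g0]][1], mb[[g0]][2], sig)
  }, "")
  ord <- order(key)
  structure(cands[ord], component = comp_ids[ord])
}

## sortable placement key for a multiblock: smallest gene id and its start
mb_order_key <- function(mb, gene_ids) {
  g <- sort(intersect(mb_keys(mb), gene_ids))
  g0 <- if (length(g)) g[1] else sort(mb_keys(mb))[1]
  sprintf("%s\r%020d", g0, mb[[g0]][1])
}

## cond 2 over a whole chain: per key, strictly increasing segments
chain_cond2_ok <- function(chain) {
  keys <- unique(unlist(lapply(chain, mb_keys)))
  for (x in keys) {
    prev <- -Inf
    for (mb in chain) {
      s <- mb[[x]]
      if (is.null(s)) next
      if (s[1] <= prev) return(FALSE)
      prev <- s[2]
    }
  }
  TRUE
}

## try to place one multiblock into a chain; returns list(chain, action)
chain_insert <- function(chain, cand, gene_ids) {
  if (length(chain) == 0L)
    return(list(chain = list(cand), action = "inserted"))
  rels <- chain_relations(cand, chain)
  if (!relations_admit_position(rels))
    return(list(chain = chain, action = "skipped: inconsistent with chain"))
  ov <- which(rels == "overlaps")
  if (length(ov) > 1L)
    return(list(chain = chain, action = "skipped: overlaps several multiblocks"))
  if (length(ov) == 1L) {
    o <- ov[1]
    merged <- chain[[o]]
    for (x in mb_keys(cand)) {
      if (is.null(merged[[x]])) merged[[x]] <- cand[[x]]
      else {
        u <- seg_union(merged[[x]], cand[[x]])
        if (is.null(u))
          return(list(chain = chain, action = "skipped: non-contiguous merge"))
        merged[[x]] <- u
      }
    }
    merged <- multiblock(merged)
    new_chain <- chain; new_chain[[o]] <- merged
    if (!chain_cond2_ok(new_chain))
      return(list(chain = chain, action = "skipped: merge breaks chain order"))
    return(list(chain = new_chain, action = sprintf("merged into %d", o)))
  }
  lo <- if (any(rels == "after")) max(which(rels == "after")) + 1L else 1L
  hi <- if (any(rels == "before")) min(which(rels == "before")) else
    length(chain) + 1L
  if (lo > hi)
    return(list(chain = chain, action = "skipped: no chain position"))
  p <- lo
  k <- mb_order_key(cand, gene_ids)
  while (p < hi && mb_order_key(chain[[p]], gene_ids) <= k) p <- p + 1L
  new_chain <- append(chain, list(cand), after = p - 1L)
  if (!chain_cond2_ok(new_chain))
    return(list(chain = chain, action = "skipped: insertion breaks chain order"))
  list(chain = new_chain, action = sprintf("inserted at %d", p))
}

#' Greedy assembly of candidate multiblocks into an MSpA
#'
#' Candidates are taken in order (decreasing size) and inserted when
#' consistent with the growing chain; a candidate whose relation to one
#' existing multiblock is overlap is merged into it when the interval union
#' keeps at most one contiguous segment per sequence, and skipped otherwise.
#' After the sweep, any CDS stretch still uncovered is patched in: positions
#' whose gene projection falls inside an existing multiblock's gene segment
#' join that multiblock, the rest form new multiblocks of the CDS segment and
#' its own-gene projection, so that the four chain conditions hold. The
#' result is validated before being returned.
#'
#' @param candidates List of \code{multiblock}s (from
#'   \code{\link{components_to_candidates}}), or any multiblocks in the
#'   desired insertion order.
#' @param models Named list of \code{gene_model} objects.
#' @param order Optional permutation of \code{seq_along(candidates)} giving an
#'   alternative insertion order (used for robustness experiments).
#' @return A valid \code{\link{mspa}}; insertion decisions are recorded in
#'   attribute \code{log}.
#' @export
assemble <- function(candidates, models, order = NULL) {
  gene_ids <- vapply(models, function(m) m$gene_id, "")
  idx <- cds_index(models)
  if (is.null(order)) order <- seq_along(candidates)
  chain <- list(); log <- character(0)
  for (i in order) {
    res <- chain_insert(chain, candidates[[i]], gene_ids)
    chain <- res$chain
    log <- c(log, sprintf("candidate %d: %s", i, res$action))
  }
  ## coverage patching
  for (cid in sort(names(idx))) {
    gid <- idx[[cid]]
    model <- models[[gid]]
    m <- chain_length(model$cds[[cid]])
    exon_of <- rep(seq_len(nrow(cds_sequence(model, cid)$exons)),
                   times = {e <- cds_sequence(model, cid)$exons; e$end - e$start + 1L})
    repeat {
      covered <- logical(m)
      for (mb in chain) if (!is.null(mb[[cid]]))
        covered[mb[[cid]][1]:mb[[cid]][2]] <- TRUE
      if (all(covered)) break
      k0 <- which(!covered)[1]
      lab0 <- patch_label(chain, gid, gpos(model, cid, k0))
      k1 <- k0
      while (k1 < m && !covered[k1 + 1L] && exon_of[k1 + 1L] == exon_of[k0] &&
             identical(patch_label(chain, gid, gpos(model, cid, k1 + 1L)), lab0))
        k1 <- k1 + 1L
      segc <- c(k0, k1)
      if (lab0 > 0L) {
        mb <- chain[[lab0]]
        mb[[cid]] <- if (is.null(mb[[cid]])) segc else {
          u <- seg_union(mb[[cid]], segc)
          if (is.null(u)) stop("patch for ", cid, " not contiguous with multiblock")
          u
        }
        new_chain <- chain; new_chain[[lab0]] <- multiblock(mb)
        if (!chain_cond2_ok(new_chain))
          stop("coverage patch for ", cid, " breaks chain order")
        chain <- new_chain
        log <- c(log, sprintf("patched %s:(%d,%d) into multiblock %d",
                              cid, k0, k1, lab0))
      } else {
        proj <- c(gpos(model, cid, k0), gpos(model, cid, k1))
        patch <- multiblock(stats::setNames(list(segc, proj), c(cid, gid)))
        res <- chain_insert(chain, patch, gene_ids)
        if (!startsWith(res$action, "inserted") &&
            !startsWith(res$action, "merged"))
          stop("cannot place coverage patch for ", cid, ": ", res$action)
        chain <- res$chain
        log <- c(log, sprintf("patch multiblock %s:(%d,%d): %s",
                              cid, k0, k1, res$action))
      }
    }
  }
  A <- mspa(sort(names(idx)), sort(unname(gene_ids)), chain)
  viol <- validate_mspa(A, models)
  if (nrow(viol) > 0L)
    stop("assembled chain violates MSpA conditions:\n",
         paste(utils::capture.output(print(viol)), collapse = "\n"))
  attr(A, "log") <- log
  A
}

## index of the chain multiblock whose segment of gene gid contains position p
patch_label <- function(chain, gid, p) {
  for (i in seq_along(chain)) {
    s <- chain[[i]][[gid]]
    if (!is.null(s) && s[1] <= p && p <= s[2]) return(i)
  }
  0L
}

#' Count input PSpA blocks contained in an MSpA's multiblocks
#'
#' The assembly objective: a conserved block of a PSpA of (c, h) is counted
#' when some multiblock contains both c and h with the block's segments
#' inside the multiblock's.
#'
#' @param X A \code{\link{pspa_set}}.
#' @param A An \code{\link{mspa}}.
#' @return Integer count.
#' @export
count_included_blocks <- function(X, A) {
  total <- 0L
  for (p in X$pspas) {
    b <- p$blocks
    for (i in seq_len(nrow(b))) {
      if (is.na(b$gene_start[i])) next
      cs <- c(b$cds_start[i], b$cds_end[i])
      gs <- c(b$gene_start[i], b$gene_end[i])
      for (mb in A$multiblocks) {
        mc <- mb[[p$cds_id]]; mg <- mb[[p$gene_id]]
        if (!is.null(mc) && !is.null(mg) &&
            seg_contains(mc, cs) && seg_contains(mg, gs)) {
          total <- total + 1L
          break
        }
      }
    }
  }
  total
}

#' Full multiblock pipeline: PSpAs to MSpA
#'
#' Convenience wrapper chaining \code{\link{build_graph}},
#' \code{\link{weight_edges}}, \code{\link{split_components}},
#' \code{\link{components_to_candidates}} and \code{\link{assemble}}.
#'
#' @param X A \code{\link{pspa_set}} (completed over C x G if needed).
#' @param models Named list of \code{gene_model} objects.
#' @return A valid \code{\link{mspa}}; the post-split graph is attached as
#'   attribute \code{graph}.
#' @export
build_mspa <- function(X, models) {
  G <- build_graph(X, models)
  G <- weight_edges(G)
  G <- split_components(G)
  cands <- components_to_candidates(G)
  A <- assemble(cands, models)
  attr(A, "graph") <- G
  A
}
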