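## Spliced alignment graph: vertices are CDS/gene segments, edges are block
## edges (cross-gene alignments from conserved PSpA blocks) and CDS edges
## (a CDS segment tied to its coordinate projection on its own gene).

vert_name <- function(seq_id, s) sprintf("%s:%d-%d", seq_id, s[1], s[2])

#' Build the spliced alignment graph of a PSpA set
#'
#' Every conserved block of a PSpA of CDS c (of gene g) against gene h
#' contributes the CDS segment, the gene segment on h and the projection
#' segment on g as vertices, a block edge (CDS segment, h segment) carrying
#' the block's PID, and a CDS edge (CDS segment, projection) with PID 1.
#' When h equals g the block contributes a single CDS edge. Deleted blocks
#' contribute nothing. Vertices are deduplicated by (sequence, start, end).
#'
#' @param X A \code{\link{pspa_set}}, complete over C x G.
#' @param models Named list of \code{gene_model} objects.
#' @return An undirected \code{igraph} graph with vertex attributes
#'   \code{seq_id}, \code{start}, \code{end}, \code{kind} and edge attributes
#'   \code{kind}, \code{pid} (\code{connect} after
#'   \code{\link{weight_edges}}).
#' @export
build_graph <- function(X, models) {
  idx <- cds_index(models)
  verts <- new.env(parent = emptyenv())
  edges <- new.env(parent = emptyenv())
  add_vert <- function(seq_id, s, kind) {
    nm <- vert_name(seq_id, s)
    if (is.null(verts[[nm]]))
      verts[[nm]] <- data.frame(name = nm, seq_id = seq_id, start = s[1],
                                end = s[2], kind = kind)
    nm
  }
  add_edge <- function(u, v, kind, pid) {
    key <- paste(sort(c(u, v)), collapse = "\r")
    prev <- edges[[key]]
    if (is.null(prev) || pid > prev$pid)
      edges[[key]] <- data.frame(from = u, to = v, kind = kind, pid = pid)
  }
  for (p in X$pspas) {
    cid <- p$cds_id; hid <- p$gene_id
    gid <- idx[[cid]]
    if (is.null(gid)) stop("CDS ", cid, " absent from models")
    src <- models[[gid]]
    b <- p$blocks
    for (i in seq_len(nrow(b))) {
      if (is.na(b$gene_start[i])) next
      cs <- c(b$cds_start[i], b$cds_end[i])
      gs <- c(b$gene_start[i], b$gene_end[i])
      proj <- tryCatch(c(gpos(src, cid, cs[1]), gpos(src, cid, cs[2])),
                       error = function(e) NULL)
      if (is.null(proj)) {
        warning("block ", i, " of ", cid, "/", hid,
                " projects outside its CDS; skipped")
        next
      }
      vc <- add_vert(cid, cs, "cds")
      if (identical(hid, gid)) {
        vg <- add_vert(hid, gs, "gene")
        add_edge(vc, vg, "cds", 1)
      } else {
        vh <- add_vert(hid, gs, "gene")
        vp <- add_vert(gid, proj, "gene")
        add_edge(vc, vh, "block", b$pid[i])
        add_edge(vc, vp, "cds", 1)
      }
    }
  }
  vtab <- do.call(rbind, mget(ls(verts), envir = verts))
  etab <- do.call(rbind, mget(ls(edges), envir = edges))
  if (is.null(vtab))
    return(igraph::make_empty_graph(directed = FALSE))
  vtab <- vtab[order(vtab$seq_id, vtab$start, vtab$end), , drop = FALSE]
  if (is.null(etab))
    etab <- data.frame(from = character(0), to = character(0),
                       kind = character(0), pid = numeric(0))
  etab <- etab[order(etab$from, etab$to), , drop = FALSE]
  igraph::graph_from_data_frame(etab, directed = FALSE, vertices = vtab)
}

#' Assign confidence weights to graph edges
#'
#' Two confidence scores per edge: \code{pid}, the percent identity of the
#' pairwise segment alignment the edge represents (set at construction; 1 for
#' CDS edges, which are exact by definition), and \code{connect}, the strength
#' of connectivity between the endpoints, computed as the Jaccard index of the
#' endpoints' neighbor sets (excluding the endpoints themselves). An edge
#' whose endpoints have no other neighbors gets \code{connect = 1}.
#'
#' @param G Graph from \code{\link{build_graph}}.
#' @param connect_fun Optional replacement \code{function(u_nbrs, v_nbrs)}
#'   returning a score in \code{[0,1]}, to swap in an alternative definition.
#' @return The graph with the \code{connect} edge attribute set.
#' @export
weight_edges <- function(G, connect_fun = NULL) {
  if (igraph::ecount(G) == 0L) return(G)
  if (is.null(connect_fun))
    connect_fun <- function(u_nbrs, v_nbrs) {
      uni <- union(u_nbrs, v_nbrs)
      if (length(uni) == 0L) return(1)
      length(intersect(u_nbrs, v_nbrs)) / length(uni)
    }
  ends <- igraph::ends(G, igraph::E(G), names = FALSE)
  adj <- igraph::adjacent_vertices(G, igraph::V(G))
  conn <- vapply(seq_len(nrow(ends)), function(i) {
    u <- ends[i, 1]; v <- ends[i, 2]
    nu <- setdiff(as.integer(adj[[u]]), c(u, v))
    nv <- setdiff(as.integer(adj[[v]]), c(u, v))
    connect_fun(nu, nv)
  }, 0)
  igraph::E(G)$connect <- conn
  G
}

## component membership with deterministic component ordering:
## decreasing vertex count, ties by smallest vertex name
ordered_components <- function(G) {
  comp <- igraph::components(G)
  nm <- igraph::V(G)$name
  first <- vapply(seq_len(comp$no), function(i) min(nm[comp$membership == i]), "")
  ord <- order(-comp$csize, first)
  relabel <- integer(comp$no); relabel[ord] <- seq_len(comp$no)
  relabel[comp$membership]
}

#' Find same-sequence conflicts inside connected components
#'
#' A connected component cannot become a multiblock if it holds two
#' non-overlapping segments of one sequence. Returns every such unordered
#' vertex pair, with its component label.
#'
#' @param G Graph from \code{\link{build_graph}}.
#' @return Data frame with columns \code{component}, \code{seq_id}, \code{v1},
#'   \code{v2}, ordered deterministically.
#' @export
find_conflicts <- function(G) {
  empty <- data.frame(component = integer(0), seq_id = character(0),
                      v1 = character(0), v2 = character(0))
  if (igraph::vcount(G) == 0L) return(empty)
  memb <- ordered_components(G)
  vt <- data.frame(name = igraph::V(G)$name, seq_id = igraph::V(G)$seq_id,
                   start = igraph::V(G)$start, end = igraph::V(G)$end,
                   component = memb)
  out <- list()
  for (ci in sort(unique(vt$component))) {
    sub <- vt[vt$component == ci, , drop = FALSE]
    for (sid in sort(unique(sub$seq_id))) {
      ss <- sub[sub$seq_id == sid, , drop = FALSE]
      ss <- ss[order(ss$start, ss$end), , drop = FALSE]
      n <- nrow(ss)
      if (n < 2L) next
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        a <- c(ss$start[i], ss$end[i]); b <- c(ss$start[j], ss$end[j])
        if (!seg_overlaps(a, b))
          out[[length(out) + 1L]] <- data.frame(
            component = ci, seq_id = sid, v1 = ss$name[i], v2 = ss$name[j])
      }
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Split conflicting components by removing low-confidence edges
#'
#' While a component holds two non-overlapping segments of one sequence, the
#' conflicting pair (first in deterministic order) is disconnected by a
#' minimum-capacity edge cut under capacity \code{pid * connect}; CDS edges
#' get effectively infinite capacity and are never removed.
#'
#' @param G Weighted graph (after \code{\link{weight_edges}}).
#' @return The graph with conflict-resolving edges removed; removed edges are
#'   recorded in the \code{removed_edges} graph attribute.
#' @export
split_components <- function(G) {
  removed <- data.frame(from = character(0), to = character(0),
                        kind = character(0), pid = numeric(0),
                        connect = numeric(0))
  repeat {
    conf <- find_conflicts(G)
    if (nrow(conf) == 0L) break
    v1 <- conf$v1[1]; v2 <- conf$v2[1]
    caps <- ifelse(igraph::E(G)$kind == "cds", 1e9,
                   igraph::E(G)$pid * igraph::E(G)$connect)
    cut <- igraph::min_cut(G, source = v1, target = v2, capacity = caps,
                           value.only = FALSE)
    eids <- cut$cut
    if (length(eids) == 0L)
      stop("internal error: empty cut for conflicting pair")
    kinds <- igraph::E(G)$kind[eids]
    if (any(kinds == "cds"))
      stop("conflict resolvable only through CDS edges; inconsistent input")
    ep <- igraph::ends(G, eids)
    removed <- rbind(removed, data.frame(
      from = ep[, 1], to = ep[, 2], kind = kinds,
      pid = igraph::E(G)$pid[eids], connect = igraph::E(G)$connect[eids]))
    G <- igraph::delete_edges(G, eids)
  }
  G <- igraph::set_graph_attr(G, "removed_edges", removed)
  G
}

#' Dump a graph's edges and component labels to TSV (debugging aid)
#'
#' @param G Graph.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
graph_dump <- function(G, path) {
  memb <- ordered_components(G)
  names(memb) <- igraph::V(G)$name
  ep <- igraph::ends(G, igraph::E(G))
  tab <- data.frame(from = ep[, 1], to = ep[, 2], kind = igraph::E(G)$kind,
                    pid = igraph::E(G)$pid,
                    connect = if (!is.null(igraph::E(G)$connect))
                      igraph::E(G)$connect else NA_real_,
                    component = memb[ep[, 1]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
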