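# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (explicit position sets, pair
# enumeration) rather than calling the code paths they check.

# gene structure by transitive clustering of exons that share >= 1 position
# (abutting exons are kept separate; only genuine overlap merges)
oracle_structure <- function(exons) {
  n <- nrow(exons)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (exons$start[i] <= exons$end[j] && exons$start[j] <= exons$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  segs <- lapply(split(seq_len(n), roots), function(ix)
    c(min(exons$start[ix]), max(exons$end[ix])))
  segs <- segs[order(vapply(segs, `[`, 0L, 1))]
  data.frame(start = unname(vapply(segs, `[`, 0L, 1)),
             end = unname(vapply(segs, `[`, 0L, 2)))
}

# full CDS-position -> gene-position map by concatenation
oracle_gpos_map <- function(chain) {
  unlist(mapply(seq, chain$start, chain$end, SIMPLIFY = FALSE))
}

# aligned nucleotide pairs by explicit double loop over columns and row pairs
oracle_msa_pairs <- function(msa) {
  ids <- names(msa)
  out <- character(0)
  mat <- do.call(rbind, strsplit(as.character(msa), ""))
  counters <- integer(length(ids))
  for (col in seq_len(ncol(mat))) {
    nz <- which(mat[, col] != "-")
    counters[nz] <- counters[nz] + 1L
    if (length(nz) < 2L) next
    for (a in seq_len(length(nz) - 1L)) for (b in (a + 1L):length(nz)) {
      i <- nz[a]; j <- nz[b]
      if (ids[i] < ids[j])
        out <- c(out, sprintf("%s:%d|%s:%d", ids[i], counters[i],
                              ids[j], counters[j]))
      else
        out <- c(out, sprintf("%s:%d|%s:%d", ids[j], counters[j],
                              ids[i], counters[i]))
    }
  }
  out
}

# Rand index by explicit element-pair agreement
oracle_rand <- function(p1, p2) {
  els <- sort(unlist(p1))
  n <- length(els)
  if (n < 2L) return(1)
  grp <- function(p, e) which(vapply(p, function(g) e %in% g, TRUE))
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    total <- total + 1L
    same1 <- grp(p1, els[i]) == grp(p1, els[j])
    same2 <- grp(p2, els[i]) == grp(p2, els[j])
    if (same1 == same2) agree <- agree + 1L
  }
  agree / total
}

# all set partitions of a character vector
all_partitions <- function(els) {
  if (length(els) == 0L) return(list(list()))
  if (length(els) == 1L) return(list(list(els)))
  head <- els[1]
  rest <- all_partitions(els[-1])
  out <- list()
  for (p in rest) {
    for (k in seq_along(p)) {
      q <- p; q[[k]] <- c(head, q[[k]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(head), p)
  }
  out
}

# literal expansion of the four MSpA chain conditions
oracle_mspa_valid <- function(A, models) {
  mbs <- A$multiblocks
  if (any(vapply(mbs, length, 0L) == 0L)) return(FALSE)
  n <- length(mbs)
  if (n >= 2L) for (i1 in seq_len(n - 1L)) for (i2 in (i1 + 1L):n)
    for (x in intersect(names(mbs[[i1]]), names(mbs[[i2]])))
      if (!(mbs[[i1]][[x]][2] < mbs[[i2]][[x]][1])) return(FALSE)
  gene_of <- function(cid) {
    for (m in models) if (cid %in% names(m$cds)) return(m$gene_id)
    NA_character_
  }
  for (cid in A$cds_ids) {
    gid <- gene_of(cid)
    ch <- models[[gid]]$cds[[cid]]
    len <- sum(ch$end - ch$start + 1L)
    pos <- integer(0)
    for (mb in mbs) if (cid %in% names(mb))
      pos <- c(pos, mb[[cid]][1]:mb[[cid]][2])
    if (any(pos > len)) return(FALSE)
    if (!all(seq_len(len) %in% pos)) return(FALSE)
  }
  for (mb in mbs) for (cid in intersect(names(mb), A$cds_ids)) {
    gid <- gene_of(cid)
    if (!(gid %in% names(mb))) return(FALSE)
    map <- oracle_gpos_map(models[[gid]]$cds[[cid]])
    pr <- c(map[mb[[cid]][1]], map[mb[[cid]][2]])
    if (anyNA(pr)) return(FALSE)
    if (pr[1] < mb[[gid]][1] || pr[2] > mb[[gid]][2]) return(FALSE)
  }
  TRUE
}

# random gapped alignment over a given alphabet whose rows ungap to random
# sequences; returns a multiple_alignment
random_alignment <- function(n_rows, n_cols = 12L) {
  rows <- vapply(seq_len(n_rows), function(i) {
    ch <- sample(c("A", "C", "G", "T", "-"), n_cols, replace = TRUE,
                 prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
    if (all(ch == "-")) ch[1] <- "A"
    paste(ch, collapse = "")
  }, "")
  names(rows) <- paste0("s", seq_len(n_rows))
  multiple_alignment(rows)
}

# helper to construct a weighted segment graph directly (for conflict and
# min-cut tests): verts = data.frame(name, seq_id, start, end, kind),
# edges = data.frame(from, to, kind, pid)
segment_graph <- function(verts, edges) {
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}
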