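test_that("build_graph follows the block/CDS edge construction rules", {
  models <- example_gene_models()
  # single conserved block of c (on g) vs gene h: 3 vertices, block + CDS edge
  one <- pspa_set(list(pspa("c1", "h", data.frame(
    cds_start = 1, cds_end = 21, gene_start = 7, gene_end = 27, pid = 0.8),
    check_coverage = TRUE)))
  G1 <- build_graph(one, models)
  expect_equal(igraph::vcount(G1), 3L)
  expect_equal(igraph::ecount(G1), 2L)
  expect_setequal(igraph::E(G1)$kind, c("block", "cds"))
  expect_setequal(igraph::E(G1)$pid, c(0.8, 1))

  # self-pairs only: CDS edges only (degenerate case of the definition)
  selfs <- pspa_set(lapply(c("c1", "c2"), function(cid)
    align_pair(models$g, cid, models$g)))
  G2 <- build_graph(selfs, models)
  expect_true(all(igraph::E(G2)$kind == "cds"))

  # worked-example fixture: 26 segment vertices, 24 edges, 7 components
  G <- build_graph(example_pspa_set(), models)
  expect_equal(igraph::vcount(G), 26L)
  expect_equal(igraph::ecount(G), 24L)
  expect_equal(igraph::components(G)$no, 7L)
  expect_equal(sum(igraph::E(G)$kind == "block"), 12L)
  expect_equal(sum(igraph::E(G)$kind == "cds"), 12L)
})

test_that("connect weights equal the Jaccard index of endpoint neighborhoods", {
  models <- example_gene_models()
  G <- weight_edges(build_graph(example_pspa_set(), models))
  ends <- igraph::ends(G, igraph::E(G), names = TRUE)
  nbrs <- lapply(igraph::V(G), function(v)
    igraph::V(G)$name[as.integer(igraph::neighbors(G, v))])
  names(nbrs) <- igraph::V(G)$name
  for (i in seq_len(igraph::ecount(G))) {
    u <- ends[i, 1]; v <- ends[i, 2]
    nu <- setdiff(nbrs[[u]], c(u, v))
    nv <- setdiff(nbrs[[v]], c(u, v))
    uni <- union(nu, nv)
    want <- if (length(uni) == 0L) 1 else length(intersect(nu, nv)) / length(uni)
    expect_equal(igraph::E(G)$connect[i], want)
  }
  expect_true(all(igraph::E(G)$connect >= 0 & igraph::E(G)$connect <= 1))
  # an isolated edge has connect 1 (endpoints trivially share all neighbors):
  # self-alignment components are single CDS edges
  iso <- weight_edges(build_graph(pspa_set(list(
    align_pair(models$g, "c1", models$g))), models))
  expect_true(all(igraph::E(iso)$connect == 1))
})

test_that("find_conflicts enumerates non-overlapping same-sequence pairs", {
  models <- example_gene_models()
  G <- weight_edges(build_graph(example_pspa_set(), models))
  expect_equal(nrow(find_conflicts(G)), 0L)  # conflict-free fixture

  verts <- data.frame(
    name = c("x:1-2", "x:4-5", "x:7-8", "y:1-3", "z:1-3"),
    seq_id = c("x", "x", "x", "y", "z"),
    start = c(1L, 4L, 7L, 1L, 1L), end = c(2L, 5L, 8L, 3L, 3L),
    kind = c("cds", "cds", "cds", "gene", "gene"))
  edges <- data.frame(from = c("x:1-2", "x:4-5", "x:7-8", "y:1-3"),
                      to = c("y:1-3", "y:1-3", "z:1-3", "z:1-3"),
                      kind = "block", pid = 1)
  G3 <- segment_graph(verts, edges)
  conf <- find_conflicts(G3)
  expect_equal(nrow(conf), 3L)  # three mutually non-overlapping x segments
  expect_true(all(conf$seq_id == "x"))
})

test_that("split_components removes a minimum-capacity cut of block edges", {
  # conflict-free graph is untouched
  models <- example_gene_models()
  G <- weight_edges(build_graph(example_pspa_set(), models))
  Gs <- split_components(G)
  expect_equal(igraph::ecount(Gs), igraph::ecount(G))

  # 4-vertex path with the conflict at the ends: the cheapest edge goes
  path_v <- data.frame(name = c("x:1-2", "a:1-3", "b:1-3", "x:9-10"),
                       seq_id = c("x", "a", "b", "x"),
                       start = c(1L, 1L, 1L, 9L), end = c(2L, 3L, 3L, 10L),
                       kind = c("cds", "gene", "gene", "cds"))
  path_e <- data.frame(from = c("x:1-2", "a:1-3", "b:1-3"),
                       to = c("a:1-3", "b:1-3", "x:9-10"),
                       kind = "block", pid = c(0.9, 0.4, 0.8))
  P <- weight_edges(segment_graph(path_v, path_e),
                    connect_fun = function(u, v) 1)
  Ps <- split_components(P)
  removed <- igraph::graph_attr(Ps, "removed_edges")
  expect_equal(nrow(removed), 1L)
  expect_equal(removed$pid, 0.4)
  expect_equal(nrow(find_conflicts(Ps)), 0L)

  # CDS edges are never cut even when they are the narrow bridge
  bridge_v <- data.frame(name = c("x:1-2", "c:1-3", "g:1-3", "x:9-10"),
                         seq_id = c("x", "c", "g", "x"),
                         start = c(1L, 1L, 1L, 9L), end = c(2L, 3L, 3L, 10L),
                         kind = c("cds", "cds", "gene", "cds"))
  bridge_e <- data.frame(from = c("x:1-2", "c:1-3", "g:1-3"),
                         to = c("c:1-3", "g:1-3", "x:9-10"),
                         kind = c("block", "cds", "block"),
                         pid = c(0.95, 1, 0.95))
  B <- weight_edges(segment_graph(bridge_v, bridge_e),
                    connect_fun = function(u, v) 1)
  Bs <- split_components(B)
  expect_true(all(igraph::graph_attr(Bs, "removed_edges")$kind == "block"))
  expect_equal(nrow(find_conflicts(Bs)), 0L)
})

test_that("removed capacity matches brute-force minimum cuts on small graphs", {
  # two parallel paths between the conflicting pair
  verts <- data.frame(
    name = c("x:1-2", "x:9-10", "a:1-3", "b:1-3", "d:1-3"),
    seq_id = c("x", "x", "a", "b", "d"),
    start = c(1L, 9L, 1L, 1L, 1L), end = c(2L, 10L, 3L, 3L, 3L),
    kind = c("cds", "cds", "gene", "gene", "gene"))
  edges <- data.frame(
    from = c("x:1-2", "a:1-3", "x:1-2", "b:1-3", "d:1-3"),
    to = c("a:1-3", "x:9-10", "b:1-3", "d:1-3", "x:9-10"),
    kind = "block", pid = c(0.7, 0.6, 0.9, 0.3, 0.9))
  G <- weight_edges(segment_graph(verts, edges),
                    connect_fun = function(u, v) 1)
  caps <- igraph::E(G)$pid
  # brute force: cheapest edge subset disconnecting the pair
  n <- length(caps)
  best <- Inf
  for (mask in 1:(2^n - 1)) {
    keep <- bitwAnd(mask, 2^(seq_len(n) - 1)) == 0
    H <- igraph::subgraph_from_edges(G, which(keep), delete.vertices = FALSE)
    d <- igraph::distances(H, v = "x:1-2", to = "x:9-10")
    if (is.infinite(d[1, 1])) best <- min(best, sum(caps[!keep]))
  }
  Gs <- split_components(G)
  removed <- igraph::graph_attr(Gs, "removed_edges")
  expect_equal(sum(removed$pid * removed$connect), best)  # 0.6 + 0.3
  # after splitting, components hold at most one segment per sequence
  expect_equal(nrow(find_conflicts(Gs)), 0L)
})

test_that("graph dumps are written with kinds, weights and components", {
  models <- example_gene_models()
  G <- weight_edges(build_graph(example_pspa_set(), models))
  path <- file.path(withr::local_tempdir(), "graph.tsv")
  graph_dump(G, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), igraph::ecount(G))
  expect_true(all(c("kind", "pid", "connect", "component") %in% names(tab)))
})
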