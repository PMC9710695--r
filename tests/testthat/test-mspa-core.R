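test_that("blocks_consistent classifies pairwise multiblock relations", {
  a <- multiblock(g = c(4, 12))
  b <- multiblock(g = c(25, 36))
  expect_equal(blocks_consistent(a, b), "before")
  expect_equal(blocks_consistent(b, a), "after")
  expect_equal(blocks_consistent(a, a), "overlaps")
  mixed_a <- multiblock(g = c(4, 12), h = c(30, 40))
  mixed_b <- multiblock(g = c(25, 36), h = c(5, 10))
  expect_equal(blocks_consistent(mixed_a, mixed_b), "inconsistent")
  disjoint <- multiblock(x = c(1, 5))
  expect_equal(blocks_consistent(a, disjoint), "before")
})

test_that("consistent_with_mspa requires a chain position", {
  A <- example_mspa()
  empty <- mspa(character(0), "g", list())
  expect_true(consistent_with_mspa(multiblock(g = c(1, 10)), empty))
  # the first multiblock of the worked example is consistent with the rest
  rest <- mspa(A$cds_ids, A$gene_ids, A$multiblocks[-1])
  expect_true(consistent_with_mspa(A$multiblocks[[1]], rest))
  # a multiblock spanning two existing segments of g cannot be placed
  spanning <- multiblock(g = c(10, 30))
  expect_false(consistent_with_mspa(spanning, A))
  # a multiblock with disjoint keys is freely placeable
  chain <- mspa(character(0), "g",
                list(multiblock(g = c(1, 5)), multiblock(g = c(10, 15))))
  expect_true(consistent_with_mspa(multiblock(z = c(1, 2)), chain))
  # before/after pattern must be monotone along the chain
  out_of_order <- mspa(character(0), c("g", "h"),
                       list(multiblock(g = c(10, 15), h = c(1, 5)),
                            multiblock(g = c(1, 5), h = c(10, 15))))
  expect_false(consistent_with_mspa(multiblock(g = c(7, 8), h = c(7, 8)),
                                    out_of_order))
})

test_that("induce_pspa reduces the chain to one CDS-gene pair", {
  A <- example_mspa()
  w <- induce_pspa(A, "c3", "g")
  expect_equal(nrow(w$blocks), 3L)
  expect_true(all(!is.na(w$blocks$gene_start)))
  expect_equal(w$blocks$gene_start, c(9L, 25L, 51L))
  # c2 occupies all five multiblocks; against h the first two lack h segments
  z <- induce_pspa(A, "c2", "h")
  expect_equal(nrow(z$blocks), 5L)
  expect_equal(sum(is.na(z$blocks$gene_start)), 1L)
  single <- mspa("c", "g", list(multiblock(c = c(1, 6), g = c(2, 7))))
  one <- induce_pspa(single, "c", "g")
  expect_equal(nrow(one$blocks), 1L)
  expect_error(induce_pspa(A, "nope", "g"), "unknown CDS")
  # induced chains inherit strict monotonicity and coverage from conds 2-3
  models <- example_gene_models()
  gid_of <- c(c1 = "g", c2 = "g", c3 = "h", c4 = "h")
  for (cid in A$cds_ids) for (gid in A$gene_ids) {
    p <- induce_pspa(A, cid, gid)
    expect_true(all(diff(p$blocks$cds_start) > 0))
    expect_equal(p$blocks$cds_start[1], 1L)
    expect_equal(p$blocks$cds_end[nrow(p$blocks)],
                 nchar(cds_sequence(models[[gid_of[[cid]]]], cid)$sequence))
  }
})

test_that("validate_mspa accepts the worked example and reports violations", {
  models <- example_gene_models()
  A <- example_mspa()
  expect_equal(nrow(validate_mspa(A, models)), 0L)

  # overlapping segments of one CDS across two multiblocks: cond 2
  bad2 <- mspa(A$cds_ids, A$gene_ids, A$multiblocks)
  bad2$multiblocks[[3]]$c2 <- c(8L, 15L)
  v <- validate_mspa(bad2, models)
  expect_true(any(v$cond == 2 & v$seq_id == "c2"))

  # dropping a multiblock that carries c1: cond 3
  bad3 <- mspa(A$cds_ids, A$gene_ids, A$multiblocks[-2])
  v3 <- validate_mspa(bad3, models)
  expect_true(any(v3$cond == 3 & v3$seq_id == "c1"))

  # removing the source gene from a multiblock holding its CDS: cond 4
  bad4 <- mspa(A$cds_ids, A$gene_ids, A$multiblocks)
  bad4$multiblocks[[4]] <- multiblock(c2 = c(16, 21), h = c(43, 48))
  v4 <- validate_mspa(bad4, models)
  expect_true(any(v4$cond == 4 & v4$seq_id == "c2"))
})

test_that("validate_mspa agrees with a brute-force condition checker", {
  models <- example_gene_models()
  base <- example_mspa()
  set.seed(23)
  n_checked <- 0L
  for (rep in 1:60) {
    A <- base
    op <- sample(5, 1)
    if (op == 1L && length(A$multiblocks) > 1L) {
      ij <- sample(length(A$multiblocks), 2)
      tmp <- A$multiblocks[[ij[1]]]
      A$multiblocks[[ij[1]]] <- A$multiblocks[[ij[2]]]
      A$multiblocks[[ij[2]]] <- tmp
    } else if (op == 2L) {
      i <- sample(length(A$multiblocks), 1)
      k <- sample(length(A$multiblocks[[i]]), 1)
      A$multiblocks[[i]][[k]] <- pmax(A$multiblocks[[i]][[k]] +
                                        sample(c(-3L, -1L, 1L, 3L), 1), 1L)
    } else if (op == 3L) {
      A$multiblocks <- A$multiblocks[-sample(length(A$multiblocks), 1)]
    } else if (op == 4L) {
      i <- sample(length(A$multiblocks), 1)
      mb <- A$multiblocks[[i]]
      if (length(mb) > 1L) {
        drop <- sample(names(mb), 1)
        A$multiblocks[[i]] <- structure(mb[names(mb) != drop],
                                        class = "multiblock")
      }
    }  # op 5: unchanged (valid case)
    got <- nrow(validate_mspa(A, models)) == 0L
    want <- oracle_mspa_valid(A, models)
    expect_equal(got, want)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 60L)
})
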