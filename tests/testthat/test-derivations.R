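test_that("the derived CDS alignment preserves sequences and homology", {
  models <- example_gene_models()
  A <- example_mspa()
  msa <- mspa_to_cds_msa(A, models)
  expect_setequal(names(msa), c("c1", "c2", "c3", "c4"))
  # every row ungaps to its CDS sequence
  gid_of <- c(c1 = "g", c2 = "g", c3 = "h", c4 = "h")
  for (cid in names(msa))
    expect_equal(ungap(msa[[cid]]),
                 cds_sequence(models[[gid_of[[cid]]]], cid)$sequence)
  # column budget: per-multiblock alignment widths in chain order
  # (5 + 4 + 18 + 6 + 9; the third multiblock spans h's 6-nt intron)
  expect_equal(nchar(msa[[1]]), 42L)
  # c3 and c4 are placed through the same gene row: where both are non-gap
  # the columns agree with their true pairing (suffix alignment)
  m3 <- strsplit(msa[["c3"]], "")[[1]]
  m4 <- strsplit(msa[["c4"]], "")[[1]]
  both <- which(m3 != "-" & m4 != "-")
  expect_equal(paste(m3[both], collapse = ""), "AAGCAGGTCTGGGGTGA")
  expect_equal(paste(m4[both], collapse = ""), "AAGCAGGTCTGGGGTGA")

  single <- mspa("c", "g", list(multiblock(c = c(1, 6), g = c(2, 7))))
  sm <- gene_model("g", "TACGTTTT", list(c = rbind(c(2, 7))))
  one <- mspa_to_cds_msa(single, list(g = sm))
  expect_equal(unname(one[["c"]]), "ACGTTT")  # one CDS: no gaps
})

test_that("identical CDSs from identical genes align gap-free", {
  seqq <- paste0("TT", "ATGGCAGACTTT", "TTTT")
  ma <- gene_model("ga", seqq, list(ta = rbind(c(3, 14))))
  mb <- gene_model("gb", seqq, list(tb = rbind(c(3, 14))))
  models <- list(ga = ma, gb = mb)
  A <- build_mspa(compute_pspa_set(models), models)
  msa <- mspa_to_cds_msa(A, models)
  expect_equal(unname(msa[["ta"]]), "ATGGCAGACTTT")
  expect_equal(unname(msa[["tb"]]), "ATGGCAGACTTT")
  truth <- multiple_alignment(c(ta = "ATGGCAGACTTT", tb = "ATGGCAGACTTT"))
  expect_equal(unname(msa_scores(msa, truth)),
               c(1, 1, 1))
})

test_that("orthology groups pair c1 with c3 on the worked example", {
  models <- example_gene_models()
  groups <- orthology_groups(example_mspa(), models)
  expect_true(any(vapply(groups, identical, TRUE, y = c("c1", "c3"))))
  expect_equal(sort(unlist(groups)), c("c1", "c2", "c3", "c4"))
  expect_equal(length(groups), 3L)
  # idempotent partition
  expect_equal(orthology_groups(example_mspa(), models), groups)
})

test_that("orthology closure joins same-gene isoforms transitively", {
  # c1 and c3 live on gene ga, c2 on gb; all three share membership and
  # frame-compatible lengths, so the equivalence closure puts the two
  # same-gene isoforms (never directly related) into one group via c2
  ga <- gene_model("ga", strrep("ACG", 20),
                   list(c1 = rbind(c(1, 6)), c3 = rbind(c(13, 18))))
  gb <- gene_model("gb", strrep("ACG", 20), list(c2 = rbind(c(1, 6))))
  models <- list(ga = ga, gb = gb)
  A <- mspa(c("c1", "c2", "c3"), c("ga", "gb"), list(
    multiblock(c1 = c(1, 6), c2 = c(1, 6), ga = c(1, 6), gb = c(1, 6)),
    multiblock(c3 = c(1, 6), ga = c(13, 18))))
  # c1 and c2 share multiblock 1; c3 does not -> c3 alone
  expect_equal(orthology_groups(A, models),
               list(c("c1", "c2"), "c3"))
  # transitive closure: c1~c2 and c2~c3 are base-related (distinct genes),
  # c1,c3 share a gene so are never base-related, yet all three group
  A3 <- mspa(c("c1", "c2", "c3"), c("ga", "gb"), list(
    multiblock(c1 = c(1, 6), c2 = c(1, 6), c3 = c(1, 6),
               ga = c(1, 18), gb = c(1, 6))))
  models3 <- list(
    ga = gene_model("ga", strrep("ACG", 20),
                    list(c1 = rbind(c(1, 6)), c3 = rbind(c(13, 18)))),
    gb = gene_model("gb", strrep("ACG", 20), list(c2 = rbind(c(1, 6)))))
  expect_equal(orthology_groups(A3, models3), list(c("c1", "c2", "c3")))
  # singleton CDS set stays a singleton group
  B <- mspa("only", "ga", list(multiblock(only = c(1, 6), ga = c(1, 6))))
  expect_equal(orthology_groups(B, list(ga = gene_model(
    "ga", strrep("ACG", 4), list(only = rbind(c(1, 6)))))), list("only"))
})

test_that("predict_cds projects a source CDS onto the target gene", {
  models <- example_gene_models()
  A <- example_mspa()
  pred <- predict_cds(A, "c4", "g", models)
  expect_equal(pred$status, "predicted")
  expect_equal(pred$sequence, "AAGCAGGTCTGGGGTGATTGA")
  expect_equal(nrow(pred$exons), 2L)
  expect_equal(pred$exons, data.frame(start = c(25L, 51L), end = c(36L, 59L)))
  # the prediction is an ortholog of its source once added to the family
  models2 <- models
  models2$g <- gene_model("g", models$g$sequence,
                          c(models$g$cds, list(cp = pred$exons)))
  mbs <- A$multiblocks
  mbs[[3]] <- multiblock(c(unclass(mbs[[3]]), list(cp = c(1, 12))))
  mbs[[5]] <- multiblock(c(unclass(mbs[[5]]), list(cp = c(13, 21))))
  A2 <- mspa(c(A$cds_ids, "cp"), A$gene_ids, mbs)
  g2 <- orthology_groups(A2, models2)
  expect_true(any(vapply(g2, function(g) all(c("c4", "cp") %in% g), TRUE)))
})

test_that("predict_cds rejects membership, frame, duplicate and STOP failures", {
  models <- example_gene_models()
  A <- example_mspa()
  # c2 occupies multiblocks where h is absent
  r1 <- predict_cds(A, "c2", "h", models)
  expect_equal(r1$status, "rejected")
  expect_match(r1$reason, "not gene h")
  # c1 vs h: last multiblock pairs a 5-nt segment with a 9-nt one
  r2 <- predict_cds(A, "c1", "h", models)
  expect_equal(r2$status, "rejected")
  expect_match(r2$reason, "modulo 3")
  # projecting c3 onto g reconstructs... also frame-incompatible at the end
  r3 <- predict_cds(A, "c3", "g", models)
  expect_equal(r3$status, "rejected")
  # duplicate: annotate the c4 projection on g first
  models4 <- models
  models4$g <- gene_model("g", models$g$sequence, c(models$g$cds, list(
    c9 = rbind(c(25, 36), c(51, 59)))))
  r4 <- predict_cds(A, "c4", "g", models4)
  expect_equal(r4$status, "rejected")
  expect_match(r4$reason, "already annotated")
  # internal in-frame STOP: build a two-block family whose target gene
  # carries TGA inside the first projected segment
  src <- gene_model("s", "ATGAAACCCGGG", list(cx = rbind(c(1, 12))))
  tgt <- gene_model("t", "ATGTGACCCGGGTTT", list(cy = rbind(c(13, 15))))
  mm <- list(s = src, t = tgt)
  Astop <- mspa("cx", c("s", "t"), list(
    multiblock(cx = c(1, 6), s = c(1, 6), t = c(1, 6)),
    multiblock(cx = c(7, 12), s = c(7, 12), t = c(7, 12))))
  r5 <- predict_cds(Astop, "cx", "t", mm)
  expect_equal(r5$status, "rejected")
  expect_match(r5$reason, "STOP")
  # a terminal STOP is allowed (the worked-example prediction ends in TGA)
  expect_equal(predict_cds(A, "c4", "g", models)$status, "predicted")
})

test_that("alignment and group writers round-trip", {
  models <- example_gene_models()
  A <- example_mspa()
  msa <- mspa_to_cds_msa(A, models)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "msa.fasta")
  write_msa_fasta(msa, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back[["c1"]]), unname(msa[["c1"]]))
  cl <- file.path(dir, "msa.aln")
  write_msa_clustal(msa, cl)
  expect_match(readLines(cl)[1], "^CLUSTAL")
  groups <- orthology_groups(A, models)
  tsv <- file.path(dir, "groups.tsv")
  write_orthology_groups(groups, tsv)
  expect_equal(read_orthology_groups(tsv), groups)
})
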