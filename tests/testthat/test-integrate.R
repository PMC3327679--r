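test_that("loop classification covers all sign patterns and partitions them 2/2/2/2", {
  grid <- expand.grid(s_mirna = c(-1, 1), s_mrna = c(-1, 1), s_protein = c(-1, 1))
  cls <- classify_loop(grid$s_mirna, grid$s_mrna, grid$s_protein)
  expect_equal(unname(table(cls$loop_type)[c("A", "B", "C", "unclassified")]),
               rep(2L, 4), ignore_attr = TRUE)
  expect_true(all(cls$coherence[cls$loop_type == "A"] == "coherent"))
  expect_true(all(cls$coherence[cls$loop_type %in% c("B", "C")] == "incoherent"))
  expect_true(all(cls$coherence[cls$loop_type == "unclassified"] == "none"))

  ## negating every sign preserves the type
  neg <- classify_loop(-grid$s_mirna, -grid$s_mrna, -grid$s_protein)
  expect_equal(neg$loop_type, cls$loop_type)
})

test_that("loop classification matches the published scenarios", {
  ## the miR-21/PDCD4 configuration: miRNA up, target down at both levels
  expect_equal(classify_loop(1, -1, -1)$loop_type, "A")
  expect_equal(classify_loop(1, -1, -1)$coherence, "coherent")
  ## translational repression: mRNA coexpressed, protein opposite
  expect_equal(classify_loop(-1, -1, 1)$loop_type, "B")
  ## full coexpression: no supported miRNA action
  expect_equal(classify_loop(1, 1, 1)$loop_type, "C")
  ## the pattern the taxonomy does not define
  expect_equal(classify_loop(1, -1, 1)$loop_type, "unclassified")
  expect_error(classify_loop(0, 1, 1), "signs")
})

test_that("pair links label predicted pairs by sign relation and honour the score cutoff", {
  mir <- toy_de(c("miR-1", "miR-2"), c(1.2, -0.5))
  tgt <- toy_de(c("G1", "G2", "G3"), c(-1.5, 2, 0), c("down", "up", "ns"))
  tm <- target_map(data.frame(
    mirna_id = c("miR-1", "miR-1", "miR-2", "miR-1"),
    gene_id = c("G1", "G2", "G1", "G3"),
    score = c(-0.5, -0.3, -0.05, -0.9)))
  links <- pair_links(mir, tgt, tm)
  ## miR-2/G1 fails the score cutoff; miR-1/G3 target is ns
  expect_equal(nrow(links), 2L)
  expect_equal(links$relation[links$gene_id == "G1"], "anti")
  expect_equal(links$relation[links$gene_id == "G2"], "co")

  empty <- pair_links(mir, tgt, target_map(tm[0, ]))
  expect_equal(nrow(empty), 0L)
})

test_that("correlation-mode pairing uses matched replicate profiles", {
  set.seed(41)
  n_bio <- 6
  prof <- rnorm(n_bio, 0, 1)
  mir_vals <- matrix(1 + prof + rnorm(n_bio, 0, 0.05), 1, n_bio,
                     dimnames = list("miR-1", NULL))
  mir_mat <- toy_ratio(mir_vals, bio_rep = 1:n_bio, tech_rep = 1,
                       dye = rep("Cy5", n_bio), layer = "miRNA")
  tgt_vals <- rbind(G1 = -1 - prof + rnorm(n_bio, 0, 0.05),
                    G2 = -1 + rev(prof) * 0 + rnorm(n_bio, 1, 1))
  tgt_mat <- toy_ratio(tgt_vals, bio_rep = 1:n_bio, tech_rep = 1,
                       dye = rep("Cy5", n_bio))
  mir <- toy_de("miR-1", 1)
  tgt <- toy_de(c("G1", "G2"), c(-1, -1))
  tm <- target_map(data.frame(mirna_id = "miR-1", gene_id = c("G1", "G2"),
                              score = -0.5))
  links <- pair_links(mir, tgt, tm, mode = "correlation",
                      mirna_mat = mir_mat, target_mat = tgt_mat)
  expect_equal(links$relation[links$gene_id == "G1"], "anti")
  expect_equal(links$relation[links$gene_id == "G2"], "co")

  short <- toy_ratio(mir_vals[, 1:3, drop = FALSE], bio_rep = 1:3, tech_rep = 1,
                     dye = rep("Cy5", 3), layer = "miRNA")
  expect_error(pair_links(mir, tgt, tm, mode = "correlation",
                          mirna_mat = short, target_mat = tgt_mat), "4 matched")
})

test_that("the mRNA-protein core intersects DE lists and flags concordance", {
  genes <- toy_de(c("G1", "G2", "G3"), c(2, 1.5, -2))
  prots <- toy_de(c("G1", "G2", "G4"), c(1, -0.8, 2))
  core <- mrna_protein_core(genes, prots)
  expect_equal(core$gene_id, c("G1", "G2"))
  expect_equal(core$concordant, c(TRUE, FALSE))

  none <- mrna_protein_core(genes, toy_de("G9", 1))
  expect_equal(nrow(none), 0L)
})

test_that("loop enumeration requires all three layers and composes the classifier", {
  mir <- toy_de("miR-1", 1.2)
  genes <- toy_de(c("G1", "G2"), c(-1.5, -1.2))
  prots <- toy_de("G1", -0.7)
  tm <- target_map(data.frame(mirna_id = "miR-1", gene_id = c("G1", "G2"),
                              score = -0.4))
  loops <- enumerate_loops(mir, genes, prots, tm)
  expect_equal(nrow(loops), 1L)   # G2 has no DE protein
  expect_equal(loops$loop_type, "A")
  expect_equal(loops$gene_id, "G1")
  expect_equal(unname(loop_counts(loops)), c(1L, 0L, 0L, 0L))
})

test_that("loop enumeration is order invariant and free of duplicate triplets", {
  set.seed(42)
  mir <- toy_de(sprintf("miR-%d", 1:6), runif(6, -2, 2) + c(1, -1))
  genes <- toy_de(sprintf("G%d", 1:10), runif(10, -2, 2) + 0.3)
  prots <- toy_de(sprintf("G%d", 1:10), runif(10, -2, 2))
  tm <- target_map(data.frame(
    mirna_id = sample(mir$feature_id, 25, replace = TRUE),
    gene_id = sample(genes$feature_id, 25, replace = TRUE),
    score = runif(25, -1, -0.2)))
  l1 <- enumerate_loops(mir, genes, prots, tm)
  perm <- sample(nrow(tm))
  l2 <- enumerate_loops(mir[sample(6), ], genes[sample(10), ],
                        prots[sample(10), ], target_map(tm[perm, ]))
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  expect_false(any(duplicated(l1[c("mirna_id", "gene_id")])))
})

test_that("miRNA clustering splits at the 1000 kb boundary and finds the chr13 pattern", {
  coords <- data.frame(
    mirna_id = c("miR-17*", "miR-19a", "miR-19b", "miR-20a", "miR-92a"),
    chromosome = "chr13",
    position = 50e3 + (0:4) * 5e3)
  cl <- cluster_mirnas(coords)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 5L)
  expect_equal(cl$members, "miR-17*,miR-19a,miR-19b,miR-20a,miR-92a")

  two <- cluster_mirnas(data.frame(mirna_id = c("a", "b"), chromosome = "chr1",
                                   position = c(0, 2000e3)))
  expect_equal(two$n_members, c(1L, 1L))

  ## exactly 1000 kb apart: strict rule splits
  edge <- cluster_mirnas(data.frame(mirna_id = c("a", "b"), chromosome = "chr1",
                                    position = c(0, 1000e3)))
  expect_equal(nrow(edge), 2L)
  just_in <- cluster_mirnas(data.frame(mirna_id = c("a", "b"), chromosome = "chr1",
                                       position = c(0, 1000e3 - 1)))
  expect_equal(nrow(just_in), 1L)

  expect_error(cluster_mirnas(data.frame(mirna_id = c("a", "a"),
                                         chromosome = "chr1",
                                         position = c(0, 10))), "duplicate")
})
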