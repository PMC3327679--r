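test_that("generation is deterministic given the seed", {
  b1 <- generate_omics(small_sim(seed = 9))
  b2 <- generate_omics(small_sim(seed = 9))
  expect_identical(b1$mrna, b2$mrna)
  expect_identical(b1$mirna$values, b2$mirna$values)
  expect_identical(b1$target_map, b2$target_map)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_omics(small_sim(seed = 10))
  expect_false(identical(b1$mirna$values, b3$mirna$values))
})

test_that("fixture directories are written once and re-read faithfully", {
  b <- generate_omics(small_sim(seed = 12))
  d <- withr::local_tempdir()
  write_fixture(b, d, overwrite = TRUE)
  expect_error(write_fixture(b, d), "not empty")
  files <- dir(d)
  expect_true(all(c("mrna.tsv", "mrna_arrays.tsv", "mirna_raw.tsv",
                    "protein.tsv", "target_map.tsv", "truth_loops.tsv",
                    "config.yaml") %in% files))
  back <- read_fixture(d)
  expect_identical(back$protein$arrays, b$protein$arrays)
  expect_equal(unclass(back$config), unclass(b$config))
})

test_that("noise-free generation reproduces planted log fold changes exactly", {
  cfg <- small_sim(seed = 13, noise_sd = 0, background_sd = 0, n_tech = 1,
                   dye_swap = FALSE, low_signal_fraction = 0)
  b <- generate_omics(cfg)
  ratios <- process_two_color(b$mrna, background = "subtract",
                              normalization = "none")
  fit <- fit_two_group(collapse_replicates(ratios))
  truth <- b$truth$true_logfc$mRNA[fit$feature_id]
  expect_equal(fit$logFC, unname(truth), tolerance = 1e-12)
})

test_that("planted loop counts, signs and low-signal features obey the configuration", {
  cfg <- small_sim(seed = 14, loops_per_type = c(A = 38, B = 34, C = 28),
                   n_de_genes = 120, n_de_proteins = 110, n_proteins = 150)
  b <- generate_omics(cfg)
  loops <- b$truth$planted_loops
  expect_equal(nrow(loops), 100L)
  expect_equal(unname(loop_counts(loops)), c(38L, 34L, 28L, 0L))

  ## truth rows consistent with the classifier
  cls <- classify_loop(loops$s_mirna, loops$s_mrna, loops$s_protein)
  expect_equal(cls$loop_type, loops$loop_type)
  expect_equal(cls$coherence, loops$coherence)

  ## signs consistent with planted status
  st <- b$truth$de_status
  expect_equal(unname(st$miRNA[loops$mirna_id]),
               ifelse(loops$s_mirna > 0, "up", "down"))
  expect_equal(unname(st$mRNA[loops$gene_id]),
               ifelse(loops$s_mrna > 0, "up", "down"))

  ## planted low-signal probes sit below background in every array
  sig <- two_color_signal_matrices(b$mrna)
  low <- b$truth$planted_low_signal
  expect_gt(length(low), 0)
  expect_true(all(sig$fg[low, ] < sig$bg[low, ]))
  rep <- filter_low_signal(sig$fg, sig$bg)
  expect_true(all(low %in% rep$removed))
})

test_that("decoy target pairs never coincide with planted loops", {
  for (seed in 15:17) {
    b <- generate_omics(small_sim(seed = seed))
    loops <- b$truth$planted_loops
    tm <- b$target_map
    key <- paste(tm$mirna_id, tm$gene_id)
    planted_key <- paste(loops$mirna_id, loops$gene_id)
    expect_true(all(planted_key %in% key))
    decoy <- tm[!key %in% planted_key, ]
    both_de <- intersect(names(which(b$truth$de_status$mRNA != "ns")),
                         names(which(b$truth$de_status$protein != "ns")))
    de_mir <- names(which(b$truth$de_status$miRNA != "ns"))
    expect_false(any(decoy$mirna_id %in% de_mir & decoy$gene_id %in% both_de))
  }
})

test_that("null features have no systematic fold change across seeds", {
  lfc <- NULL
  for (seed in 1:25) {
    cfg <- small_sim(seed = seed, n_genes = 120, n_proteins = 30,
                     n_de_genes = 12, n_de_mirnas = 4, n_de_proteins = 8,
                     loops_per_type = c(A = 1, B = 1, C = 1, unclassified = 0),
                     n_decoy_targets = 10, low_signal_fraction = 0)
    b <- generate_omics(cfg)
    ratios <- process_two_color(b$mrna, background = "subtract",
                                normalization = "none")
    fit <- fit_two_group(collapse_replicates(ratios))
    null <- b$truth$de_status$mRNA[fit$feature_id] == "ns"
    lfc <- c(lfc, fit$logFC[null])
  }
  se <- sd(lfc) / sqrt(length(lfc))
  expect_lt(abs(mean(lfc)), 3 * se + 1e-3)
})

test_that("planted anti-correlated pairs are anti-correlated across replicate profiles", {
  cfg <- small_sim(seed = 18, n_bio = 12, n_tech = 8,
                   loops_per_type = c(A = 12, B = 0, C = 0, unclassified = 0),
                   n_de_genes = 30, n_de_mirnas = 10, n_de_proteins = 20)
  b <- generate_omics(cfg)
  mir_prof <- loopomics:::.bio_profile(collapse_replicates(vsn_like_normalize(b$mirna)))
  mrna_prof <- loopomics:::.bio_profile(
    collapse_replicates(process_two_color(b$mrna, background = "subtract",
                                          normalization = "lowess")))
  loops <- b$truth$planted_loops
  r <- vapply(seq_len(nrow(loops)), function(i)
    cor(mir_prof[loops$mirna_id[i], ], mrna_prof[loops$gene_id[i], ]), 0)
  expect_gte(mean(r < 0), 0.95)
})

test_that("infeasible configurations fail before generating output", {
  expect_error(sim_config(n_proteins = 200, n_genes = 100), "n_proteins")
  expect_error(sim_config(loops_per_type = c(A = 500), n_de_genes = 100,
                          n_de_proteins = 400), "infeasible")
  expect_error(sim_config(n_de_mirnas = 0, loops_per_type = c(A = 1)),
               "infeasible")
})
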