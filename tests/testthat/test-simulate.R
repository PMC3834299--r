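test_that("the generator is fully determined by its seed", {
  cfg <- small_config(seed = 5)
  t1 <- simulate_pangenome(cfg)
  t2 <- simulate_pangenome(cfg)
  expect_identical(t1$truth, t2$truth)
  expect_identical(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  a1 <- simulate_arrays(t1)
  a2 <- simulate_arrays(t2)
  expect_identical(a1$intensities, a2$intensities)
  expect_identical(a1$selfself, a2$selfself)
  # and the emitted TSV bytes are identical too
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_table(a1$intensities, f1)
  write_intensity_table(a2$intensities, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate configurations produce the expected trivial truth", {
  # everything core: no variable genes, no trait genes to plant
  cfg <- simulation_config(n_strains = 5, n_genes = 100, core_fraction = 1,
                           n_reference_specific = 0, n_trait_genes = 10,
                           seed = 3)
  truth <- simulate_pangenome(cfg)
  expect_true(all(truth$truth == "present"))
  expect_length(truth$trait_gene_ids, 0)

  # no loss events and nothing forced: all genes present everywhere
  cfg2 <- simulation_config(n_strains = 5, n_genes = 100, core_fraction = 0.5,
                            loss_rate_per_branch = 0, n_reference_specific = 0,
                            n_trait_genes = 0, outgroup_absent_fraction = 0,
                            seed = 3)
  expect_true(all(simulate_pangenome(cfg2)$truth == "present"))
})

test_that("core fraction is honoured and matches a brute-force recount", {
  cfg <- simulation_config(n_strains = 16, n_genes = 2000, core_fraction = 0.6,
                           seed = 7)
  truth <- simulate_pangenome(cfg)
  present_everywhere <- apply(truth$truth == "present", 1, all)
  expect_gte(mean(present_everywhere), 0.6)
  # column-wise AND recount equals the same quantity computed element-wise
  recount <- rowSums(truth$truth == "present") == ncol(truth$truth)
  expect_identical(unname(present_everywhere), unname(recount))
  # declared core genes really are present in every strain
  expect_true(all(truth$truth[truth$core_gene_ids, ] == "present"))
})

test_that("forced patterns hold: reference-specific, trait genes, reference column", {
  truth <- simulate_pangenome(small_config(seed = 11))
  expect_true(all(truth$truth[, truth$reference] == "present"))
  rs <- truth$truth[truth$reference_specific_ids, ]
  expect_true(all(rs[, truth$reference] == "present"))
  expect_true(all(rs[, setdiff(colnames(rs), truth$reference)] == "absent"))
  a <- names(truth$trait_groups)[truth$trait_groups == "A"]
  b <- names(truth$trait_groups)[truth$trait_groups == "B"]
  expect_true(all(truth$truth[truth$trait_gene_ids, a] == "present"))
  expect_true(all(truth$truth[truth$trait_gene_ids, b] == "absent"))
})

test_that("class-conditional intensities converge to configured moments", {
  cfg <- simulation_config(n_strains = 10, n_genes = 2000, core_fraction = 0.3,
                           loss_rate_per_branch = 0.1, n_reference_specific = 0,
                           n_trait_genes = 0, n_replicates = 3, seed = 9)
  truth <- simulate_pangenome(cfg)
  arr <- simulate_arrays(truth)
  cls <- truth$truth[cbind(arr$intensities$probe_id, arr$intensities$strain)]
  for (k in c("present", "absent")) {
    xs <- arr$intensities$log2_ratio[cls == k]
    mu <- if (k == "present") cfg$present_mean else cfg$absent_mean
    s2 <- (if (k == "present") cfg$present_sd else cfg$absent_sd)^2 +
      cfg$replicate_sd^2
    se <- sqrt(s2 / length(xs))
    expect_lt(abs(mean(xs) - mu), 3 * se)
    expect_lt(abs(sd(xs) - sqrt(s2)), 3 * sqrt(s2 / (2 * length(xs))))
  }
})

test_that("planted low-signal probes match the configured fraction exactly", {
  cfg <- simulation_config(n_strains = 4, n_outgroups = 0, n_genes = 2000,
                           n_reference_specific = 0, n_trait_genes = 3,
                           background_fail_fraction = 0.05, seed = 2)
  arr <- simulate_arrays(simulate_pangenome(cfg))
  expect_length(arr$low_signal_probe_ids, 100)
})

test_that("degenerate noise pins absent-gene ratios at the class mean", {
  cfg <- simulation_config(n_strains = 4, n_outgroups = 0, n_genes = 200,
                           core_fraction = 0.2, loss_rate_per_branch = 0.3,
                           present_sd = 1e-9, absent_sd = 1e-9,
                           diverged_sd = 1e-9, replicate_sd = 1e-9,
                           diverged_fraction = 0, n_reference_specific = 0,
                           n_trait_genes = 0, seed = 4)
  truth <- simulate_pangenome(cfg)
  arr <- simulate_arrays(truth)
  cls <- truth$truth[cbind(arr$intensities$probe_id, arr$intensities$strain)]
  expect_true(any(cls == "absent"))
  expect_true(all(abs(arr$intensities$log2_ratio[cls == "absent"] + 2.5) < 1e-6))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(core_fraction = 1.2), "core_fraction")
  expect_error(simulation_config(n_genes = 100, core_fraction = 0.99,
                                 n_reference_specific = 50), "exceeds")
  expect_error(simulation_config(absent_mean = 0.5), "Class means")
  expect_error(simulation_config(present_sd = 0), "positive")
  cfg <- small_config()
  cfg$trait_group_assignment <- setNames(rep("A", 5), sprintf("EHS%02d", 2:6))
  expect_error(simulate_pangenome(cfg), "empty")
})
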