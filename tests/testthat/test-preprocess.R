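selfself_fixture <- function() {
  # 3 probes x 2 replicates; p2 sits exactly at the flagging threshold
  bg <- rep(100, 6)
  tibble::tibble(
    probe_id = rep(c("p1", "p2", "p3"), each = 2),
    strain = "SELFSELF", replicate = rep(1:2, 3),
    test_signal = c(10000, 10000, 100, 100, 20, 20),
    ref_signal = c(10000, 10000, 10000, 10000, 20, 20),
    background = bg)
}

test_that("background QC keeps only probes strictly above threshold in both channels", {
  ss <- selfself_fixture()
  rep <- filter_selfself_background(ss, k = 3)
  # sd(background) = 0 so threshold = 100; p2 test channel sits exactly there
  expect_equal(attr(rep, "threshold"), 100)
  expect_false(rep$low_signal_selfself[rep$probe_id == "p1"])
  expect_true(rep$low_signal_selfself[rep$probe_id == "p2"])
  expect_true(rep$low_signal_selfself[rep$probe_id == "p3"])
})

test_that("background QC without raw signals warns and keeps everything", {
  ss <- selfself_fixture()[, c("probe_id", "strain", "replicate")]
  ss$log2_ratio <- 0
  expect_warning(rep <- filter_selfself_background(ss), "skipped")
  expect_false(any(rep$low_signal_selfself))
})

test_that("background QC recovers exactly the planted failure set", {
  cfg <- simulation_config(n_strains = 4, n_outgroups = 0, n_genes = 2000,
                           n_reference_specific = 0, n_trait_genes = 3,
                           background_fail_fraction = 0.05, seed = 21)
  arr <- simulate_arrays(simulate_pangenome(cfg))
  rep <- filter_selfself_background(arr$selfself)
  flagged <- rep$probe_id[rep$low_signal_selfself]
  expect_setequal(flagged, arr$low_signal_probe_ids)
  expect_length(flagged, 100)
})

test_that("the per-probe ANOVA matches stats::aov and handles degeneracy", {
  set.seed(31)
  tab <- tidyr::expand_grid(probe_id = sprintf("p%02d", 1:10),
                            strain = c("s1", "s2", "s3"), replicate = 1:3)
  tab$log2_ratio <- rnorm(nrow(tab)) +
    rep(rnorm(10), each = 9) * (tab$strain == "s2")
  res <- anova_probe_filter(tab, alpha = 0.05)
  for (p in unique(tab$probe_id)) {
    sub <- tab[tab$probe_id == p, ]
    ref <- summary(stats::aov(log2_ratio ~ strain, data = sub))[[1]]
    expect_equal(res$f_stat[res$probe_id == p], ref[["F value"]][1],
                 tolerance = 1e-10)
    expect_equal(res$p_value[res$probe_id == p], ref[["Pr(>F)"]][1],
                 tolerance = 1e-10)
  }
  expect_equal(res$p_adj, pmin(1, res$p_value * 10))

  # no variation at all: p = 1, never significant
  flat <- tab; flat$log2_ratio <- 1
  res_flat <- anova_probe_filter(flat)
  expect_true(all(res_flat$p_value == 1))
  expect_false(any(res_flat$significant))

  # complete separation with tiny jitter: significant at any reasonable alpha
  sep <- tidyr::expand_grid(probe_id = "p1", strain = c("s1", "s2"),
                            replicate = 1:3)
  sep$log2_ratio <- ifelse(sep$strain == "s1", 0, -3) +
    c(-1, 0, 1, -1, 0, 1) * 1e-6
  expect_true(anova_probe_filter(sep, alpha = 0.01)$significant)

  # exact separation, zero within-group variance: p = 0
  sep$log2_ratio <- ifelse(sep$strain == "s1", 0, -3)
  expect_equal(anova_probe_filter(sep)$p_value, 0)
})

test_that("with no strain effect the Bonferroni ANOVA retains nothing", {
  set.seed(17)
  tab <- tidyr::expand_grid(probe_id = sprintf("p%04d", 1:1000),
                            strain = c("s1", "s2", "s3"), replicate = 1:3)
  tab$log2_ratio <- rnorm(nrow(tab), 0, 0.3)
  res <- anova_probe_filter(tab, alpha = 0.01)
  expect_equal(sum(res$significant), 0)
  expect_lte(mean(res$significant), 0.01)
})

test_that("replicate averaging is an arithmetic mean with missing-value bookkeeping", {
  tab <- tibble::tibble(
    probe_id = c("p1", "p1", "p1", "p2", "p3", "p3"),
    strain = "s1", replicate = c(1, 2, 3, 1, 1, 2),
    log2_ratio = c(-1, 0, 1, 0.7, NA, NA))
  av <- average_replicates(tab)
  expect_equal(av$log2_ratio[av$probe_id == "p1"], 0)
  expect_equal(av$log2_ratio[av$probe_id == "p2"], 0.7)
  expect_true(is.na(av$log2_ratio[av$probe_id == "p3"]))
  expect_equal(av$n_replicates, c(3L, 1L, 0L))
})

test_that("averaging commutes with probe subsetting", {
  set.seed(41)
  tab <- tidyr::expand_grid(probe_id = sprintf("p%03d", 1:50),
                            strain = c("s1", "s2"), replicate = 1:3)
  tab$log2_ratio <- rnorm(nrow(tab))
  keep <- sample(unique(tab$probe_id), 20)
  a <- average_replicates(tab, keep = keep)
  b <- dplyr::filter(average_replicates(tab), .data$probe_id %in% keep)
  expect_equal(a, b)
})

test_that("QC reporting is idempotent and its counts reconcile", {
  cfg <- small_config(seed = 13, background_fail_fraction = 0.05)
  arr <- simulate_arrays(simulate_pangenome(cfg))
  rep1 <- probe_qc(arr$intensities, arr$selfself, anova_policy = "none")
  counts <- attr(rep1, "counts")
  expect_equal(counts$n_input, 400)
  expect_equal(counts$n_kept + counts$n_low_signal + counts$n_anova_fail -
                 counts$n_both, counts$n_input)
  expect_equal(rep1$kept, !rep1$low_signal_selfself & !rep1$anova_fail)
  # rerunning on the kept set flags nothing new
  kept <- rep1$probe_id[rep1$kept]
  rep2 <- probe_qc(
    dplyr::filter(arr$intensities, .data$probe_id %in% kept),
    dplyr::filter(arr$selfself, .data$probe_id %in% kept),
    anova_policy = "none")
  expect_true(all(rep2$kept))
})

test_that("the ANOVA retention policy is selectable", {
  cfg <- small_config(seed = 19)
  arr <- simulate_arrays(simulate_pangenome(cfg))
  keep_sig <- probe_qc(arr$intensities, arr$selfself,
                       anova_policy = "keep_significant")
  drop_sig <- probe_qc(arr$intensities, arr$selfself,
                       anova_policy = "drop_significant")
  none <- probe_qc(arr$intensities, arr$selfself, anova_policy = "none")
  expect_false(any(none$anova_fail))
  # the two opposite policies partition the background-passing probes
  ok <- !keep_sig$low_signal_selfself
  expect_equal(keep_sig$anova_fail[ok], !drop_sig$anova_fail[ok])
  # strain-differential probes exist, so keep_significant retains some
  expect_gt(sum(keep_sig$kept), 0)
})
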