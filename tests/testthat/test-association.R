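simple_traits <- function(a, b) {
  tibble::tibble(strain = c(a, b), group = rep(c("A", "B"), c(length(a), length(b))))
}

test_that("perfect and near-perfect patterns classify correctly", {
  strains <- paste0("s", 1:8)
  a <- strains[1:4]; b <- strains[5:8]
  P <- matrix(0L, 4, 8, dimnames = list(paste0("g", 1:4), strains))
  P["g1", a] <- 1L                      # perfect
  P["g2", a[1:3]] <- 1L                 # one false negative
  P["g3", c(a, b[1])] <- 1L             # one false positive
  P["g4", c(a[1:3], b[1])] <- 1L        # one of each: rejected by default
  hits <- associate_trait(P, simple_traits(a, b))
  expect_equal(hits$gene_id, c("g1", "g2", "g3"))
  expect_equal(hits$match_class, c("perfect", "one_fn", "one_fp"))
  expect_false("g4" %in% hits$gene_id)
  # one-of-each is admitted only when the cap is lifted
  loose <- associate_trait(P, simple_traits(a, b), cap_sum = FALSE)
  expect_true("g4" %in% loose$gene_id)
})

test_that("hit lists equal brute-force enumeration for every tolerance setting", {
  set.seed(71)
  strains <- paste0("s", 1:12)
  a <- strains[1:6]; b <- strains[7:12]
  P <- matrix(rbinom(500 * 12, 1, 0.5), nrow = 500, ncol = 12,
              dimnames = list(sprintf("g%03d", 1:500), strains))
  traits <- simple_traits(a, b)
  for (rule in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 2))) {
    for (cap in c(TRUE, FALSE)) {
      hits <- associate_trait(P, traits, max_fn = rule[1], max_fp = rule[2],
                              cap_sum = cap)
      expect_setequal(hits$gene_id,
                      brute_force_hits(P, a, b, rule[1], rule[2], cap))
    }
  }
})

test_that("tightening the tolerance never adds hits", {
  set.seed(72)
  strains <- paste0("s", 1:10)
  P <- matrix(rbinom(300 * 10, 1, 0.6), nrow = 300, ncol = 10,
              dimnames = list(sprintf("g%03d", 1:300), strains))
  traits <- simple_traits(strains[1:5], strains[6:10])
  h11 <- associate_trait(P, traits, max_fn = 1, max_fp = 1)
  h10 <- associate_trait(P, traits, max_fn = 1, max_fp = 0)
  h01 <- associate_trait(P, traits, max_fn = 0, max_fp = 1)
  h00 <- associate_trait(P, traits, max_fn = 0, max_fp = 0)
  expect_true(all(h10$gene_id %in% h11$gene_id))
  expect_true(all(h01$gene_id %in% h11$gene_id))
  expect_true(all(h00$gene_id %in% h10$gene_id))
  expect_true(all(h00$gene_id %in% h01$gene_id))
})

test_that("zero tolerance reduces to exact set algebra", {
  set.seed(73)
  strains <- paste0("s", 1:8)
  a <- strains[1:4]; b <- strains[5:8]
  P <- matrix(rbinom(200 * 8, 1, 0.5), nrow = 200, ncol = 8,
              dimnames = list(sprintf("g%03d", 1:200), strains))
  hits <- associate_trait(P, simple_traits(a, b), max_fn = 0, max_fp = 0)
  algebra <- rownames(P)[apply(P[, a] == 1, 1, all) &
                           apply(P[, b] == 0, 1, all)]
  expect_setequal(hits$gene_id, algebra)
})

test_that("the search direction is intentionally asymmetric", {
  strains <- paste0("s", 1:6)
  a <- strains[1:3]; b <- strains[4:6]
  P <- matrix(0L, 2, 6, dimnames = list(c("gA", "gB"), strains))
  P["gA", a] <- 1L   # present in A only
  P["gB", b] <- 1L   # present in B only
  forward <- associate_trait(P, simple_traits(a, b), max_fn = 0, max_fp = 0)
  swapped <- associate_trait(P, simple_traits(b, a), max_fn = 0, max_fp = 0)
  expect_equal(forward$gene_id, "gA")
  expect_equal(swapped$gene_id, "gB")
})

test_that("group bookkeeping errors are caught", {
  P <- matrix(1L, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expect_error(associate_trait(P, simple_traits("s1", "s9")), "missing.*s9")
  expect_error(associate_trait(P, simple_traits("s1", "s2"),
                               exclude = "s2"), "non-empty")
})

test_that("near-noiseless simulation recovers all planted genes and only the truth-matching extras", {
  cfg <- simulation_config(n_strains = 10, n_outgroups = 1, n_genes = 800,
                           core_fraction = 0.5, n_reference_specific = 5,
                           n_trait_genes = 10, present_sd = 0.05,
                           absent_sd = 0.05, diverged_sd = 0.05,
                           replicate_sd = 0.01, background_fail_fraction = 0,
                           seed = 33)
  truth <- simulate_pangenome(cfg)
  rec <- recover_planted_traits(truth)
  expect_equal(rec$sensitivity, 1)
  # every hit is explained by the truth matrix: false hits are exactly the
  # genes whose random loss pattern happens to match the split
  expect_equal(rec$n_false_beyond_truth, 0)
  expect_setequal(rec$hits$gene_id, rec$truth_expected_hits)
})

test_that("shuffled trait labels drop recovery to the truth-side chance level", {
  cfg <- simulation_config(n_strains = 12, n_outgroups = 0, n_genes = 600,
                           core_fraction = 0.5, n_reference_specific = 0,
                           n_trait_genes = 10, seed = 34)
  truth <- simulate_pangenome(cfg)
  set.seed(99)
  shuffled <- truth$trait_groups
  names(shuffled) <- sample(names(shuffled))
  truth_shuffled <- truth
  truth_shuffled$trait_groups <- shuffled
  rec <- recover_planted_traits(truth_shuffled)
  # chance level computed on the truth side with the same shuffled labels
  traits <- tibble::tibble(strain = names(shuffled), group = unname(shuffled))
  chance <- associate_trait(truth_presence_matrix(truth), traits,
                            exclude = c(truth$reference, truth$outgroups))
  planted_by_chance <- mean(truth$trait_gene_ids %in% chance$gene_id)
  expect_lte(rec$sensitivity, planted_by_chance + 0.1)
})
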