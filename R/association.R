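#' Genes whose presence pattern matches a two-group phenotype
#'
#' Set-algebraic search for genes present in the phenotype-positive group (A,
#' e.g. virus-susceptible or calcifying) and absent in the phenotype-negative
#' group (B), relaxed to tolerate one false negative (an A strain with an
#' absent call) or one false positive (a B strain with a present call) — an
#' exclusive-or by default, not one of each. Only the A-present direction is
#' searched: every probe derives from the reference genome, so genes private
#' to group B are unobservable on this array design. The reference strain and
#' outgroups should be excluded via `exclude` (they are in the pipeline).
#'
#' @param presence A `cgh_presence` or 0/1 genes-x-strains matrix.
#' @param traits Tibble with columns `strain` and `group` (`"A"`, `"B"` or
#'   `"excluded"`), e.g. from [load_trait_fixture()].
#' @param max_fn,max_fp Maximum tolerated false negatives / positives.
#'   Default 1 each.
#' @param cap_sum If `TRUE` (default) the relaxations are exclusive:
#'   `fn + fp <= max(max_fn, max_fp)`, so a gene with one of each is rejected.
#' @param exclude Additional strains dropped from scoring.
#' @return Tibble of hits (class `cgh_trait_hits`): `gene_id`, `n_A_present`,
#'   `n_A_total`, `n_B_absent`, `n_B_total`, `fn`, `fp`, `match_class`
#'   (`"perfect"`, `"one_fn"`, `"one_fp"` or `"relaxed"`), sorted by match
#'   class then gene id. Attributes record the rule and group memberships.
#' @export
associate_trait <- function(presence, traits, max_fn = 1L, max_fp = 1L,
                            cap_sum = TRUE, exclude = character()) {
  P <- presence_as_matrix(presence)
  traits <- dplyr::filter(traits, !.data$strain %in% exclude,
                          .data$group %in% c("A", "B"))
  missing <- setdiff(traits$strain, colnames(P))
  if (length(missing) > 0)
    abort(paste0("Trait strains missing from the presence matrix: ",
                 paste(missing, collapse = ", ")))
  a_strains <- traits$strain[traits$group == "A"]
  b_strains <- traits$strain[traits$group == "B"]
  if (length(a_strains) == 0 || length(b_strains) == 0)
    abort("Both phenotype groups must be non-empty after exclusions.")
  fn <- rowSums(P[, a_strains, drop = FALSE] == 0)
  fp <- rowSums(P[, b_strains, drop = FALSE] == 1)
  ok <- fn <= max_fn & fp <= max_fp
  if (cap_sum) ok <- ok & (fn + fp) <= max(max_fn, max_fp)
  hits <- tibble(
    gene_id = rownames(P)[ok],
    n_A_present = length(a_strains) - unname(fn[ok]),
    n_A_total = length(a_strains),
    n_B_absent = length(b_strains) - unname(fp[ok]),
    n_B_total = length(b_strains),
    fn = as.integer(unname(fn[ok])), fp = as.integer(unname(fp[ok]))) |>
    dplyr::mutate(match_class = dplyr::case_when(
      .data$fn == 0 & .data$fp == 0 ~ "perfect",
      .data$fn == 1 & .data$fp == 0 ~ "one_fn",
      .data$fn == 0 & .data$fp == 1 ~ "one_fp",
      TRUE ~ "relaxed")) |>
    dplyr::arrange(factor(.data$match_class,
                          levels = c("perfect", "one_fn", "one_fp", "relaxed")),
                   .data$gene_id)
  structure(hits, class = c("cgh_trait_hits", class(hits)),
            rule = list(max_fn = max_fn, max_fp = max_fp, cap_sum = cap_sum),
            groups = list(A = a_strains, B = b_strains),
            trait_name = attr(traits, "trait_name"))
}

#' End-to-end recovery of planted trait genes
#'
#' Validation harness: simulates arrays from a truth object (or uses supplied
#' ones), runs QC, replicate averaging, presence calling and the trait filter,
#' and scores the hit list against the planted trait genes. The truth-side
#' expected hits (genes whose true pattern happens to match the phenotype
#' split within the tolerance) are enumerated for comparison.
#'
#' @param truth A `cgh_truth` from [simulate_pangenome()].
#' @param arrays Optional pre-simulated `cgh_arrays`.
#' @param cutoff EPP presence cutoff. Default 0.95.
#' @param max_fn,max_fp,cap_sum Trait-rule parameters, see
#'   [associate_trait()].
#' @return List: `hits` (the called hit tibble), `sensitivity` (fraction of
#'   planted genes recovered), `n_false_hits` (called hits not planted),
#'   `truth_expected_hits` (gene ids matching the split in the truth matrix),
#'   `n_false_beyond_truth` (false hits not explained by the truth pattern).
#' @export
recover_planted_traits <- function(truth, arrays = NULL, cutoff = 0.95,
                                   max_fn = 1L, max_fp = 1L, cap_sum = TRUE) {
  if (is.null(arrays)) arrays <- simulate_arrays(truth)
  qc <- probe_qc(arrays$intensities, arrays$selfself, anova_policy = "none")
  kept <- qc$probe_id[qc$kept]
  averaged <- average_replicates(arrays$intensities, keep = kept)
  calls <- call_presence(averaged, cutoff = cutoff)
  traits <- tibble(strain = names(truth$trait_groups),
                   group = unname(truth$trait_groups))
  hits <- associate_trait(calls, traits,
                          max_fn = max_fn, max_fp = max_fp, cap_sum = cap_sum,
                          exclude = c(truth$reference, truth$outgroups))
  planted <- truth$trait_gene_ids
  truth_hits <- associate_trait(
    truth_presence_matrix(truth), traits,
    max_fn = max_fn, max_fp = max_fp, cap_sum = cap_sum,
    exclude = c(truth$reference, truth$outgroups))
  list(
    hits = hits,
    sensitivity = if (length(planted) > 0)
      mean(planted %in% hits$gene_id) else NA_real_,
    n_false_hits = sum(!hits$gene_id %in% planted),
    truth_expected_hits = truth_hits$gene_id,
    n_false_beyond_truth = sum(!hits$gene_id %in% truth_hits$gene_id),
    calls = calls, qc = qc
  )
}

#' @export
print.cgh_trait_hits <- function(x, ...) {
  rule <- attr(x, "rule")
  cat("<cgh_trait_hits> ", nrow(x), " gene(s); rule max_fn=", rule$max_fn,
      " max_fp=", rule$max_fp, if (rule$cap_sum) " (exclusive)" else "",
      "\n", sep = "")
  NextMethod()
}
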