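#' Flag probes without reliable signal on the self-self arrays
#'
#' A probe whose reference DNA does not hybridize against itself carries no
#' information about any test strain. Operationalized as: a probe is kept iff
#' its mean raw signal across the self-self replicates is strictly above
#' `mean(background) + k * sd(background)` in both channels; a probe exactly
#' at the threshold is flagged.
#'
#' @param selfself Tibble of self-self spots with columns `probe_id`,
#'   `replicate`, `test_signal`, `ref_signal`, `background`.
#' @param k Multiplier on the background spread. Default 3.
#' @return A tibble with columns `probe_id`, `mean_test`, `mean_ref`,
#'   `low_signal_selfself`; attributes `threshold` and `k`. If raw signals are
#'   absent a warning is raised and every probe is kept.
#' @export
filter_selfself_background <- function(selfself, k = 3) {
  has_raw <- all(c("test_signal", "ref_signal", "background") %in%
                   names(selfself)) &&
    !all(is.na(selfself$test_signal))
  probes <- unique(selfself$probe_id)
  if (!has_raw) {
    warn("Self-self arrays carry no raw signals; background QC skipped, all probes kept.")
    return(structure(
      tibble(probe_id = probes, mean_test = NA_real_, mean_ref = NA_real_,
             low_signal_selfself = FALSE),
      threshold = NA_real_, k = k))
  }
  thr <- mean(selfself$background, na.rm = TRUE) +
    k * sd(selfself$background, na.rm = TRUE)
  rep <- selfself |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(mean_test = mean(.data$test_signal, na.rm = TRUE),
                     mean_ref = mean(.data$ref_signal, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(low_signal_selfself =
                    !(.data$mean_test > thr & .data$mean_ref > thr))
  rep <- rep[match(probes, rep$probe_id), ]
  structure(rep, threshold = thr, k = k)
}

#' Per-probe one-way ANOVA across strains
#'
#' For each probe, a fixed-effects one-way ANOVA of the replicate log ratios
#' across strain groups, Bonferroni-corrected over all tested probes. A probe
#' with zero within-group variance gets p = 0 if any between-group difference
#' exists and p = 1 otherwise.
#'
#' @param intensities Long tibble with `probe_id`, `strain`, `replicate`,
#'   `log2_ratio`.
#' @param alpha Significance level after correction. Default 0.01.
#' @param correction Multiple-testing correction (passed to
#'   [stats::p.adjust()]). Default `"bonferroni"`.
#' @return Tibble with `probe_id`, `f_stat`, `p_value`, `p_adj`,
#'   `significant` (adjusted p < alpha); attributes `alpha` and `correction`.
#' @export
anova_probe_filter <- function(intensities, alpha = 0.01,
                               correction = "bonferroni") {
  n_strain <- dplyr::n_distinct(intensities$strain)
  if (n_strain < 2)
    abort("ANOVA filter needs at least two strains.")
  stats_tab <- intensities |>
    dplyr::filter(is.finite(.data$log2_ratio)) |>
    dplyr::group_by(.data$probe_id, .data$strain) |>
    dplyr::summarise(n = dplyr::n(), s = sum(.data$log2_ratio),
                     ss = sum(.data$log2_ratio^2), .groups = "drop_last") |>
    dplyr::summarise(
      n_groups = dplyr::n(),
      n_total = sum(.data$n),
      ss_within = sum(.data$ss - .data$s^2 / .data$n),
      ss_between = sum(.data$s^2 / .data$n) - sum(.data$s)^2 / sum(.data$n),
      .groups = "drop")
  out <- stats_tab |>
    dplyr::mutate(
      df_between = .data$n_groups - 1L,
      df_within = .data$n_total - .data$n_groups,
      ss_within = pmax(.data$ss_within, 0),
      ss_between = pmax(.data$ss_between, 0),
      f_stat = (.data$ss_between / .data$df_between) /
        (.data$ss_within / .data$df_within),
      p_value = pf(.data$f_stat, .data$df_between, .data$df_within,
                   lower.tail = FALSE),
      # degenerate: no within-group variance at all
      p_value = dplyr::case_when(
        .data$ss_within <= 1e-300 & .data$ss_between > 1e-12 ~ 0,
        .data$ss_within <= 1e-300 ~ 1,
        TRUE ~ .data$p_value))
  out <- out |>
    dplyr::mutate(p_adj = p.adjust(.data$p_value, method = correction),
                  significant = .data$p_adj < alpha) |>
    dplyr::select("probe_id", "f_stat", "p_value", "p_adj", "significant")
  structure(out, alpha = alpha, correction = correction)
}

#' Combine QC stages into a probe report
#'
#' @param intensities Long intensity tibble.
#' @param selfself Self-self spot tibble (or `NULL` to skip background QC).
#' @param k Background threshold multiplier, see
#'   [filter_selfself_background()].
#' @param alpha,correction ANOVA parameters, see [anova_probe_filter()].
#' @param anova_policy `"keep_significant"` retains only probes significant in
#'   the ANOVA (the literal published procedure), `"drop_significant"` the
#'   complement, `"none"` applies no ANOVA-based removal (the report still
#'   carries the per-probe statistics).
#' @return Tibble with per-probe flags `low_signal_selfself`, `anova_fail`,
#'   `kept`; attribute `counts` summarising input/flag/kept totals.
#' @export
probe_qc <- function(intensities, selfself = NULL, k = 3, alpha = 0.01,
                     correction = "bonferroni",
                     anova_policy = c("keep_significant", "drop_significant",
                                      "none")) {
  anova_policy <- match.arg(anova_policy)
  probes <- unique(intensities$probe_id)
  if (!is.null(selfself)) {
    bg <- filter_selfself_background(selfself, k = k)
    low <- setNames(bg$low_signal_selfself, bg$probe_id)[probes]
    low[is.na(low)] <- FALSE
  } else {
    low <- setNames(rep(FALSE, length(probes)), probes)
  }
  av <- anova_probe_filter(intensities, alpha = alpha, correction = correction)
  sig <- setNames(av$significant, av$probe_id)[probes]
  anova_fail <- switch(anova_policy,
    keep_significant = !sig,
    drop_significant = sig,
    none = rep(FALSE, length(probes)))
  low <- unname(low)
  anova_fail <- unname(anova_fail)
  rep <- tibble(probe_id = probes,
                low_signal_selfself = low,
                anova_fail = anova_fail,
                kept = !low & !anova_fail)
  counts <- list(n_input = length(probes),
                 n_low_signal = sum(rep$low_signal_selfself),
                 n_anova_fail = sum(rep$anova_fail),
                 n_both = sum(rep$low_signal_selfself & rep$anova_fail),
                 n_kept = sum(rep$kept))
  structure(rep, counts = counts, k = k, alpha = alpha,
            correction = correction, anova_policy = anova_policy)
}

#' Average replicate spots to one log ratio per probe and strain
#'
#' Arithmetic mean over non-missing replicates; probes with zero valid
#' replicates for a strain yield `NA` and are reported.
#'
#' @param intensities Long tibble with `probe_id`, `strain`, `replicate`,
#'   `log2_ratio` (usually pre-filtered to kept probes).
#' @param keep Optional character vector of probe ids to retain first.
#' @return Tibble `probe_id`, `strain`, `log2_ratio`, `n_replicates`.
#' @export
average_replicates <- function(intensities, keep = NULL) {
  tab <- intensities
  if (!is.null(keep)) tab <- dplyr::filter(tab, .data$probe_id %in% keep)
  tab |>
    dplyr::group_by(.data$probe_id, .data$strain) |>
    dplyr::summarise(
      n_replicates = sum(is.finite(.data$log2_ratio)),
      log2_ratio = mean(.data$log2_ratio[is.finite(.data$log2_ratio)]),
      .groups = "drop") |>
    dplyr::mutate(log2_ratio = ifelse(.data$n_replicates > 0,
                                      .data$log2_ratio, NA_real_)) |>
    dplyr::select("probe_id", "strain", "log2_ratio", "n_replicates")
}
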