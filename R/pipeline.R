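#' Assemble a pipeline run configuration
#'
#' One object gathers every analysis parameter so a run is reproducible from
#' its manifest. Inputs are either file paths (intensity table, self-self
#' table, trait table) or a simulation config, in which case the pipeline
#' generates its own inputs.
#'
#' @param intensity_path,selfself_path,trait_path Input TSV paths (any may be
#'   `NULL` when `simulate` is given; a `NULL` `trait_path` skips the
#'   association stage).
#' @param simulate Optional [simulation_config()] used to generate inputs.
#' @param reference Reference strain name (defaults to the simulator's).
#' @param outgroups Outgroup strain names.
#' @param alpha,anova_policy,background_k QC parameters (see [probe_qc()]).
#' @param epp_cutoff Presence cutoff. Default 0.95.
#' @param bootstrap_B Bootstrap replicates. Default 1000.
#' @param metric Binary distance metric. Default `"hamming"`.
#' @param max_fn,max_fp,cap_sum Trait-association rule.
#' @param seed Root seed; per-stage seeds are derived deterministically.
#' @return A list of class `cgh_run_config`.
#' @export
run_config <- function(intensity_path = NULL, selfself_path = NULL,
                       trait_path = NULL, simulate = NULL,
                       reference = NULL, outgroups = character(),
                       alpha = 0.01, anova_policy = "none", background_k = 3,
                       epp_cutoff = 0.95, bootstrap_B = 1000,
                       metric = "hamming",
                       max_fn = 1L, max_fp = 1L, cap_sum = TRUE,
                       seed = 1L) {
  for (p in c(intensity_path, selfself_path, trait_path)) {
    if (!is.null(p) && !file.exists(p))
      abort(paste0("Input path does not exist: ", p))
  }
  if (is.null(intensity_path) && is.null(simulate))
    abort("Either `intensity_path` or `simulate` must be given.")
  structure(list(
    intensity_path = intensity_path, selfself_path = selfself_path,
    trait_path = trait_path, simulate = simulate,
    reference = reference, outgroups = outgroups,
    alpha = alpha, anova_policy = anova_policy, background_k = background_k,
    epp_cutoff = epp_cutoff, bootstrap_B = as.integer(bootstrap_B),
    metric = metric, max_fn = max_fn, max_fp = max_fp, cap_sum = cap_sum,
    seed = as.integer(seed)
  ), class = "cgh_run_config")
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11, bootstrap = 29)
  # double arithmetic avoids 32-bit overflow for large root seeds
  as.integer((as.numeric(config$seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' Run the full CGH genomotyping pipeline
#'
#' Executes QC, replicate averaging, presence calling, pan-genome
#' partitioning, the bootstrapped neighbour-joining dendrogram and (when a
#' trait table is available) the trait-association filter, writing every
#' intermediate artifact plus a JSON manifest of all headline counts into
#' `output_dir`. A rerun with the same config and inputs is bit-identical.
#'
#' @param config A [run_config()].
#' @param output_dir Directory created (if needed) for all artifacts.
#' @return Invisibly, a list with the in-memory results (`qc`, `averaged`,
#'   `calls`, `partition`, `tree`, `hits`, `manifest`).
#' @export
run_all <- function(config, output_dir) {
  stopifnot(inherits(config, "cgh_run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- as.integer(stage_seed(config, "simulate"))
    truth <- stage("simulate", simulate_pangenome(sim_cfg))
    arrays <- stage("simulate", simulate_arrays(truth, sim_cfg))
    intensities <- arrays$intensities
    selfself <- arrays$selfself
    reference <- truth$reference
    outgroups <- truth$outgroups
    traits <- if (length(truth$trait_groups) > 0)
      tibble(strain = names(truth$trait_groups),
             group = unname(truth$trait_groups)) else NULL
    write_intensity_table(intensities, file.path(output_dir, "intensities.tsv"))
    write_intensity_table(selfself, file.path(output_dir, "selfself.tsv"))
    write_matrix_tsv(truth_presence_matrix(truth),
                     file.path(output_dir, "truth_presence.tsv"))
    write_newick(truth$tree, file.path(output_dir, "true_tree.nwk"))
  } else {
    intensities <- stage("read", read_intensity_table(config$intensity_path))
    selfself <- if (!is.null(config$selfself_path))
      stage("read", read_intensity_table(config$selfself_path)) else NULL
    reference <- config$reference
    outgroups <- config$outgroups
    traits <- if (!is.null(config$trait_path))
      readr::read_tsv(config$trait_path, show_col_types = FALSE,
                      progress = FALSE) else NULL
    if (is.null(reference)) abort("`reference` must be set for file inputs.")
  }

  qc <- stage("qc", probe_qc(intensities, selfself, k = config$background_k,
                             alpha = config$alpha,
                             anova_policy = config$anova_policy))
  kept <- qc$probe_id[qc$kept]
  readr::write_tsv(qc, file.path(output_dir, "qc_report.tsv"),
                   progress = FALSE)

  averaged <- stage("average", average_replicates(intensities, keep = kept))
  readr::write_tsv(averaged, file.path(output_dir, "averaged.tsv"),
                   progress = FALSE)

  calls <- stage("call", call_presence(averaged, cutoff = config$epp_cutoff))
  write_matrix_tsv(calls$presence, file.path(output_dir, "presence.tsv"))
  write_matrix_tsv(calls$epp, file.path(output_dir, "epp.tsv"), digits = 4)
  readr::write_tsv(calls$strain_info, file.path(output_dir, "fit_report.tsv"),
                   progress = FALSE)

  partition <- stage("pangenome", pangenome_partition(
    calls, reference = reference, exclude_from_core = outgroups))
  writeLines(partition$core_genes, file.path(output_dir, "core_genes.txt"))
  writeLines(partition$reference_specific,
             file.path(output_dir, "reference_specific.txt"))
  write_matrix_tsv(partition$overlap, file.path(output_dir, "overlaps.tsv"))
  readr::write_tsv(partition$dissimilarity,
                   file.path(output_dir, "dissimilarity.tsv"),
                   progress = FALSE)

  tree <- stage("tree", bootstrap_consensus(
    calls, B = config$bootstrap_B,
    seed = as.integer(stage_seed(config, "bootstrap")),
    metric = config$metric))
  write_newick(tree$consensus, file.path(output_dir, "consensus.nwk"))
  write_newick(tree$full_tree, file.path(output_dir, "nj_tree.nwk"))
  readr::write_tsv(tree$bipartitions,
                   file.path(output_dir, "bipartitions.tsv"),
                   progress = FALSE)

  hits <- NULL
  if (!is.null(traits) && nrow(traits) > 0) {
    hits <- stage("associate", associate_trait(
      calls, traits, max_fn = config$max_fn, max_fp = config$max_fp,
      cap_sum = config$cap_sum, exclude = c(reference, outgroups)))
    readr::write_tsv(as_tibble(hits), file.path(output_dir, "trait_hits.tsv"),
                     progress = FALSE)
  } else {
    message("No trait table: association stage skipped.")
  }

  counts <- attr(qc, "counts")
  ingroup <- setdiff(colnames(calls$presence), outgroups)
  manifest <- list(
    config = config_for_manifest(config),
    probes_input = counts$n_input,
    probes_low_signal = counts$n_low_signal,
    probes_anova_flagged = counts$n_anova_fail,
    probes_kept = counts$n_kept,
    strains = colnames(calls$presence),
    reference = reference,
    outgroups = outgroups,
    present_counts = as.list(partition$present_counts),
    core_size = length(partition$core_genes),
    variable_size = length(partition$variable_genes),
    reference_specific_size = length(partition$reference_specific),
    dissimilarity_pct = setNames(
      as.list(partition$dissimilarity$dissimilarity_pct),
      partition$dissimilarity$strain),
    bootstrap_B = tree$B,
    n_trait_hits = if (is.null(hits)) NA_integer_ else nrow(hits),
    outputs = list.files(output_dir)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(truth = truth, qc = qc, averaged = averaged, calls = calls,
                 partition = partition, tree = tree, hits = hits,
                 manifest = manifest))
}

config_for_manifest <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulate)) out$simulate <- unclass(out$simulate)
  out
}
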