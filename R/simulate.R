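#' Configuration for a synthetic CGH strain-collection experiment
#'
#' Bundles every knob of the synthetic-data generator: the size of the strain
#' collection, the composition of the pan-genome, the gene-loss process along
#' the strain tree, and the two-color intensity noise model. The defaults
#' emulate the structure of a 16-strain coccolithophore CGH experiment with
#' technical triplicates, one hybridized outgroup species, and a log-ratio
#' mixture in which the "present" class peaks near 0 and the absent class is
#' left-shifted by about five standard deviations.
#'
#' @param n_strains Number of in-group strains, including the reference
#'   (which is always the first strain and carries every probe).
#' @param n_outgroups Number of outgroup species hybridized alongside.
#' @param n_genes Number of gene-model probes on the array.
#' @param core_fraction Fraction of genes forced present in every strain.
#' @param n_reference_specific Number of genes forced present only in the
#'   reference.
#' @param loss_rate_per_branch Probability that a variable gene, still present
#'   at the top of a branch of the strain tree, is lost along that branch.
#'   Loss is irreversible down the tree.
#' @param present_mean,present_sd Log2-ratio distribution of present genes.
#' @param absent_mean,absent_sd Log2-ratio distribution of absent genes.
#' @param diverged_mean,diverged_sd Log2-ratio distribution of diverged genes
#'   (an intermediate class exercising the grey zone of the presence caller).
#' @param diverged_fraction Fraction of loss events relabelled "diverged".
#' @param n_replicates Technical replicates per strain (triplicates by
#'   default, as in the emulated experiment).
#' @param replicate_sd Additional replicate-to-replicate noise (log2 units).
#' @param background_fail_fraction Fraction of probes emitted with raw
#'   self-self signals at background level (planted QC failures).
#' @param n_trait_genes Number of genes planted with a perfect
#'   present-in-group-A / absent-in-group-B phenotype pattern.
#' @param trait_group_assignment Named character vector mapping strain names
#'   to `"A"` or `"B"`. `NULL` splits the non-reference in-group strains
#'   7/8 (first seven to A).
#' @param outgroup_absent_fraction Extra probability that a variable gene is
#'   absent in an outgroup, creating the deep outgroup split of the dendrogram.
#' @param star_tree If `TRUE`, losses are i.i.d. per strain (star tree) rather
#'   than correlated along a random strain tree.
#' @param seed Integer seed; fully determines the generator output.
#'
#' @return An object of class `cgh_sim_config` (a named list).
#' @export
#' @examples
#' cfg <- simulation_config(n_strains = 6, n_genes = 200, seed = 1)
#' truth <- simulate_pangenome(cfg)
simulation_config <- function(n_strains = 16,
                              n_outgroups = 1,
                              n_genes = 2000,
                              core_fraction = 0.6,
                              n_reference_specific = 20,
                              loss_rate_per_branch = 0.05,
                              present_mean = 0, present_sd = 0.3,
                              absent_mean = -2.5, absent_sd = 0.5,
                              diverged_mean = -1.0, diverged_sd = 0.3,
                              diverged_fraction = 0.1,
                              n_replicates = 3,
                              replicate_sd = 0.1,
                              background_fail_fraction = 0.02,
                              n_trait_genes = 20,
                              trait_group_assignment = NULL,
                              outgroup_absent_fraction = 0.3,
                              star_tree = FALSE,
                              seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains), n_outgroups = as.integer(n_outgroups),
    n_genes = as.integer(n_genes), core_fraction = core_fraction,
    n_reference_specific = as.integer(n_reference_specific),
    loss_rate_per_branch = loss_rate_per_branch,
    present_mean = present_mean, present_sd = present_sd,
    absent_mean = absent_mean, absent_sd = absent_sd,
    diverged_mean = diverged_mean, diverged_sd = diverged_sd,
    diverged_fraction = diverged_fraction,
    n_replicates = as.integer(n_replicates), replicate_sd = replicate_sd,
    background_fail_fraction = background_fail_fraction,
    n_trait_genes = as.integer(n_trait_genes),
    trait_group_assignment = trait_group_assignment,
    outgroup_absent_fraction = outgroup_absent_fraction,
    star_tree = isTRUE(star_tree),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "cgh_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_strains >= 2, cfg$n_outgroups >= 0, cfg$n_genes >= 1,
            cfg$n_replicates >= 1)
  if (cfg$core_fraction < 0 || cfg$core_fraction > 1)
    abort("`core_fraction` must lie in [0, 1].")
  n_core <- round(cfg$core_fraction * cfg$n_genes)
  if (n_core + cfg$n_reference_specific > cfg$n_genes)
    abort("core_fraction * n_genes + n_reference_specific exceeds n_genes.")
  if (!(cfg$absent_mean < cfg$diverged_mean && cfg$diverged_mean < cfg$present_mean))
    abort("Class means must satisfy absent_mean < diverged_mean < present_mean.")
  if (any(c(cfg$present_sd, cfg$absent_sd, cfg$diverged_sd, cfg$replicate_sd) <= 0))
    abort("All class and replicate standard deviations must be positive.")
  if (cfg$loss_rate_per_branch < 0 || cfg$loss_rate_per_branch > 1)
    abort("`loss_rate_per_branch` must be a probability.")
  if (cfg$background_fail_fraction < 0 || cfg$background_fail_fraction > 1)
    abort("`background_fail_fraction` must be a probability.")
  invisible(cfg)
}

sim_strain_names <- function(cfg) {
  ingroup <- sprintf("EHS%02d", seq_len(cfg$n_strains))
  outgroup <- if (cfg$n_outgroups > 0) sprintf("OG%02d", seq_len(cfg$n_outgroups)) else character()
  list(reference = ingroup[1L], ingroup = ingroup, outgroups = outgroup,
       all = c(ingroup, outgroup))
}

default_trait_groups <- function(cfg, names) {
  candidates <- setdiff(names$ingroup, names$reference)
  n_a <- min(7L, max(1L, floor(length(candidates) / 2)))
  groups <- setNames(rep("B", length(candidates)), candidates)
  groups[seq_len(n_a)] <- "A"
  groups
}

# Sequential random-attachment unrooted tree with exponential branch lengths.
# Built as an edge table (parent, child, length) over node ids, converted to
# Newick and re-read with ape so downstream code sees a standard `phylo`.
random_attachment_tree <- function(tips, rate = 1) {
  n <- length(tips)
  stopifnot(n >= 3)
  root <- "n1"
  edges <- tibble(
    parent = root, child = tips[1:3], length = rexp(3, rate)
  )
  next_node <- 2L
  for (k in seq(4, length.out = max(0, n - 3))) {
    i <- sample.int(nrow(edges), 1L)
    old <- edges[i, ]
    new_node <- paste0("n", next_node); next_node <- next_node + 1L
    u <- runif(1)
    edges <- edges[-i, ]
    edges <- dplyr::bind_rows(edges, tibble(
      parent = c(old$parent, new_node, new_node),
      child = c(new_node, old$child, tips[k]),
      length = c(u * old$length, (1 - u) * old$length, rexp(1, rate))
    ))
  }
  newick_from_edges <- function(node) {
    kids <- edges[edges$parent == node, ]
    if (nrow(kids) == 0) return(node)
    parts <- vapply(seq_len(nrow(kids)), function(j) {
      paste0(newick_from_edges(kids$child[j]), ":",
             format(kids$length[j], digits = 12))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(newick_from_edges(root), ";"))
}

#' Simulate a pan-genome with known gene-content truth
#'
#' Draws a random strain tree (sequential random attachment, exponential
#' branch lengths), marks a core set of genes present in every strain, evolves
#' the remaining variable genes by irreversible Bernoulli loss events along
#' each branch, relabels a fraction of losses as "diverged", and finally
#' forces the reference-specific and planted trait-gene patterns. The
#' reference strain carries every probe by construction (the array is designed
#' from its genome).
#'
#' @param config A [simulation_config()].
#' @return An object of class `cgh_truth`: a list with `truth` (character
#'   matrix genes x strains with entries `"present"`, `"diverged"`,
#'   `"absent"`), `tree` (the true strain tree, class `phylo`),
#'   `trait_gene_ids`, `reference_specific_ids`, `trait_groups` (named A/B
#'   vector), `reference`, `outgroups` and the `config` used.
#' @export
simulate_pangenome <- function(config) {
  validate_sim_config(config)
  names <- sim_strain_names(config)
  groups <- config$trait_group_assignment %||% default_trait_groups(config, names)
  groups <- groups[groups %in% c("A", "B")]
  if (config$n_trait_genes > 0 &&
      (!any(groups == "A") || !any(groups == "B")))
    abort("Trait pattern impossible: group A or group B is empty.")
  if (!all(names(groups) %in% names$all))
    abort("trait_group_assignment names unknown strains.")

  set.seed(config$seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  strains <- names$all
  n_core <- round(config$core_fraction * config$n_genes)
  core_ids <- sort(sample(genes, n_core))
  variable_ids <- setdiff(genes, core_ids)

  # strain tree over all hybridized tips (outgroups included)
  tree <- if (config$star_tree || length(strains) < 3) {
    ape::read.tree(text = paste0(
      "(", paste(paste0(strains, ":1"), collapse = ","), ");"))
  } else {
    random_attachment_tree(sample(strains))
  }

  absent <- matrix(FALSE, nrow = length(variable_ids), ncol = length(strains),
                   dimnames = list(variable_ids, strains))
  if (length(variable_ids) > 0 && config$loss_rate_per_branch > 0) {
    tr <- ape::reorder.phylo(tree, "cladewise")
    n_tip <- length(tr$tip.label)
    n_node <- n_tip + tr$Nnode
    state <- matrix(FALSE, nrow = length(variable_ids), ncol = n_node)
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      loss <- runif(length(variable_ids)) < config$loss_rate_per_branch
      state[, child] <- state[, parent] | loss
    }
    absent[, tr$tip.label] <- state[, seq_len(n_tip)]
  }
  if (length(names$outgroups) > 0 && length(variable_ids) > 0 &&
      config$outgroup_absent_fraction > 0) {
    # the extra outgroup absence is mostly ancestral: genes gained on the
    # reference lineage after the outgroup split are missing from every
    # outgroup (fraction = outgroup_absent_fraction), with an additional
    # one-third of that rate lost per outgroup lineage individually
    shared <- runif(length(variable_ids)) < config$outgroup_absent_fraction
    for (og in names$outgroups) {
      extra <- runif(length(variable_ids)) < config$outgroup_absent_fraction / 3
      absent[, og] <- absent[, og] | shared | extra
    }
  }
  absent[, names$reference] <- FALSE

  truth <- matrix("present", nrow = config$n_genes, ncol = length(strains),
                  dimnames = list(genes, strains))
  if (length(variable_ids) > 0) {
    div <- absent & (matrix(runif(length(absent)), nrow = nrow(absent)) <
                       config$diverged_fraction)
    truth[variable_ids, ][absent] <- "absent"
    truth[variable_ids, ][div] <- "diverged"
  }

  free_ids <- variable_ids
  ref_specific <- character()
  if (config$n_reference_specific > 0) {
    ref_specific <- sort(sample(free_ids, config$n_reference_specific))
    free_ids <- setdiff(free_ids, ref_specific)
    truth[ref_specific, ] <- "absent"
    truth[ref_specific, names$reference] <- "present"
  }
  trait_ids <- character()
  n_trait <- min(config$n_trait_genes, length(free_ids))
  if (n_trait > 0) {
    trait_ids <- sort(sample(free_ids, n_trait))
    a_strains <- names(groups)[groups == "A"]
    b_strains <- names(groups)[groups == "B"]
    truth[trait_ids, a_strains] <- "present"
    truth[trait_ids, b_strains] <- "absent"
    truth[trait_ids, names$reference] <- "present"
  }

  structure(list(
    truth = truth, tree = tree,
    trait_gene_ids = trait_ids, reference_specific_ids = ref_specific,
    core_gene_ids = core_ids,
    trait_groups = groups,
    reference = names$reference, outgroups = names$outgroups,
    strains = strains, config = config
  ), class = "cgh_truth")
}

#' Simulate two-color CGH intensity tables from gene-content truth
#'
#' Per gene, strain and replicate the log2(test/reference) ratio is drawn as
#' `Normal(mu_class, sd_class) + Normal(0, replicate_sd)` with the class taken
#' from the truth matrix. Self-versus-self arrays (reference DNA in both
#' channels) are drawn entirely from the "present" class. Raw channel signals
#' are emitted for every spot; a `background_fail_fraction` of probes is
#' planted with self-self signals at background level so the QC stage has
#' known failures to find.
#'
#' @param truth A `cgh_truth` from [simulate_pangenome()].
#' @param config The matching [simulation_config()]. Defaults to the config
#'   stored in `truth`.
#' @return A list of class `cgh_arrays` with tibbles `intensities` (columns
#'   `probe_id`, `strain`, `replicate`, `log2_ratio`, `test_signal`,
#'   `ref_signal`, `background`) and `selfself` (same columns, strain
#'   `"SELFSELF"`), plus `reference`, `outgroups`, `low_signal_probe_ids`
#'   (the planted failures) and `config`.
#' @export
simulate_arrays <- function(truth, config = truth$config) {
  validate_sim_config(config)
  if (!identical(rownames(truth$truth), sprintf("g%05d", seq_len(config$n_genes))))
    stopifnot(nrow(truth$truth) == config$n_genes)
  set.seed(config$seed + 1000L)
  genes <- rownames(truth$truth)
  strains <- colnames(truth$truth)
  n_rep <- config$n_replicates

  mu <- c(present = config$present_mean, diverged = config$diverged_mean,
          absent = config$absent_mean)
  sdv <- c(present = config$present_sd, diverged = config$diverged_sd,
           absent = config$absent_sd)

  grid <- tidyr::expand_grid(strain = strains, replicate = seq_len(n_rep),
                             probe_id = genes)
  cls <- truth$truth[cbind(grid$probe_id, grid$strain)]
  ratio <- rnorm(nrow(grid), mu[cls], sdv[cls]) +
    rnorm(nrow(grid), 0, config$replicate_sd)

  n_fail <- round(config$background_fail_fraction * config$n_genes)
  fail_ids <- if (n_fail > 0) sort(sample(genes, n_fail)) else character()

  make_signals <- function(tab, ratio) {
    bg <- pmax(1, rnorm(nrow(tab), 50, 5))
    ref_sig <- pmax(1, rnorm(nrow(tab), 5000, 500))
    test_sig <- ref_sig * 2^ratio
    fail <- tab$probe_id %in% fail_ids
    # planted low-signal probes sit at background level in both channels
    test_sig[fail] <- pmax(1, rnorm(sum(fail), 50, 5))
    ref_sig[fail] <- pmax(1, rnorm(sum(fail), 50, 5))
    tibble(test_signal = test_sig, ref_signal = ref_sig, background = bg)
  }

  intensities <- dplyr::bind_cols(
    grid[, c("probe_id", "strain", "replicate")],
    tibble(log2_ratio = ratio),
    make_signals(grid, ratio)
  )

  self_grid <- tidyr::expand_grid(strain = "SELFSELF",
                                  replicate = seq_len(n_rep),
                                  probe_id = genes)
  self_ratio <- rnorm(nrow(self_grid), config$present_mean, config$present_sd) +
    rnorm(nrow(self_grid), 0, config$replicate_sd)
  selfself <- dplyr::bind_cols(
    self_grid[, c("probe_id", "strain", "replicate")],
    tibble(log2_ratio = self_ratio),
    make_signals(self_grid, self_ratio)
  )

  structure(list(
    intensities = as_tibble(intensities), selfself = as_tibble(selfself),
    reference = truth$reference, outgroups = truth$outgroups,
    low_signal_probe_ids = fail_ids, config = config
  ), class = "cgh_arrays")
}

#' Map simulation truth classes to binary presence
#'
#' The presence caller is binary, whereas the simulator distinguishes
#' "diverged" from "absent". Following standard CGH scoring, diverged genes
#' are unobservable as present (their probes do not hybridize well) and map
#' to absent.
#'
#' @param truth A `cgh_truth` object or its character matrix.
#' @return Integer matrix of 0/1 with the same dimnames.
#' @export
truth_presence_matrix <- function(truth) {
  m <- if (inherits(truth, "cgh_truth")) truth$truth else truth
  out <- (m == "present") * 1L
  dimnames(out) <- dimnames(m)
  out
}

#' @export
print.cgh_truth <- function(x, ...) {
  cat("<cgh_truth> ", nrow(x$truth), " genes x ", ncol(x$truth), " strains\n",
      "  reference: ", x$reference,
      "; outgroups: ", paste(x$outgroups, collapse = ", "), "\n",
      "  core genes: ", length(x$core_gene_ids),
      "; reference-specific: ", length(x$reference_specific_ids),
      "; planted trait genes: ", length(x$trait_gene_ids), "\n", sep = "")
  invisible(x)
}

#' @export
print.cgh_arrays <- function(x, ...) {
  cat("<cgh_arrays> ", dplyr::n_distinct(x$intensities$probe_id), " probes, ",
      dplyr::n_distinct(x$intensities$strain), " strains, ",
      max(x$intensities$replicate), " replicates (+ self-self)\n", sep = "")
  invisible(x)
}
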