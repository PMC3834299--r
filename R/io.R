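#' Read a long-format CGH intensity table
#'
#' The canonical intensity format is a tidy TSV with one spot per row and
#' mandatory columns `probe_id`, `strain`, `replicate`, `log2_ratio`; the raw
#' channel columns `test_signal`, `ref_signal`, `background` are optional and
#' only needed for background QC. Probe order is the file order of first
#' occurrence and is preserved downstream.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param reference Name of the reference strain (recorded as an attribute).
#' @param outgroups Character vector of outgroup strain names.
#' @return A tibble with attributes `reference` and `outgroups`; probe order
#'   of first appearance stored in attribute `probe_levels`.
#' @export
read_intensity_table <- function(path, reference = NULL, outgroups = character()) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE, na = c("", "NA"))
  mandatory <- c("probe_id", "strain", "replicate", "log2_ratio")
  missing_cols <- setdiff(mandatory, names(tab))
  if (length(missing_cols) > 0)
    abort(paste0("Missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  prob <- readr::problems(tab)
  if (nrow(prob) > 0)
    abort(paste0("Malformed cells at line(s): ",
                 paste(unique(prob$row + 1L), collapse = ", ")))
  key <- paste(tab$probe_id, tab$strain, tab$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    abort(paste0("Duplicate (probe, strain, replicate) at file line(s): ",
                 paste(dup + 1L, collapse = ", ")))  # +1 for the header row
  if (!is.null(reference) && !reference %in% tab$strain)
    abort(paste0("Reference strain '", reference, "' not present in file."))
  structure(as_tibble(tab),
            reference = reference, outgroups = outgroups,
            probe_levels = unique(tab$probe_id))
}

#' Write an intensity table as TSV
#'
#' Deterministic writer: identical inputs produce identical bytes. Numeric
#' values are written with 15 significant digits so a round trip reproduces
#' them to at least 12 significant digits.
#'
#' @param tab Tibble with intensity columns (see [read_intensity_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(tab, path) {
  out <- dplyr::mutate(tab, dplyr::across(
    dplyr::where(is.numeric) & !dplyr::any_of("replicate"),
    ~ formatC(.x, digits = 15, format = "g")))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Load a packaged phenotype table
#'
#' Two fixture tables ship with the package, transcribing the published strain
#' phenotypes of the emulated experiment: `"coccoliths"` (whether each of the
#' 16 strains bears coccoliths, Y/N) and `"virus_susceptibility"` (a 16-strain
#' by 9-virus lysis matrix; `+` = culture lysis, `-` = no lysis). The
#' coccolith table maps Y to group A (calcifying) and N to group B. The lysis
#' matrix is reduced to two groups by a configurable rule because the source
#' study does not state one: a strain is susceptible (group A) if it is lysed
#' by at least `min_lysed` of the tested virus strains.
#'
#' @param name `"coccoliths"` or `"virus_susceptibility"`.
#' @param min_lysed Minimum number of lysing viruses for a strain to be
#'   labelled susceptible (virus fixture only). Default 1.
#' @param exclude Strains to mark `"excluded"` (e.g. the reference).
#' @return A tibble with columns `strain`, `group` (`"A"`, `"B"` or
#'   `"excluded"`) and attribute `trait_name`.
#' @export
#' @examples
#' load_trait_fixture("coccoliths")
#' load_trait_fixture("virus_susceptibility", min_lysed = 2)
load_trait_fixture <- function(name = c("coccoliths", "virus_susceptibility"),
                               min_lysed = 1L, exclude = character()) {
  name <- match.arg(name)
  fixture <- function(f) system.file("extdata", f, package = "cghpangenome",
                                     mustWork = TRUE)
  if (name == "coccoliths") {
    tab <- readr::read_tsv(fixture("coccoliths.tsv"), show_col_types = FALSE,
                           progress = FALSE)
    out <- tibble(strain = tab$strain,
                  group = ifelse(tab$coccoliths == "Y", "A", "B"))
    trait <- "calcification"
  } else {
    tab <- readr::read_tsv(fixture("virus_lysis.tsv"), show_col_types = FALSE,
                           progress = FALSE)
    n_lysed <- rowSums(tab[, -1] == "+")
    out <- tibble(strain = tab$strain,
                  group = ifelse(n_lysed >= min_lysed, "A", "B"))
    trait <- "virus_susceptibility"
  }
  out$group[out$strain %in% exclude] <- "excluded"
  if (!any(out$group == "A") || !any(out$group == "B"))
    abort("Trait table must keep at least one strain in each of A and B.")
  structure(out, trait_name = trait)
}

#' Normalize strain names via the shipped alias table
#'
#' Published strain tables sometimes carry annotated names such as
#' `"12-1 ( = CCMP371)"`; this maps them onto the canonical short names used
#' by the fixtures.
#'
#' @param x Character vector of strain names.
#' @return Character vector with aliases replaced.
#' @export
normalize_strain_names <- function(x) {
  aliases <- readr::read_tsv(
    system.file("extdata", "strain_aliases.tsv", package = "cghpangenome",
                mustWork = TRUE), show_col_types = FALSE, progress = FALSE)
  idx <- match(x, aliases$alias)
  ifelse(is.na(idx), x, aliases$canonical[idx])
}

#' Write a tree to a Newick file
#'
#' Bootstrap supports, when present as node labels, are serialized as standard
#' internal-node labels so any Newick parser recovers them.
#'
#' @param tree A `phylo` object or a `cgh_support_tree` (its consensus tree is
#'   written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "cgh_support_tree")) tree <- tree$consensus
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a genes-by-strains matrix as TSV
#'
#' Genes as rows, strains as columns, with a leading `gene_id` header column.
#'
#' @param m Matrix with rownames (gene ids) and colnames (strains).
#' @param path Output path.
#' @param digits Significant digits for numeric matrices (`NULL` = as is).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, digits = NULL) {
  vals <- if (!is.null(digits)) round(m, digits) else m
  out <- dplyr::bind_cols(tibble(gene_id = rownames(m)),
                          as_tibble(as.data.frame(vals)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  m
}
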