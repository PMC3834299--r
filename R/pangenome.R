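#' Partition the gene complement into core, variable and reference-specific
#'
#' Core genes are present in every strain of the chosen scope (by convention
#' the in-group strains, outgroups excluded); the variable (non-core) genome
#' is the complement within the kept probes; reference-specific genes are
#' present in the reference and absent from every other hybridized strain,
#' outgroups included.
#'
#' @param presence A `cgh_presence` object or a 0/1 genes-x-strains matrix.
#' @param reference Reference strain name (must be a column).
#' @param scope Strains defining the core (default: all columns except
#'   `exclude_from_core`).
#' @param exclude_from_core Strains excluded from the core definition
#'   (typically the outgroups).
#' @return Object of class `cgh_pangenome`: gene-id sets `core_genes`,
#'   `variable_genes`, `reference_specific`, per-strain present counts,
#'   pairwise overlap matrix `overlap` and reference-anchored dissimilarities
#'   (see [dissimilarity_vs_reference()]).
#' @export
pangenome_partition <- function(presence, reference,
                                scope = NULL, exclude_from_core = character()) {
  P <- presence_as_matrix(presence)
  if (!reference %in% colnames(P))
    abort(paste0("Reference strain '", reference, "' is not a column of P."))
  scope <- scope %||% setdiff(colnames(P), exclude_from_core)
  if (length(scope) == 0) abort("Empty strain scope for the core definition.")
  if (!all(scope %in% colnames(P)))
    abort("`scope` names strains absent from the presence matrix.")
  core <- rownames(P)[rowSums(P[, scope, drop = FALSE]) == length(scope)]
  variable <- setdiff(rownames(P), core)
  others <- setdiff(colnames(P), reference)
  ref_specific <- rownames(P)[P[, reference] == 1 &
                                rowSums(P[, others, drop = FALSE]) == 0]
  O <- pairwise_overlaps(P)
  d <- dissimilarity_vs_reference(P, reference)
  structure(list(
    core_genes = core, variable_genes = variable,
    reference_specific = ref_specific,
    present_counts = colSums(P), overlap = O, dissimilarity = d,
    reference = reference, scope = scope, n_genes = nrow(P)
  ), class = "cgh_pangenome")
}

presence_as_matrix <- function(presence) {
  P <- if (inherits(presence, "cgh_presence")) presence$presence else presence
  if (is.null(rownames(P))) rownames(P) <- sprintf("g%05d", seq_len(nrow(P)))
  storage.mode(P) <- "integer"
  if (nrow(P) == 0 || ncol(P) == 0) abort("Empty presence matrix.")
  P
}

#' Gene-content dissimilarity of each strain against the reference
#'
#' `d(s)` is the percentage of reference-present genes that strain `s`
#' lacks: `d(s) = 100 * #(present in ref, absent in s) / #(present in ref)`.
#' Identity is its complement.
#'
#' @inheritParams pangenome_partition
#' @return Tibble `strain`, `n_differing`, `n_reference_present`,
#'   `dissimilarity_pct`, `identity_pct`.
#' @export
dissimilarity_vs_reference <- function(presence, reference) {
  P <- presence_as_matrix(presence)
  ref <- P[, reference]
  n_ref <- sum(ref == 1)
  if (n_ref == 0) abort("Reference strain has zero present genes.")
  diff_counts <- colSums(ref == 1 & P == 0)
  tibble(strain = colnames(P),
         n_differing = unname(diff_counts),
         n_reference_present = n_ref,
         dissimilarity_pct = unname(100 * diff_counts / n_ref),
         identity_pct = unname(100 - 100 * diff_counts / n_ref))
}

#' Pairwise overlap of present genes between strains
#'
#' `O(s, t)` counts the genes called present in both strains; the diagonal is
#' each strain's present count.
#'
#' @inheritParams pangenome_partition
#' @return Symmetric integer matrix with strain dimnames.
#' @export
pairwise_overlaps <- function(presence) {
  P <- presence_as_matrix(presence)
  O <- crossprod(P)
  storage.mode(O) <- "integer"
  O
}

#' @export
print.cgh_pangenome <- function(x, ...) {
  cat("<cgh_pangenome> ", x$n_genes, " kept probes\n",
      "  core: ", length(x$core_genes),
      "  variable: ", length(x$variable_genes),
      "  reference-specific: ", length(x$reference_specific), "\n",
      "  core scope: ", paste(x$scope, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' One-row summary of a pan-genome partition
#'
#' @param x A `cgh_pangenome`.
#' @param ... Unused.
#' @method glance cgh_pangenome
#' @export
glance.cgh_pangenome <- function(x, ...) {
  d <- x$dissimilarity[x$dissimilarity$strain != x$reference, ]
  tibble(n_genes = x$n_genes, n_core = length(x$core_genes),
         n_variable = length(x$variable_genes),
         n_reference_specific = length(x$reference_specific),
         min_dissimilarity_pct = min(d$dissimilarity_pct),
         max_dissimilarity_pct = max(d$dissimilarity_pct))
}

#' Per-strain tidy view of a pan-genome partition
#'
#' @param x A `cgh_pangenome`.
#' @param ... Unused.
#' @return Tibble `strain`, `n_present`, `dissimilarity_pct`, `identity_pct`.
#' @method tidy cgh_pangenome
#' @export
tidy.cgh_pangenome <- function(x, ...) {
  dplyr::left_join(
    tibble(strain = names(x$present_counts),
           n_present = unname(x$present_counts)),
    x$dissimilarity[, c("strain", "dissimilarity_pct", "identity_pct")],
    by = "strain")
}

#' Bar chart of per-strain present counts and dissimilarities
#'
#' @param object A `cgh_pangenome`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cgh_pangenome
#' @export
autoplot.cgh_pangenome <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$strain,
                                                       .data$dissimilarity_pct),
                                    y = .data$dissimilarity_pct)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "gene-content dissimilarity vs reference (%)")
}
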