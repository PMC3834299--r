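#' Binary gene-content distance between strains
#'
#' From the presence/absence matrix (ones for genes present with EPP above the
#' cutoff, zeros otherwise), computes the pairwise mismatch proportion
#' (Hamming, the default) or the Jaccard distance.
#'
#' @param presence A `cgh_presence` or 0/1 genes-x-strains matrix.
#' @param metric `"hamming"` (mismatch proportion over all kept probes) or
#'   `"jaccard"` (1 - intersection/union over genes present in either).
#' @return Symmetric numeric matrix with zero diagonal, class `cgh_distance`.
#' @export
binary_distance <- function(presence, metric = c("hamming", "jaccard")) {
  metric <- match.arg(metric)
  P <- presence_as_matrix(presence)
  G <- nrow(P)
  if (G == 0) abort("No genes in the presence matrix.")
  O <- crossprod(P)                       # shared presences
  n_present <- diag(O)
  if (metric == "hamming") {
    # mismatches = present in exactly one of the two strains
    D <- (outer(n_present, n_present, "+") - 2 * O) / G
  } else {
    union <- outer(n_present, n_present, "+") - O
    D <- ifelse(union > 0, 1 - O / union, 0)
  }
  diag(D) <- 0
  structure(D, class = c("cgh_distance", class(D)), metric = metric)
}

validate_distance <- function(D) {
  D <- unclass(D)
  attr(D, "metric") <- NULL
  if (!is.matrix(D) || nrow(D) != ncol(D))
    abort("Distance matrix must be square.")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    abort("Distance matrix must be symmetric.")
  if (any(!is.finite(D))) abort("Distance matrix entries must be finite.")
  if (any(D < 0)) abort("Distance matrix entries must be non-negative.")
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classical agglomeration: at each step the pair minimizing
#' `Q(i, j) = (n - 2) D(i, j) - R_i - R_j` (with `R` the row sums) is joined;
#' ties are broken by lexicographic order of the sorted label pair. Branch
#' lengths follow the standard formulas; negative estimates are clamped to
#' zero with a warning. For an additive distance matrix the tree's path
#' lengths reproduce the input exactly.
#'
#' @param D Symmetric distance matrix with labelled rows/columns, `n >= 3`.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- validate_distance(D)
  n <- nrow(D)
  if (n < 3) abort("Neighbour joining needs at least three taxa.")
  labels <- rownames(D)
  # tip names may contain Newick metacharacters; build the tree over safe
  # tokens ordered like the labels (so the lexicographic tie-break on labels
  # is preserved) and restore the names afterwards
  tokens <- sprintf("x%06d", rank(labels, ties.method = "first"))
  rownames(D) <- colnames(D) <- tokens
  # working newick fragments per active cluster
  frag <- setNames(tokens, tokens)
  clamped <- FALSE
  fmt <- function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE)
  while (nrow(D) > 3) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    hits <- which(Q <= min(Q) + 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    pair_labels <- cbind(rownames(D)[hits[, 1]], rownames(D)[hits[, 2]])
    pair_key <- apply(pair_labels, 1, function(p) paste(sort(p), collapse = "\r"))
    pick <- order(pair_key)[1]
    i <- hits[pick, 1]; j <- hits[pick, 2]
    d_ij <- D[i, j]
    v_i <- d_ij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    v_j <- d_ij - v_i
    if (v_i < 0 || v_j < 0) clamped <- TRUE
    v_i <- max(v_i, 0); v_j <- max(v_j, 0)
    li <- rownames(D)[i]; lj <- rownames(D)[j]
    new_lab <- paste0("(", frag[li], ":", fmt(v_i), ",",
                      frag[lj], ":", fmt(v_j), ")")
    d_new <- (D[i, ] + D[j, ] - d_ij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], d_new[keep]),
                c(d_new[keep], 0))
    key <- paste0("c", m)
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], key)
    frag <- c(frag[rownames(D)[keep]], setNames(new_lab, key))
    D <- D2
  }
  a <- rownames(D)[1]; b <- rownames(D)[2]; c_ <- rownames(D)[3]
  v_a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v_b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v_c <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (any(c(v_a, v_b, v_c) < 0)) clamped <- TRUE
  v <- pmax(c(v_a, v_b, v_c), 0)
  if (clamped)
    warn("Negative branch-length estimate(s) clamped to zero.")
  txt <- paste0("(", frag[a], ":", fmt(v[1]), ",", frag[b], ":", fmt(v[2]),
                ",", frag[c_], ":", fmt(v[3]), ");")
  tree <- ape::read.tree(text = txt)
  tree$tip.label <- labels[match(tree$tip.label, tokens)]
  tree
}

# Canonical bipartition strings of an unrooted tree: every internal edge
# splits the tips; each split is keyed by the sorted labels of the side not
# containing the alphabetically first tip.
tree_bipartitions <- function(tree) {
  labs <- tree$tip.label
  anchor <- sort(labs)[1]
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > length(labs) - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  keys
}

#' Bootstrap supports and majority-rule consensus over gene resampling
#'
#' Resamples the gene columns of the presence matrix with replacement `B`
#' times, recomputes the binary distance and the neighbour-joining tree for
#' each replicate, and counts bipartition frequencies. Returns both the
#' strict-majority (>50%) consensus with supports attached and the full-data
#' NJ tree with the same supports painted on its internal nodes.
#'
#' @param presence A `cgh_presence` or 0/1 matrix.
#' @param B Number of bootstrap replicates. Default 1000.
#' @param seed Integer seed making the resampling deterministic.
#' @param metric Distance metric, see [binary_distance()].
#' @return Object of class `cgh_support_tree`: `consensus` and `full_tree`
#'   (`phylo` with supports as percent node labels), the bipartition frequency
#'   table `bipartitions`, `B` and `seed`.
#' @export
bootstrap_consensus <- function(presence, B = 1000, seed = 1L,
                                metric = "hamming") {
  if (B < 1) abort("`B` must be at least 1.")
  P <- presence_as_matrix(presence)
  full <- neighbor_joining(binary_distance(P, metric = metric))
  set.seed(seed)
  G <- nrow(P)
  counts <- new.env(parent = emptyenv())
  trees <- vector("list", B)
  for (b in seq_len(B)) {
    Pb <- P[sample.int(G, G, replace = TRUE), , drop = FALSE]
    tr <- suppressWarnings(neighbor_joining(binary_distance(Pb, metric = metric)))
    trees[[b]] <- tr
    for (k in tree_bipartitions(tr)) {
      if (!is.na(k)) assign(k, (get0(k, envir = counts) %||% 0L) + 1L,
                            envir = counts)
    }
  }
  keys <- ls(counts)
  freq <- tibble(
    bipartition = keys,
    count = vapply(keys, function(k) get(k, envir = counts), integer(1)),
    support_pct = 100 * vapply(keys, function(k) get(k, envir = counts),
                               integer(1)) / B) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$bipartition)
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5, check.labels = TRUE)
  paint <- function(tree) {
    keys_t <- tree_bipartitions(tree)
    support <- vapply(keys_t, function(k) {
      if (is.na(k)) return(NA_real_)
      100 * (get0(k, envir = counts) %||% 0L) / B
    }, numeric(1))
    tree$node.label <- ifelse(is.na(support), "",
                              format(round(support, 1), trim = TRUE))
    tree
  }
  structure(list(consensus = paint(cons), full_tree = paint(full),
                 bipartitions = freq, B = B, seed = seed, metric = metric),
            class = "cgh_support_tree")
}

#' Support of one strain bipartition
#'
#' @param x A `cgh_support_tree`.
#' @param tips Character vector of strain names forming one side of the split.
#' @return Support in percent (0 if the split never occurred).
#' @export
bipartition_support <- function(x, tips) {
  labs <- x$full_tree$tip.label
  anchor <- sort(labs)[1]
  side <- if (anchor %in% tips) setdiff(labs, tips) else tips
  key <- paste(sort(side), collapse = "|")
  hit <- x$bipartitions$support_pct[x$bipartitions$bipartition == key]
  if (length(hit) == 0) 0 else unname(hit)
}

#' @export
print.cgh_support_tree <- function(x, ...) {
  cat("<cgh_support_tree> ", length(x$full_tree$tip.label), " strains, B = ",
      x$B, " replicates (", x$metric, " distance)\n", sep = "")
  cat("consensus:\n")
  print(x$consensus)
  invisible(x)
}

#' Bipartition table of a bootstrapped tree
#'
#' @param x A `cgh_support_tree`.
#' @param ... Unused.
#' @return Tibble `bipartition`, `count`, `support_pct`.
#' @method tidy cgh_support_tree
#' @export
tidy.cgh_support_tree <- function(x, ...) x$bipartitions

#' Plot the consensus dendrogram with bootstrap supports
#'
#' @param x A `cgh_support_tree`.
#' @param which `"consensus"` or `"full"`.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.cgh_support_tree <- function(x, which = c("consensus", "full"), ...) {
  which <- match.arg(which)
  tr <- if (which == "consensus") x$consensus else x$full_tree
  ape::plot.phylo(tr, type = "unrooted", ...)
  if (!is.null(tr$node.label)) ape::nodelabels(tr$node.label, frame = "none")
  invisible(x)
}
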