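# Small simulation scenarios shared across test files.

small_config <- function(seed = 1, ...) {
  simulation_config(n_strains = 6, n_outgroups = 1, n_genes = 400,
                    core_fraction = 0.6, n_reference_specific = 5,
                    n_trait_genes = 5, seed = seed, ...)
}

# presence matrix with two perfectly separated 4-strain clades:
# 100 genes lost exclusively in each clade plus a shared backbone
two_clade_presence <- function(n_core = 300, n_marker = 100) {
  strains <- c(paste0("A", 1:4), paste0("B", 1:4))
  P <- matrix(1L, nrow = n_core + 2 * n_marker, ncol = 8,
              dimnames = list(sprintf("g%04d", seq_len(n_core + 2 * n_marker)),
                              strains))
  P[n_core + seq_len(n_marker), 5:8] <- 0L          # lost in clade B
  P[n_core + n_marker + seq_len(n_marker), 1:4] <- 0L  # lost in clade A
  P
}

# additive distance matrix from a random unrooted tree with positive lengths
random_additive_case <- function(n_taxa = 8, seed = 1) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.1, 2))
  tree$tip.label <- sort(tree$tip.label)[order(seq_len(n_taxa))]
  D <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(D))
  list(tree = tree, D = D[ord, ord])
}

# the reference trait-filter implementation: exhaustive per-gene evaluation
brute_force_hits <- function(P, a_strains, b_strains, max_fn, max_fp,
                             cap_sum = TRUE) {
  out <- character()
  for (g in rownames(P)) {
    fn <- sum(P[g, a_strains] == 0)
    fp <- sum(P[g, b_strains] == 1)
    ok <- fn <= max_fn && fp <= max_fp
    if (cap_sum) ok <- ok && (fn + fp) <= max(max_fn, max_fp)
    if (ok) out <- c(out, g)
  }
  out
}
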