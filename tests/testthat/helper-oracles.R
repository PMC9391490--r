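# Independent oracles used to check the package implementations.

# Generalized-least-squares ancestral states under Brownian motion, computed
# from explicit covariance matrices (no pruning): the ML root state is
# (1' V^-1 1)^-1 1' V^-1 x on the tip covariance V, and any node's state is
# the conditional mean a + C_k V^-1 (x - a), with C_k the covariance between
# node k and the tips (depth of their most recent common ancestor).
gls_ancestral_states <- function(tree, tip_values) {
  x <- as.numeric(tip_values[tree$tip.label])
  ntip <- length(tree$tip.label)
  V <- ape::vcv(tree)
  Vi <- solve(V)
  one <- rep(1, ntip)
  a <- as.numeric((t(one) %*% Vi %*% x) / (t(one) %*% Vi %*% one))
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)  # pairwise MRCA over tips and nodes
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  states <- vapply(nodes, function(k) {
    Ck <- depth[M[k, seq_len(ntip)]]
    a + as.numeric(Ck %*% Vi %*% (x - a * one))
  }, numeric(1))
  names(states) <- as.character(nodes)
  states
}

# Brute-force two-sided permutation p-value for the Pearson correlation of
# log10(mass) with rate at n = 4: explicit nested loops over all 24
# orderings, written independently of the package's permutation machinery.
brute_force_perm_p <- function(mass, rate) {
  stopifnot(length(mass) == 4L, length(rate) == 4L)
  x <- log10(mass)
  r_obs <- stats::cor(x, rate)
  hits <- 0L; total <- 0L
  for (i in 1:4) for (j in 1:4) for (k in 1:4) for (l in 1:4) {
    p <- c(i, j, k, l)
    if (length(unique(p)) != 4L) next
    total <- total + 1L
    if (abs(stats::cor(x, rate[p])) >= abs(r_obs) - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# A random rooted tree with strictly positive branch lengths.
random_test_tree <- function(ntip, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntip)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

# Fixture-derived family for a taxon with published functional/replacement
# counts (direct method rows only).
fixture_direct_family <- function(fixture, taxon) {
  row <- fixture[fixture$taxon == taxon & fixture$method == "direct" &
                   !is.na(fixture$functional_lines), ][1L, ]
  f <- tooth_record(row$taxon, row$specimen, age_days = row$functional_lines)
  r <- tooth_record(row$taxon, row$specimen, age_days = row$replacement_lines)
  tooth_family(f, list(r))
}
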