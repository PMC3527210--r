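# Independent oracles used across the suite.

t4 <- fixture_tree()
t4_ead <- compute_ead(t4)

# Exhaustive enumeration over all 2^N tip-inclusion outcomes of a small
# tree under independent per-tip Bernoulli sampling.  Returns the induced
# PD of every subset plus the inclusion pattern, so moments for many p
# can be formed from one enumeration.
exhaustive_pd_table <- function(tree) {
  tips <- tree$tip.label
  N <- length(tips)
  stopifnot(N <= 12)
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), N)))
  pd <- apply(patterns, 1L, function(inc) induced_pd(tree, tips[inc]))
  list(patterns = patterns, pd = pd, N = N)
}

# mean and variance of sampled PD at per-tip probability p, from the table
exhaustive_pd_moments <- function(tab, p) {
  k <- rowSums(tab$patterns)
  pr <- p^k * (1 - p)^(tab$N - k)
  m <- sum(pr * tab$pd)
  c(mean = m, var = sum(pr * (tab$pd - m)^2))
}

# Quadratic-time variance oracle from first principles: explicit pairwise
# covariances derived by inclusion-exclusion on each pair's descendant
# tip-set union, P(I_a = I_b = 1) = 1 - q(n_a) - q(n_b) + q(n_union),
# where q is the scheme's absence probability (gamma-mixture closed form
# for negbinom).  Independent of the accumulation shortcut in
# variance_pd().
pairwise_variance_oracle <- function(tree, scheme) {
  q <- function(n) {
    p <- scheme$p
    switch(scheme$family,
      binomial = (1 - p)^n,
      poisson = exp(-p * n),
      negbinom = (1 + scheme$eps * p * n)^(-1 / scheme$eps)
    )
  }
  ntip <- ape::Ntip(tree)
  nedge <- nrow(tree$edge)
  # descendant tip sets per edge (root pseudo-edge last)
  desc <- vector("list", nedge + 1L)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- c(as.list(seq_len(ntip)), vector("list", tree$Nnode))
  for (i in seq_len(nrow(po$edge))) {
    pa <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    sets[[pa]] <- c(sets[[pa]], sets[[ch]])
  }
  for (e in seq_len(nedge)) desc[[e]] <- sets[[tree$edge[e, 2L]]]
  desc[[nedge + 1L]] <- seq_len(ntip)
  lens <- c(tree$edge.length, if (is.null(tree$root.edge)) 0 else tree$root.edge)
  nE <- nedge + 1L
  P <- 1 - q(lengths(desc))
  v <- sum(lens^2 * P * (1 - P))
  for (a in seq_len(nE - 1L)) {
    for (b in (a + 1L):nE) {
      n_union <- length(union(desc[[a]], desc[[b]]))
      joint <- 1 - q(length(desc[[a]])) - q(length(desc[[b]])) + q(n_union)
      v <- v + 2 * lens[a] * lens[b] * (joint - P[a] * P[b])
    }
  }
  v
}

# random small tree for enumeration tests
small_random_tree <- function(seed) {
  n <- 3L + (seed %% 6L) # 3..8 tips
  yule_tree(n, seed = seed)
}
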