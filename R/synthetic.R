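#' Four-tip fixture tree
#'
#' The package's worked example: `((A:1,B:2):2,(C:1,D:1):1);`, four
#' individuals, total branch length 8, EAD `{1: 5, 2: 3, 4: 0}`.  Its
#' internal edge of length 2 with two descendant tips contributes exactly
#' 2 to `L(2)`, making every closed form checkable by hand.
#'
#' @return A validated `phylo` with 4 tips.
#' @examples
#' compute_ead(fixture_tree())
#' @export
fixture_tree <- function() {
  parse_newick("((A:1.0,B:2.0):2.0,(C:1.0,D:1.0):1.0);")
}

#' Simulate a Yule (pure-birth) tree with exponential branch lengths
#'
#' Standard neutral topology generator for property tests: a pure-birth
#' topology from [ape::rphylo()] with every branch length redrawn i.i.d.
#' exponential with mean `length_scale`.
#'
#' @param n_tips Number of tips, >= 2.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param length_scale Mean branch length, > 0.
#' @return A validated `phylo`.
#' @examples
#' yule_tree(10, seed = 1)
#' @export
yule_tree <- function(n_tips, seed = NULL, length_scale = 1) {
  if (n_tips < 2 || n_tips != round(n_tips)) abort("n_tips must be an integer >= 2")
  if (length_scale <= 0) abort("length_scale must be positive")
  if (!is.null(seed)) withr::local_seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$edge.length <- rexp(nrow(tr$edge), rate = 1 / length_scale)
  validate_tree(tr)
}

#' Simulate a random tree whose EAD is an exact power law
#'
#' Builds a random binary topology by uniform coalescent-style merges,
#' then assigns each edge of abundance class `n` the length
#' `scale * n^(-exponent) / (number of edges in class n)`, so the tree's
#' EAD equals `L(n) = scale * n^(-exponent)` exactly on every occupied
#' class.  The root edge is the sole member of class `n_tips` and gets
#' `scale * n_tips^(-exponent)`.  Classes no edge happens to occupy are
#' simply absent from the EAD (not an error); on random topologies most
#' large classes below `n_tips` are unoccupied, which is exactly the
#' occupancy pattern [fit_power_law()]'s default normalization corrects
#' for.
#'
#' @param n_tips Number of tips, >= 4.
#' @param exponent Target power-law exponent, > 0.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param scale Overall EAD scale, > 0.
#' @return A validated `phylo` with `root.edge` set.
#' @examples
#' tr <- powerlaw_tree(64, exponent = 1, seed = 7)
#' head(compute_ead(tr))
#' @export
powerlaw_tree <- function(n_tips, exponent, seed = NULL, scale = 1) {
  if (n_tips < 4 || n_tips != round(n_tips)) abort("n_tips must be an integer >= 4")
  if (exponent <= 0) abort("exponent must be positive")
  if (scale <= 0) abort("scale must be positive")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- as.integer(n_tips)
  active_id <- seq_len(n)
  active_size <- rep(1L, n)
  edge <- matrix(0L, nrow = 2L * (n - 1L), ncol = 2L)
  child_size <- integer(2L * (n - 1L))
  row <- 0L
  for (k in seq_len(n - 1L)) {
    pick <- sample.int(length(active_id), 2L)
    new_id <- 2L * n - k # last merge (k = n-1) becomes the root, id n+1
    for (j in pick) {
      row <- row + 1L
      edge[row, ] <- c(new_id, active_id[j])
      child_size[row] <- active_size[j]
    }
    new_size <- sum(active_size[pick])
    active_id <- c(active_id[-pick], new_id)
    active_size <- c(active_size[-pick], new_size)
  }
  class_count <- table(child_size)
  lens <- scale * child_size^(-exponent) /
    as.numeric(class_count[as.character(child_size)])
  tr <- structure(
    list(
      edge = edge,
      edge.length = lens,
      Nnode = n - 1L,
      tip.label = paste0("t", seq_len(n)),
      root.edge = scale * n^(-exponent)
    ),
    class = "phylo"
  )
  tr <- ape::reorder.phylo(tr, "cladewise")
  validate_tree(tr)
}
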