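#' Expected shared and total branch length of two independent samples
#'
#' For two local communities drawn independently from the same
#' metacommunity, an edge of abundance class `n` is present in both
#' samples with probability `P_A(n) * P_B(n)` and in at least one with
#' probability `1 - (1 - P_A(n)) (1 - P_B(n))`, so
#' `E(shared) = sum_n L(n) P_A(n) P_B(n)` and
#' `E(union) = sum_n L(n) (1 - (1-P_A(n))(1-P_B(n)))`.
#'
#' @param ead An `ead` tibble of the metacommunity.
#' @param scheme_a,scheme_b [sampling_scheme()]s for the two samples.
#' @return Expected branch length.
#' @examples
#' ead <- compute_ead(fixture_tree())
#' s <- sampling_scheme("binomial", 0.5)
#' expected_shared(ead, s, s) # 2.9375
#' expected_union(ead, s, s)  # 6.5625
#' @export
expected_shared <- function(ead, scheme_a, scheme_b) {
  pa <- presence_probability(scheme_a, ead$n)
  pb <- presence_probability(scheme_b, ead$n)
  sum(ead$edge_length * pa * pb)
}

#' @rdname expected_shared
#' @export
expected_union <- function(ead, scheme_a, scheme_b) {
  pa <- presence_probability(scheme_a, ead$n)
  pb <- presence_probability(scheme_b, ead$n)
  sum(ead$edge_length * (1 - (1 - pa) * (1 - pb)))
}

#' Expected UniFrac distance between two random samples
#'
#' Unweighted UniFrac as a function of the two sampling intensities:
#' `1 - E(shared) / E(union)`, the ratio of expectations.  (The
#' expectation of the per-pair ratio differs slightly; [mc_beta()]
#' reports both so the bias of this definition can be measured.)  This is
#' the reference value against which an observed UniFrac between
#' unequally sized samples can be normalized ([normalize_unifrac()]),
#' instead of rarefying both communities down to the smaller size.
#'
#' @inheritParams expected_shared
#' @return Expected UniFrac in `[0, 1]`.
#' @export
expected_unifrac <- function(ead, scheme_a, scheme_b) {
  u <- expected_union(ead, scheme_a, scheme_b)
  if (u <= 0) abort("expected union branch length is zero; UniFrac undefined")
  1 - expected_shared(ead, scheme_a, scheme_b) / u
}

#' Observed shared/union branch length and UniFrac of two tip sets
#'
#' An edge belongs to a sample when at least one of its descendant tips
#' does (rooted convention, as in [induced_pd()]); `shared` sums edges in
#' both samples, `union` edges in either, and UniFrac is
#' `(union - shared) / union`.  Identical samples score 0; samples whose
#' subtrees share no branch length score 1.
#'
#' @param tree A validated `phylo`.
#' @param tips_a,tips_b Non-empty character vectors of tip labels.
#' @return `observed_beta()`: a one-row tibble with `shared`, `union`,
#'   `unifrac`; `observed_unifrac()`: the UniFrac score alone.
#' @examples
#' observed_unifrac(fixture_tree(), c("A", "B"), c("C", "D")) # 1
#' observed_unifrac(fixture_tree(), c("A"), c("A", "B"))      # 0.4
#' @export
observed_beta <- function(tree, tips_a, tips_b) {
  if (length(tips_a) == 0L || length(tips_b) == 0L) {
    abort("both tip sets must be non-empty")
  }
  pa <- edge_presence(tree, match_tips(tree, tips_a, "tips_a"))
  pb <- edge_presence(tree, match_tips(tree, tips_b, "tips_b"))
  lens <- c(tree$edge.length, root_edge_length(tree))
  shared <- sum(lens[pa & pb])
  un <- sum(lens[pa | pb])
  if (un <= 0) abort("union branch length is zero; UniFrac undefined")
  tibble(shared = shared, union = un, unifrac = (un - shared) / un)
}

#' @rdname observed_beta
#' @export
observed_unifrac <- function(tree, tips_a, tips_b) {
  observed_beta(tree, tips_a, tips_b)$unifrac
}

#' Normalize an observed UniFrac by its random-sampling expectation
#'
#' Divides an observed UniFrac distance by the expected UniFrac of two
#' random samples of the same sizes from the same metacommunity
#' ([expected_unifrac()] with intensities matched via
#' [solve_intensity()]).  Values below 1 mean the two communities are
#' more similar than equally sized random samples would be.
#'
#' @param observed Observed UniFrac in `[0, 1]`.
#' @param expected Expected UniFrac under matched random sampling, > 0.
#' @return The dimensionless ratio `observed / expected`.
#' @export
normalize_unifrac <- function(observed, expected) {
  if (any(expected <= 0)) abort("expected UniFrac must be positive to normalize")
  observed / expected
}

#' Average-linkage clustering of a UniFrac distance matrix
#'
#' Deterministic agglomerative (UPGMA) clustering: labels are sorted
#' lexicographically before linkage so equal-distance merges always
#' resolve to the smallest label pair first.
#'
#' @param mat Square symmetric numeric matrix with zero diagonal and
#'   row/column names.
#' @return An `hclust` object; convert to newick with
#'   [dendrogram_newick()].
#' @export
cluster_distances <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) abort("distance matrix must be square")
  if (is.null(rownames(mat))) abort("distance matrix needs labels")
  if (any(!is.finite(mat))) abort("distance matrix contains non-finite values")
  if (!isSymmetric(unname(mat))) abort("distance matrix must be symmetric")
  if (any(abs(diag(mat)) > 1e-12)) abort("distance matrix diagonal must be zero")
  ord <- order(rownames(mat))
  hclust(as.dist(mat[ord, ord]), method = "average")
}

#' @rdname cluster_distances
#' @param hc An `hclust` object.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Pairwise observed (and optionally normalized) UniFrac for many samples
#'
#' Computes every pairwise unweighted UniFrac distance among the samples
#' of a membership table.  With `normalize = TRUE` each pair also gets the
#' expected UniFrac of two random samples of matched sizes (binomial
#' intensities fitted by [solve_intensity()]) and the ratio
#' observed/expected.
#'
#' @param tree A validated `phylo` (the metacommunity).
#' @param membership Tibble with columns `sample`, `tip`
#'   (see [read_membership()]).
#' @param normalize Also compute expected and normalized UniFrac?
#' @param family Scheme family used for the expectation.
#' @param eps Clustering parameter for negbinom expectations.
#' @return A tibble with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `observed`, and when normalizing `expected`,
#'   `normalized`.
#' @export
unifrac_matrix <- function(tree, membership, normalize = FALSE,
                           family = "binomial", eps = NULL) {
  sets <- split(membership$tip, membership$sample)
  ids <- names(sets)
  if (length(ids) < 2L) abort("need at least two samples")
  ead <- if (normalize) compute_ead(tree) else NULL
  N <- ape::Ntip(tree)
  pairs <- utils::combn(ids, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    obs <- observed_unifrac(tree, sets[[a]], sets[[b]])
    row <- tibble(sample_a = a, sample_b = b, observed = obs)
    if (normalize) {
      sa <- solve_intensity(family, N, length(unique(sets[[a]])), eps = eps)
      sb <- solve_intensity(family, N, length(unique(sets[[b]])), eps = eps)
      exp_uf <- expected_unifrac(ead, sa, sb)
      row$expected <- exp_uf
      row$normalized <- normalize_unifrac(obs, exp_uf)
    }
    row
  })
}
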