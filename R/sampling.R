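#' Define a sampling scheme for local-community assembly
#'
#' A sampling scheme describes how a local community is drawn from the
#' metacommunity, through the probability `P(n)` that a clade with `n`
#' tips contributes at least one individual to the sample:
#' \describe{
#'   \item{binomial}{every individual appears independently with
#'     probability `p` (sampling without replacement);
#'     `P(n) = 1 - (1 - p)^n`.}
#'   \item{poisson}{each tip is sampled a Poisson(`p`) number of times
#'     (sampling with replacement, `p` = per-tip mean count);
#'     `P(n) = 1 - exp(-p * n)`.}
#'   \item{negbinom}{Poisson sampling whose intensity is modulated by one
#'     community-wide gamma factor with mean 1 and variance `eps`;
#'     `P(n) = 1 - (1 + eps * p * n)^(-1/eps)`.  `eps > 0` gives clustered
#'     sampling (nearby tips co-occur), `eps < 0` overdispersed sampling
#'     (valid only while `1 + eps * p * n > 0`), and `eps -> 0` recovers
#'     the Poisson scheme.}
#' }
#'
#' @param family `"binomial"`, `"poisson"`, or `"negbinom"`.
#' @param p Intensity: per-individual probability (binomial, in `[0, 1]`)
#'   or per-tip mean count (poisson/negbinom, `>= 0`).
#' @param eps Clustering parameter (negbinom only), non-zero.
#' @return A `sampling_scheme` object.
#' @examples
#' sampling_scheme("binomial", 0.5)
#' sampling_scheme("negbinom", 0.1, eps = 0.5)
#' @export
sampling_scheme <- function(family = c("binomial", "poisson", "negbinom"),
                            p, eps = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p))
  if (p < 0) abort("intensity p must be non-negative")
  if (family == "binomial" && p > 1) abort("binomial intensity p must be in [0, 1]")
  if (family == "negbinom") {
    if (is.null(eps)) abort("negbinom scheme needs a clustering parameter eps")
    stopifnot(is.numeric(eps), length(eps) == 1L, is.finite(eps))
    if (eps == 0) family <- "poisson"
  }
  structure(
    list(family = family, p = p, eps = if (family == "negbinom") eps else NULL),
    class = "sampling_scheme"
  )
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(format_scheme(x), "\n")
  invisible(x)
}

format_scheme <- function(scheme) {
  if (scheme$family == "negbinom") {
    sprintf("negbinom:p=%g,eps=%g", scheme$p, scheme$eps)
  } else {
    sprintf("%s:p=%g", scheme$family, scheme$p)
  }
}

#' Parse a scheme specification string
#'
#' Accepts the flat `family:key=value[,key=value]` format used on the
#' command line, e.g. `"binomial:p=0.5"` or `"negbinom:p=0.1,eps=0.5"`.
#'
#' @param text Specification string.
#' @return A `sampling_scheme`.
#' @export
parse_scheme <- function(text) {
  parts <- strsplit(trimws(text), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) abort(paste0("cannot parse scheme string: ", text))
  kv <- strsplit(strsplit(parts[2], ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- vapply(kv, function(x) as.numeric(x[2]), numeric(1))
  names(vals) <- vapply(kv, `[`, character(1), 1L)
  if (!"p" %in% names(vals)) abort("scheme string must set p")
  sampling_scheme(parts[1], p = vals[["p"]],
                  eps = if ("eps" %in% names(vals)) vals[["eps"]] else NULL)
}

#' Probability that a clade of n tips is represented in the sample
#'
#' The scheme-dependent presence probability `P(n)`: the chance that an
#' edge with `n` descendant tips appears in the sampled tree.  Evaluated
#' with `log1p`/`expm1` transforms so extreme intensities and abundances
#' stay accurate.
#'
#' @param scheme A [sampling_scheme()].
#' @param n Abundance class(es), positive; vectorized.
#' @return Probabilities in `[0, 1]`, same length as `n`.
#' @examples
#' presence_probability(sampling_scheme("binomial", 0.5), 2) # 0.75
#' @export
presence_probability <- function(scheme, n) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  if (any(n < 1)) abort("abundance class n must be >= 1")
  p <- scheme$p
  switch(scheme$family,
    binomial = if (p == 1) rep(1, length(n)) else -expm1(n * log1p(-p)),
    poisson = -expm1(-p * n),
    negbinom = {
      eps <- scheme$eps
      x <- eps * p * n
      if (any(1 + x <= 0)) {
        bad <- n[1 + x <= 0]
        abort(sprintf(
          "negbinom domain error: 1 + eps*p*n <= 0 for n = %s",
          paste(utils::head(bad, 5L), collapse = ", ")
        ))
      }
      -expm1(-log1p(x) / eps)
    }
  )
}

# survival probability 1 - P(n), kept separate for the covariance algebra
absence_probability <- function(scheme, n) {
  p <- scheme$p
  switch(scheme$family,
    binomial = if (p == 1) as.numeric(n == 0) else exp(n * log1p(-p)),
    poisson = exp(-p * n),
    negbinom = {
      x <- scheme$eps * p * n
      if (any(1 + x <= 0)) abort("negbinom domain error: 1 + eps*p*n <= 0")
      exp(-log1p(x) / scheme$eps)
    }
  )
}

#' Expected phylogenetic diversity of a sampled local community
#'
#' The closed-form replacement for randomization nulls: summing each
#' abundance class's branch length, weighted by the probability that the
#' class is represented,
#' `E(PD) = sum_n L(n) * P(n)`.
#' Only the EAD of the metacommunity tree is needed, so the cost is
#' independent of how many sample sizes or schemes are evaluated.
#'
#' @param ead An `ead` tibble ([compute_ead()] or [power_law_ead()]).
#' @param scheme A [sampling_scheme()].
#' @return Expected PD (branch-length units).
#' @examples
#' expected_pd(compute_ead(fixture_tree()), sampling_scheme("binomial", 0.5)) # 4.75
#' @export
expected_pd <- function(ead, scheme) {
  sum(ead$edge_length * presence_probability(scheme, ead$n))
}

#' Expected number of distinct tips in the sample
#'
#' Each of the `N` pendant edges is present exactly when its tip is
#' sampled, so the expected number of distinct tips is `N * P(1)`.
#'
#' @param scheme A [sampling_scheme()].
#' @param N Metacommunity tip count.
#' @return Expected distinct-tip count in `[0, N]`.
#' @export
expected_tips <- function(scheme, N) {
  stopifnot(N >= 1)
  N * presence_probability(scheme, 1)
}

#' Solve for the intensity matching an observed sample size
#'
#' Inverts [expected_tips()]: given a scheme family (and `eps` for
#' negbinom) and an observed number of distinct tips `target_tips`,
#' returns the scheme whose expected distinct-tip count equals it.  All
#' three families invert in closed form:
#' binomial `p = T/N`; poisson `p = -log(1 - T/N)`;
#' negbinom `p = ((1 - T/N)^(-eps) - 1)/eps`.
#' This is how an observed community is placed on a theory curve: sample
#' size is matched through expected distinct tips, the one quantity both
#' observable and analytic in every family.
#'
#' @param family Scheme family.
#' @param N Metacommunity tip count.
#' @param target_tips Observed number of distinct tips, in `[0, N]`
#'   (strictly below `N` for poisson/negbinom, which cannot make presence
#'   certain at finite intensity).
#' @param eps Clustering parameter for negbinom.
#' @return A [sampling_scheme()].
#' @examples
#' solve_intensity("binomial", N = 4, target_tips = 2) # p = 0.5
#' @export
solve_intensity <- function(family = c("binomial", "poisson", "negbinom"),
                            N, target_tips, eps = NULL) {
  family <- match.arg(family)
  if (target_tips < 0 || target_tips > N) {
    abort(sprintf("target_tips = %g outside [0, %g]", target_tips, N))
  }
  frac <- target_tips / N
  if (frac == 1 && family != "binomial") {
    abort(paste0(family, " sampling cannot reach a full sample at finite intensity"))
  }
  p <- switch(family,
    binomial = frac,
    poisson = -log1p(-frac),
    negbinom = {
      if (is.null(eps)) abort("negbinom scheme needs eps")
      if (eps == 0) -log1p(-frac) else {
        val <- expm1(-eps * log1p(-frac)) / eps
        if (!is.finite(val) || val < 0) {
          abort(sprintf("target_tips = %g unattainable under eps = %g", target_tips, eps))
        }
        val
      }
    }
  )
  sampling_scheme(family, p = p, eps = eps)
}

#' Variance of sampled phylogenetic diversity
#'
#' Writing PD of the sample as `sum_e l_e I_e` over edge-presence
#' indicators,
#' `Var(PD) = sum_e l_e^2 P_e (1-P_e) + 2 sum_{a<d} l_a l_d Cov(I_a, I_d)`.
#' Descendant presence implies ancestor presence, so for a nested pair
#' (ancestor `a`, descendant `d`) `Cov = P_d (1 - P_a)` in every family.
#' Under binomial and Poisson sampling tips are independent and
#' branch-disjoint edges are uncorrelated; under negative-binomial
#' sampling the shared gamma factor correlates *all* edges, and disjoint
#' pairs contribute `Cov = q(n_a + n_d) - q(n_a) q(n_d)` with
#' `q(n) = (1 + eps*p*n)^(-1/eps)`.  Nested covariances are accumulated
#' in one post-order pass; the negbinom disjoint term is aggregated by
#' abundance class, so no quadratic pairwise loop over edges of large
#' trees is needed for the dominant part.
#'
#' @param tree A validated `phylo` (the variance depends on the tree's
#'   nesting structure, not only on its EAD).
#' @param scheme A [sampling_scheme()].
#' @param weights Optional tip weights (see [tip_counts()]).
#' @return `Var(PD)` in squared branch-length units (non-negative).
#' @examples
#' variance_pd(fixture_tree(), sampling_scheme("binomial", 0.5)) # 4.6875
#' @export
variance_pd <- function(tree, scheme, weights = NULL) {
  et <- edge_table(tree, weights)
  P <- presence_probability(scheme, et$n)
  l <- et$length
  v <- sum(l^2 * P * (1 - P))

  # nested pairs: for each edge a, sum over strict descendants d of l_d P_d.
  # A[node] = sum of l_e P_e over edges inside the subtree rooted at node.
  nnode <- ape::Ntip(tree) + tree$Nnode
  A <- numeric(nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  lp <- setNames(l[seq_len(nrow(et) - 1L)] * P[seq_len(nrow(et) - 1L)], NULL)
  # map edge rows of `tree` (same order as et rows 1..E) for postorder walk
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  po_key <- paste(po$edge[, 1], po$edge[, 2])
  po_row <- match(po_key, key)
  for (i in seq_along(po_row)) {
    e <- po_row[i]
    ch <- tree$edge[e, 2L]
    pa <- tree$edge[e, 1L]
    A[pa] <- A[pa] + A[ch] + lp[e]
  }
  nested <- sum(l * (1 - P) * A[et$child])
  v <- v + 2 * nested

  if (scheme$family == "negbinom") {
    eps <- scheme$eps
    p <- scheme$p
    # clamped absence probability: for eps < 0 the base 1 + eps*p*n can
    # reach 0 at large n (absence impossible), where q continues to 0.
    # Class-pair sums above N only ever arise for nested pairs, whose f
    # contributions cancel exactly between all_pairs and nested_f below.
    q <- function(n) {
      x <- eps * p * n
      out <- numeric(length(x))
      ok <- 1 + x > 0
      out[ok] <- exp(-log1p(x[ok]) / eps)
      out
    }
    f <- function(na, nb) q(na + nb) - q(na) * q(nb)
    # all unordered distinct-edge pairs, aggregated by abundance class
    cls <- sort(unique(et$n))
    Lc <- vapply(cls, function(nn) sum(l[et$n == nn]), numeric(1))
    S2 <- vapply(cls, function(nn) sum(l[et$n == nn]^2), numeric(1))
    Fm <- outer(cls, cls, f)
    all_pairs <- 0.5 * (drop(Lc %*% Fm %*% Lc) - sum(S2 * diag(Fm)))
    # subtract the nested pairs (counted with f, then re-added with the
    # exact nested covariance above): walk each edge's ancestor chain
    parent_of <- integer(nnode)
    edge_above <- integer(nnode) # row in et of the edge above each node
    parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
    edge_above[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
    rt <- root_node(tree)
    parent_of[rt] <- 0L
    edge_above[rt] <- nrow(et) # the root pseudo-edge
    nested_f <- 0
    for (e in seq_len(nrow(et) - 1L)) { # root edge has no strict ancestor
      node <- et$parent[e]
      while (node != 0L) {
        a <- edge_above[node]
        nested_f <- nested_f + l[e] * l[a] * f(et$n[a], et$n[e])
        node <- parent_of[node]
      }
    }
    v <- v + 2 * (all_pairs - nested_f)
  }
  max(v, 0)
}

#' Analytic PD prediction for a scheme on a tree
#'
#' Convenience wrapper bundling [expected_pd()], [variance_pd()] and
#' [expected_tips()] into one tidy row.
#'
#' @inheritParams variance_pd
#' @return A one-row tibble with columns `family`, `intensity`, `eps`,
#'   `expected_pd`, `variance_pd`, `sd_pd`, `expected_tips`.
#' @examples
#' predict_pd(fixture_tree(), sampling_scheme("binomial", 0.5))
#' @export
predict_pd <- function(tree, scheme, weights = NULL) {
  ead <- compute_ead(tree, weights)
  v <- variance_pd(tree, scheme, weights)
  tibble(
    family = scheme$family,
    intensity = scheme$p,
    eps = scheme$eps %||% NA_real_,
    expected_pd = expected_pd(ead, scheme),
    variance_pd = v,
    sd_pd = sqrt(v),
    expected_tips = expected_tips(scheme, ead_total_tips(ead))
  )
}
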