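#' Draw one random local community from a metacommunity tree
#'
#' Generative counterpart of [presence_probability()]:
#' binomial — each tip independently with probability `p`;
#' poisson — a tip is present when its Poisson(`p`) count is positive;
#' negbinom (`eps > 0` only) — one gamma factor `g` with mean 1 and
#' variance `eps` is drawn per replicate and every tip's Poisson
#' intensity becomes `g * p`, which is what makes clustered samples
#' co-occur.  Overdispersed `eps < 0` has no such generative story and is
#' supported analytically only.
#'
#' Uses the current RNG state; seed via [withr::with_seed()] or the
#' `seed` arguments of [mc_pd()] / [mc_beta()].
#'
#' @param tree A validated `phylo`.
#' @param scheme A [sampling_scheme()].
#' @return Character vector of sampled tip labels (possibly empty).
#' @export
draw_sample <- function(tree, scheme) {
  inc <- draw_inclusion(scheme, ape::Ntip(tree), 1L)
  tree$tip.label[inc[1L, ]]
}

# reps x ntip logical inclusion matrix
draw_inclusion <- function(scheme, ntip, reps) {
  p <- scheme$p
  switch(scheme$family,
    binomial = matrix(runif(reps * ntip) < p, nrow = reps),
    poisson = matrix(rpois(reps * ntip, p) > 0, nrow = reps),
    negbinom = {
      eps <- scheme$eps
      if (eps <= 0) {
        abort("no generative sampler for negbinom with eps <= 0 (analytic only)")
      }
      g <- rgamma(reps, shape = 1 / eps, rate = 1 / eps)
      matrix(rpois(reps * ntip, rep(g, times = ntip) * p) > 0, nrow = reps)
    }
  )
}

# tips x edges incidence: M[t, e] = 1 if tip t descends through edge e
# (last column = root edge, hit by every tip)
edge_incidence <- function(tree) {
  ntip <- ape::Ntip(tree)
  nedge <- nrow(tree$edge)
  parent_of <- integer(ntip + tree$Nnode)
  edge_above <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_above[tree$edge[, 2L]] <- seq_len(nedge)
  rt <- root_node(tree)
  M <- matrix(0, nrow = ntip, ncol = nedge + 1L)
  for (t in seq_len(ntip)) {
    node <- t
    while (node != rt && node != 0L) {
      M[t, edge_above[node]] <- 1
      node <- parent_of[node]
    }
    M[t, nedge + 1L] <- 1
  }
  M
}

mc_new_summary <- function(pd, reps, tips, seed) {
  m4 <- mean((pd - mean(pd))^4)
  s2 <- var(pd)
  se_mean <- if (reps > 1L) sd(pd) / sqrt(reps) else {
    warn("reps = 1: standard errors undefined, reported as Inf")
    Inf
  }
  out <- tibble(
    reps = reps,
    mean_pd = mean(pd),
    sd_pd = if (reps > 1L) sd(pd) else NA_real_,
    se_mean = se_mean,
    var_pd = if (reps > 1L) s2 else NA_real_,
    se_var = if (reps > 1L) sqrt(max(m4 - s2^2, 0) / reps) else Inf,
    mean_tips = tips,
    seed = seed
  )
  class(out) <- c("mc_summary", class(out))
  out
}

#' Monte-Carlo null distribution of sampled PD
#'
#' The brute-force randomization null that the analytic theory replaces,
#' kept as the package's independent oracle: draws `reps` local
#' communities under `scheme` and summarizes the rooted PD of each.
#' Fully reproducible: identical `seed`, inputs and `reps` give
#' bit-identical summaries (the RNG state is restored afterwards).
#'
#' @param tree A validated `phylo`.
#' @param scheme A [sampling_scheme()] (negbinom requires `eps > 0`).
#' @param reps Number of replicates, >= 1.
#' @param seed Integer seed.
#' @return An `mc_summary` tibble: `reps`, `mean_pd`, `sd_pd`, `se_mean`,
#'   `var_pd`, `se_var` (moment-based standard error of the variance
#'   estimate), `mean_tips`, `seed`.
#' @examples
#' mc_pd(fixture_tree(), sampling_scheme("binomial", 0.5), reps = 200, seed = 1)
#' @export
mc_pd <- function(tree, scheme, reps, seed) {
  stopifnot(reps >= 1)
  withr::local_seed(seed)
  M <- edge_incidence(tree)
  lens <- c(tree$edge.length, root_edge_length(tree))
  pd <- numeric(reps)
  tips <- 0
  for (chunk in chunk_indices(reps, 5000L)) {
    inc <- draw_inclusion(scheme, nrow(M), length(chunk))
    pres <- (inc %*% M) > 0
    pd[chunk] <- as.numeric(pres %*% lens)
    tips <- tips + sum(inc)
  }
  mc_new_summary(pd, as.integer(reps), tips / reps, seed)
}

chunk_indices <- function(n, size) {
  split(seq_len(n), ceiling(seq_len(n) / size))
}

#' Monte-Carlo shared/union branch length for paired samples
#'
#' Per replicate, draws independent communities A and B and records their
#' shared and union (rooted) branch length; validates
#' [expected_shared()] / [expected_union()] and measures the bias of the
#' ratio-of-expectations UniFrac: `mean_unifrac` is the mean of
#' per-replicate UniFrac scores (pairs with empty union dropped), while
#' `unifrac_of_means` is `1 - mean_shared/mean_union`.
#'
#' @inheritParams mc_pd
#' @param scheme_a,scheme_b Schemes for the two samples.
#' @return An `mc_summary`-like tibble: `reps`, `mean_shared`,
#'   `se_shared`, `mean_union`, `se_union`, `mean_unifrac`,
#'   `unifrac_of_means`, `n_defined`, `seed`.
#' @export
mc_beta <- function(tree, scheme_a, scheme_b, reps, seed) {
  stopifnot(reps >= 1)
  withr::local_seed(seed)
  M <- edge_incidence(tree)
  lens <- c(tree$edge.length, root_edge_length(tree))
  shared <- numeric(reps)
  un <- numeric(reps)
  for (chunk in chunk_indices(reps, 5000L)) {
    pa <- (draw_inclusion(scheme_a, nrow(M), length(chunk)) %*% M) > 0
    pb <- (draw_inclusion(scheme_b, nrow(M), length(chunk)) %*% M) > 0
    shared[chunk] <- as.numeric((pa & pb) %*% lens)
    un[chunk] <- as.numeric((pa | pb) %*% lens)
  }
  ok <- un > 0
  uf <- (un[ok] - shared[ok]) / un[ok]
  out <- tibble(
    reps = as.integer(reps),
    mean_shared = mean(shared),
    se_shared = if (reps > 1L) sd(shared) / sqrt(reps) else Inf,
    mean_union = mean(un),
    se_union = if (reps > 1L) sd(un) / sqrt(reps) else Inf,
    mean_unifrac = if (length(uf)) mean(uf) else NA_real_,
    unifrac_of_means = if (mean(un) > 0) 1 - mean(shared) / mean(un) else NA_real_,
    n_defined = sum(ok),
    seed = seed
  )
  class(out) <- c("mc_summary", class(out))
  out
}
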