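#' Classify a local community against the random-sampling null
#'
#' Places an observed community on the analytic null distribution of PD:
#' the sampling intensity is fitted so the null's expected number of
#' distinct tips equals the observed tip count ([solve_intensity()]),
#' expected PD and its variance follow from the metacommunity EAD and
#' tree, and the community is labeled by where its observed (rooted) PD
#' falls relative to a two-sided confidence band:
#' `clustered` below the band (less branch length than random sampling,
#' the classic signature of environmental filtering), `overdispersed`
#' above it (more than random, conventionally competition), `random`
#' inside.
#'
#' @param tree The metacommunity tree (validated `phylo`).
#' @param tips Character vector of tip labels forming the local community.
#' @param family Null scheme family (`"binomial"`, `"poisson"`,
#'   `"negbinom"`).
#' @param eps Clustering parameter when `family = "negbinom"`.
#' @param alpha Two-sided tail probability of the band (default 0.05).
#' @param conf `"normal"` (mean ± z(1-alpha/2)·sd, default) or
#'   `"chebyshev"` (mean ± sd/sqrt(alpha)), a conservative
#'   distribution-free alternative.
#' @param ead Optional precomputed [compute_ead()] of `tree`, to avoid
#'   recomputation across many samples.
#' @param sample_id Optional label stored in the result.
#' @return A one-row tibble: `sample_id`, `observed_tips`, `observed_pd`,
#'   `family`, `fitted_intensity`, `expected_pd`, `sd_pd`, `z_score`,
#'   `ci_low`, `ci_high`, `label`.
#' @examples
#' tr <- yule_tree(50, seed = 1)
#' classify_sample(tr, sample(tr$tip.label, 10))
#' @export
classify_sample <- function(tree, tips, family = "binomial", eps = NULL,
                            alpha = 0.05, conf = c("normal", "chebyshev"),
                            ead = NULL, sample_id = NA_character_) {
  conf <- match.arg(conf)
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  tips <- unique(as.character(tips))
  match_tips(tree, tips)
  ead <- ead %||% compute_ead(tree)
  N <- ape::Ntip(tree)
  scheme <- solve_intensity(family, N, length(tips), eps = eps)
  epd <- expected_pd(ead, scheme)
  sdv <- sqrt(variance_pd(tree, scheme))
  obs <- induced_pd(tree, tips)
  zcrit <- switch(conf, normal = qnorm(1 - alpha / 2), chebyshev = 1 / sqrt(alpha))
  ci_low <- epd - zcrit * sdv
  ci_high <- epd + zcrit * sdv
  if (sdv == 0) {
    if (isTRUE(all.equal(obs, epd))) {
      z <- 0
    } else {
      warn("degenerate null (sd = 0) with observed != expected; labeling by sign")
      z <- sign(obs - epd) * Inf
    }
  } else {
    z <- (obs - epd) / sdv
  }
  label <- if (obs < ci_low) "clustered" else if (obs > ci_high) "overdispersed" else "random"
  tibble(
    sample_id = sample_id,
    observed_tips = length(tips),
    observed_pd = obs,
    family = family,
    fitted_intensity = scheme$p,
    expected_pd = epd,
    sd_pd = sdv,
    z_score = z,
    ci_low = ci_low,
    ci_high = ci_high,
    label = label
  )
}

#' @rdname classify_sample
#' @param membership Tibble with columns `sample` and `tip`
#'   ([read_membership()]); each sample is classified against the same
#'   metacommunity tree.
#' @export
classify_samples <- function(tree, membership, family = "binomial", eps = NULL,
                             alpha = 0.05, conf = c("normal", "chebyshev")) {
  conf <- match.arg(conf)
  ead <- compute_ead(tree)
  sets <- split(membership$tip, membership$sample)
  purrr::map_dfr(names(sets), function(id) {
    classify_sample(tree, sets[[id]], family = family, eps = eps,
                    alpha = alpha, conf = conf, ead = ead, sample_id = id)
  })
}

#' Expected-PD theory curve with confidence band
#'
#' For a grid of target sample sizes (expected distinct tips), fits the
#' intensity, and evaluates expected PD — and, when the input is a tree,
#' the variance-based confidence band.  A pure EAD (e.g.
#' [power_law_ead()]) carries no nesting structure, so no variance: the
#' band columns are then `NA`.
#'
#' @param x A validated `phylo` or an `ead` tibble.
#' @param grid Numeric vector of target distinct-tip counts in `(0, N]`.
#' @param family,eps,alpha,conf As in [classify_sample()].
#' @return A `pd_curve` tibble: `expected_tips`, `intensity`,
#'   `expected_pd`, `sd_pd`, `ci_low`, `ci_high`.
#' @examples
#' pd_curve(fixture_tree(), grid = c(2, 4))
#' @export
pd_curve <- function(x, grid, family = "binomial", eps = NULL,
                     alpha = 0.05, conf = c("normal", "chebyshev")) {
  conf <- match.arg(conf)
  is_tree <- inherits(x, "phylo")
  ead <- if (is_tree) compute_ead(x) else x
  N <- if (is_tree) ape::Ntip(x) else ead_total_tips(ead)
  if (any(grid <= 0) || any(grid > N)) {
    abort(sprintf("grid values must lie in (0, %g]", N))
  }
  zcrit <- switch(conf, normal = qnorm(1 - alpha / 2), chebyshev = 1 / sqrt(alpha))
  out <- purrr::map_dfr(grid, function(tt) {
    scheme <- solve_intensity(family, N, tt, eps = eps)
    epd <- expected_pd(ead, scheme)
    sdv <- if (is_tree) sqrt(variance_pd(x, scheme)) else NA_real_
    tibble(
      expected_tips = tt,
      intensity = scheme$p,
      expected_pd = epd,
      sd_pd = sdv,
      ci_low = epd - zcrit * sdv,
      ci_high = epd + zcrit * sdv
    )
  })
  class(out) <- c("pd_curve", class(out))
  out
}
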