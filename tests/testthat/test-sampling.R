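test_that("presence probabilities match their closed forms and limits", {
  expect_equal(presence_probability(sampling_scheme("binomial", 0.5), 2), 0.75)
  expect_equal(presence_probability(sampling_scheme("poisson", 0.1), 10),
               1 - exp(-1))
  expect_equal(presence_probability(sampling_scheme("binomial", 1), c(1, 5)), c(1, 1))
  expect_equal(presence_probability(sampling_scheme("binomial", 0), 7), 0)

  # negbinom converges to poisson as eps -> 0
  po <- sampling_scheme("poisson", 0.1)
  nb <- sampling_scheme("negbinom", 0.1, eps = 1e-8)
  for (n in c(1, 10, 1000)) {
    expect_equal(presence_probability(nb, n), presence_probability(po, n),
                 tolerance = 1e-6)
  }
  # clustered (eps > 0) lowers presence, overdispersed (eps < 0) raises it
  expect_lt(presence_probability(sampling_scheme("negbinom", 0.5, eps = 1), 4),
            presence_probability(po <- sampling_scheme("poisson", 0.5), 4))
  expect_gt(presence_probability(sampling_scheme("negbinom", 0.5, eps = -0.1), 4),
            presence_probability(po, 4))
  expect_error(
    presence_probability(sampling_scheme("negbinom", 1, eps = -0.5), 10),
    "domain"
  )
})

test_that("scheme construction and string parsing are validated", {
  expect_error(sampling_scheme("binomial", 1.2), "\\[0, 1\\]")
  expect_error(sampling_scheme("poisson", -1), "non-negative")
  expect_error(sampling_scheme("negbinom", 0.5), "eps")
  s <- parse_scheme("negbinom:p=0.1,eps=0.5")
  expect_equal(s$family, "negbinom")
  expect_equal(s$p, 0.1)
  expect_equal(s$eps, 0.5)
  expect_equal(parse_scheme("binomial:p=0.5")$family, "binomial")
  expect_error(parse_scheme("binomial"), "parse")
  # eps = 0 collapses to poisson
  expect_equal(sampling_scheme("negbinom", 0.3, eps = 0)$family, "poisson")
})

test_that("expected PD evaluates the EAD sum and honors its bounds", {
  expect_equal(expected_pd(t4_ead, sampling_scheme("binomial", 0.5)), 4.75)
  expect_equal(expected_pd(t4_ead, sampling_scheme("binomial", 1)), 8)
  for (fam in c("binomial", "poisson")) {
    expect_equal(expected_pd(t4_ead, sampling_scheme(fam, 0)), 0)
  }
  # monotone non-decreasing in p for every family
  grid <- seq(0.05, 0.95, by = 0.1)
  for (sc in list(
    lapply(grid, function(p) sampling_scheme("binomial", p)),
    lapply(grid, function(p) sampling_scheme("poisson", 2 * p)),
    lapply(grid, function(p) sampling_scheme("negbinom", 2 * p, eps = 0.5))
  )) {
    vals <- vapply(sc, function(s) expected_pd(t4_ead, s), numeric(1))
    expect_true(all(diff(vals) > 0))
    expect_true(all(vals >= 0 & vals <= 8))
  }
})

test_that("expected tips and intensity solving invert each other", {
  expect_equal(expected_tips(sampling_scheme("binomial", 0.5), 4), 2)
  expect_equal(expected_tips(sampling_scheme("binomial", 1), 17), 17)
  expect_equal(expected_tips(sampling_scheme("poisson", 0.1), 100),
               100 * (1 - exp(-0.1)))

  expect_equal(solve_intensity("binomial", 4, 2)$p, 0.5)
  expect_equal(solve_intensity("poisson", 100, 100 * (1 - exp(-0.1)))$p, 0.1,
               tolerance = 1e-10)
  expect_error(solve_intensity("binomial", 4, 5), "outside")
  expect_error(solve_intensity("poisson", 10, 10), "full sample")

  # round trip across families and sizes
  for (fam in c("binomial", "poisson", "negbinom")) {
    for (tt in c(0.5, 7, 63)) {
      eps <- if (fam == "negbinom") 0.7 else NULL
      sc <- solve_intensity(fam, 100, tt, eps = eps)
      expect_equal(expected_tips(sc, 100), tt, tolerance = 1e-10)
    }
  }
  # overdispersed branch stays invertible while the domain allows
  sc <- solve_intensity("negbinom", 100, 30, eps = -0.2)
  expect_equal(expected_tips(sc, 100), 30, tolerance = 1e-10)
})

test_that("expected and variance of PD match exhaustive enumeration", {
  expect_equal(variance_pd(t4, sampling_scheme("binomial", 0.5)), 4.6875)
  expect_equal(variance_pd(t4, sampling_scheme("binomial", 1)), 0)
  expect_equal(variance_pd(t4, sampling_scheme("binomial", 0)), 0)

  for (seed in 1:8) {
    tr <- small_random_tree(seed)
    tab <- exhaustive_pd_table(tr)
    ead <- compute_ead(tr)
    for (p in seq(0.1, 0.9, by = 0.2)) {
      ex <- exhaustive_pd_moments(tab, p)
      sc <- sampling_scheme("binomial", p)
      expect_equal(expected_pd(ead, sc), unname(ex["mean"]), tolerance = 1e-12)
      expect_equal(variance_pd(tr, sc), unname(ex["var"]), tolerance = 1e-12)
    }
  }
})

test_that("variance matches the pairwise-covariance oracle in every family", {
  schemes <- list(
    sampling_scheme("binomial", 0.3),
    sampling_scheme("poisson", 0.6),
    sampling_scheme("negbinom", 0.6, eps = 0.8),
    sampling_scheme("negbinom", 0.4, eps = -0.05)
  )
  for (seed in c(2, 5)) {
    tr <- yule_tree(30, seed = seed)
    for (sc in schemes) {
      expect_equal(variance_pd(tr, sc), pairwise_variance_oracle(tr, sc),
                   tolerance = 1e-10)
    }
  }
  # a supplied root edge participates in the variance
  tr <- parse_newick("((A:1.0,B:2.0):2.0,(C:1.0,D:1.0):1.0):0.7;")
  sc <- sampling_scheme("negbinom", 0.5, eps = 0.5)
  expect_equal(variance_pd(tr, sc), pairwise_variance_oracle(tr, sc),
               tolerance = 1e-10)
})

test_that("predict_pd bundles the analytic summaries", {
  row <- predict_pd(t4, sampling_scheme("binomial", 0.5))
  expect_equal(row$expected_pd, 4.75)
  expect_equal(row$variance_pd, 4.6875)
  expect_equal(row$expected_tips, 2)
  expect_equal(row$sd_pd, sqrt(4.6875))
})
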