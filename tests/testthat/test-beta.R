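half <- sampling_scheme("binomial", 0.5)
one <- sampling_scheme("binomial", 1)

test_that("expected shared/union/UniFrac match hand evaluation on the fixture", {
  expect_equal(expected_shared(t4_ead, one, one), 8)
  expect_equal(expected_shared(t4_ead, half, half), 2.9375)
  expect_equal(expected_shared(t4_ead, sampling_scheme("binomial", 0), half), 0)

  expect_equal(expected_union(t4_ead, half, half), 6.5625)
  expect_equal(expected_union(t4_ead, one, sampling_scheme("poisson", 0.2)), 8)
  # inclusion-exclusion identity
  for (pb in c(0.2, 0.5, 0.9)) {
    sb <- sampling_scheme("binomial", pb)
    expect_equal(
      expected_union(t4_ead, half, sb),
      expected_pd(t4_ead, half) + expected_pd(t4_ead, sb) -
        expected_shared(t4_ead, half, sb)
    )
  }

  expect_equal(expected_unifrac(t4_ead, half, half), 1 - 2.9375 / 6.5625)
  expect_equal(expected_unifrac(t4_ead, one, one), 0)
  expect_error(expected_unifrac(t4_ead, sampling_scheme("binomial", 0),
                                sampling_scheme("binomial", 0)), "undefined")
  # symmetric in the two schemes
  po <- sampling_scheme("poisson", 0.3)
  expect_equal(expected_unifrac(t4_ead, half, po),
               expected_unifrac(t4_ead, po, half))
})

test_that("observed UniFrac hits its boundary values and hand cases", {
  expect_equal(observed_unifrac(t4, c("A", "B"), c("A", "B")), 0)
  expect_equal(observed_unifrac(t4, c("A", "B"), c("C", "D")), 1)
  expect_equal(observed_unifrac(t4, "A", c("A", "B")), 0.4)
  b <- observed_beta(t4, "A", c("A", "B"))
  expect_equal(b$shared, 3)
  expect_equal(b$union, 5)
  expect_error(observed_unifrac(t4, character(0), "A"), "non-empty")
  expect_error(observed_unifrac(t4, "A", c("A", "Q")), "Q")
})

test_that("normalization divides by the matched-size expectation", {
  expect_equal(normalize_unifrac(0.5, 0.5), 1)
  expect_equal(normalize_unifrac(0, 0.3), 0)
  expect_error(normalize_unifrac(0.5, 0), "positive")
  euf <- expected_unifrac(t4_ead, half, half)
  expect_equal(normalize_unifrac(euf, euf), 1)
})

test_that("unequal sample sizes inflate expected UniFrac at fixed mean size", {
  ead <- power_law_ead(1, 2^10)
  deltas <- c(0, 0.05, 0.1, 0.15, 0.2)
  uf <- vapply(deltas, function(d) {
    expected_unifrac(ead, sampling_scheme("binomial", 0.3 + d),
                     sampling_scheme("binomial", 0.3 - d))
  }, numeric(1))
  expect_true(all(diff(uf) > 0))
  expect_gt(uf[5], uf[1])
})

test_that("pairwise UniFrac tables and clustering are deterministic", {
  members <- tibble::tibble(
    sample = c("s1", "s1", "s2", "s2", "s3"),
    tip = c("A", "B", "C", "D", "A")
  )
  tab <- unifrac_matrix(t4, members)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$observed[tab$sample_a == "s1" & tab$sample_b == "s2"], 1)
  tabn <- unifrac_matrix(t4, members, normalize = TRUE)
  expect_true(all(c("expected", "normalized") %in% names(tabn)))
  expect_equal(tabn$normalized, tabn$observed / tabn$expected)

  m <- matrix(c(0, 0.1, 0.5, 0.1, 0, 0.5, 0.5, 0.5, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- cluster_distances(m)
  expect_equal(hc$height, c(0.1, 0.5))
  expect_true(grepl("A", dendrogram_newick(hc)))
  # 2x2: single merge at the pair distance
  m2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(cluster_distances(m2)$height, 0.3)
  # tie-break: identical rows merge lexicographically smallest pair first
  m3 <- matrix(0.2, 3, 3, dimnames = list(c("C", "B", "A"), c("C", "B", "A")))
  diag(m3) <- 0
  hc3 <- cluster_distances(m3)
  expect_equal(hc3$labels[-hc3$merge[1, ]], c("A", "B"))
  expect_error(cluster_distances(matrix(c(0, 1, 2, 0), 2,
    dimnames = list(c("A", "B"), c("A", "B")))), "symmetric")
})
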