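test_that("the fixture EAD matches direct edge enumeration", {
  expect_equal(t4_ead$n, c(1, 2, 4))
  expect_equal(t4_ead$edge_length, c(5, 3, 0))
  # an edge of length 2 with 2 descendant tips contributes exactly 2 to L(2)
  et <- compute_ead(parse_newick("((A:0,B:0):2.0,C:0);"))
  expect_equal(et$edge_length[et$n == 2], 2)
  # star tree: every edge pendant
  star <- compute_ead(parse_newick("(A:1,B:1,C:1,D:1,E:1);"))
  expect_equal(star$edge_length, c(5, 0))
  expect_equal(star$n, c(1, 5))
})

test_that("EAD conserves branch length and ignores label/child order", {
  for (seed in 1:25) {
    tr <- yule_tree(10 + seed * 7, seed = seed)
    ead <- compute_ead(tr)
    expect_equal(sum(ead$edge_length), total_branch_length(tr), tolerance = 1e-12)
    expect_equal(ead$edge_length[ead$n == 1],
                 sum(tr$edge.length[tr$edge[, 2] <= ape::Ntip(tr)]))
  }
  a <- compute_ead(parse_newick("((A:1.0,B:2.0):2.0,(C:1.0,D:1.0):1.0);"))
  b <- compute_ead(parse_newick("((D:1.0,C:1.0):1.0,(B:2.0,A:1.0):2.0);"))
  expect_equal(a$n, b$n)
  expect_equal(a$edge_length, b$edge_length)
})

test_that("octave binning is half-open, complete and mass-conserving", {
  b <- bin_ead(t4_ead)
  expect_equal(b$bin_lower, c(1, 2, 4))
  expect_equal(b$bin_upper, c(2, 4, 8))
  expect_equal(b$mass, c(5, 3, 0))
  expect_equal(sum(b$mass), sum(t4_ead$edge_length))

  b3 <- bin_ead(as_ead(data.frame(n = 3, edge_length = 1), N = 3))
  expect_equal(b3$mass[b3$bin_lower == 2], 1)

  # boundary class 2^k lands in the bin whose lower edge it equals
  b4 <- bin_ead(as_ead(data.frame(n = c(2, 4), edge_length = c(1, 1)), N = 4))
  expect_equal(b4$mass, c(0, 1, 1))
})

test_that("power-law EADs evaluate the formula and round-trip the exponent", {
  e1 <- power_law_ead(1, 4)
  expect_equal(e1$edge_length, c(1, 1 / 2, 1 / 3, 1 / 4))
  e0 <- power_law_ead(0, 3, scale = 2)
  expect_equal(e0$edge_length, rep(2, 3))
  expect_error(power_law_ead(1, 1), "n_max")

  # dense synthetic EAD: exponent recovered within 0.1
  f1 <- fit_power_law(bin_ead(power_law_ead(1, 1024, scale = 100)))
  expect_lt(abs(f1$exponent - 1), 0.1)
  f12 <- fit_power_law(bin_ead(power_law_ead(1.2, 2^12, scale = 50)))
  expect_lt(abs(f12$exponent - 1.2), 0.1)
  # flat EAD: zero exponent
  f0 <- fit_power_law(bin_ead(power_law_ead(0, 256)))
  expect_lt(abs(f0$exponent), 0.05)
})

test_that("power-law fitting validates input and exposes tidy summaries", {
  two_bins <- bin_ead(as_ead(data.frame(n = c(1, 2), edge_length = c(1, 1)), N = 3))
  expect_error(fit_power_law(two_bins), "insufficient")

  f <- fit_power_law(bin_ead(power_law_ead(1, 256)))
  expect_true(f$r_squared >= 0 && f$r_squared <= 1)
  td <- tidy(f)
  expect_equal(td$term, c("exponent", "intercept"))
  gl <- glance(f)
  expect_named(gl, c("exponent", "intercept", "r_squared", "n_bins"))
  expect_equal(gl$exponent, f$exponent)
  # width normalization agrees with the default when every octave is
  # fully occupied (n_max one below a power of 2, so no lone top class)
  fc <- fit_power_law(bin_ead(power_law_ead(1, 1023)))
  fw <- fit_power_law(bin_ead(power_law_ead(1, 1023)), normalize = "width")
  expect_lt(abs(fw$exponent - fc$exponent), 0.05)
})

test_that("EAD TSV serialization round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ead(t4_ead, f)
  back <- read_ead(f)
  expect_equal(back$n, t4_ead$n)
  expect_equal(back$edge_length, t4_ead$edge_length)
})
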