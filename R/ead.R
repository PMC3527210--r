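#' Edge-length abundance distribution (EAD) of a tree
#'
#' The EAD is the package's central summary of a metacommunity tree: for
#' each abundance class `n` (number of descendant tips of an edge), the
#' total branch length `L(n)` carried by all edges of that class.  Pendant
#' edges make up class 1, the root edge belongs to class `N` (total tip
#' count) and is always reported even when its length is 0.  The EAD
#' conserves branch length: `sum(L(n))` equals
#' [total_branch_length()] of the tree.
#'
#' @param tree A validated `phylo` object.
#' @param weights Optional per-tip integer weights (see [tip_counts()]);
#'   a tip with weight `w` counts as `w` identical individuals when edges
#'   are assigned to abundance classes.
#' @return An `ead` tibble with columns `n` (abundance class) and
#'   `edge_length` (`L(n)`), ordered by `n`, carrying the total tip count
#'   as attribute `N`.
#' @examples
#' compute_ead(fixture_tree())
#' @export
compute_ead <- function(tree, weights = NULL) {
  et <- edge_table(tree, weights)
  agg <- dplyr::summarise(
    dplyr::group_by(as_tibble(et), n = .data$n),
    edge_length = sum(.data$length), .groups = "drop"
  )
  N <- et$n[nrow(et)] # root edge class = (weighted) tip total
  if (!N %in% agg$n) {
    agg <- dplyr::bind_rows(agg, tibble(n = N, edge_length = 0))
  }
  new_ead(dplyr::arrange(agg, .data$n), N = N)
}

new_ead <- function(df, N) {
  out <- as_tibble(df)[, c("n", "edge_length")]
  attr(out, "N") <- as.numeric(N)
  class(out) <- c("ead", class(out))
  out
}

#' Build an EAD from a data frame
#'
#' @param df Data frame with columns `n` and `edge_length`.
#' @param N Total tip count of the (possibly hypothetical) source tree;
#'   defaults to `max(df$n)`.
#' @return An `ead` tibble.
#' @export
as_ead <- function(df, N = max(df$n)) {
  if (!all(c("n", "edge_length") %in% names(df))) {
    abort("an EAD needs columns 'n' and 'edge_length'")
  }
  if (any(df$n < 1) || any(df$n != round(df$n))) abort("abundance classes must be positive integers")
  if (any(df$edge_length < 0)) abort("edge lengths must be non-negative")
  if (anyDuplicated(df$n)) abort("duplicate abundance class")
  new_ead(dplyr::arrange(as_tibble(df), .data$n), N = N)
}

ead_total_tips <- function(ead) {
  N <- attr(ead, "N")
  if (is.null(N)) max(ead$n) else N
}

#' Exact power-law EAD for theory curves
#'
#' Returns the EAD of a hypothetical metacommunity with
#' `L(n) = scale * n^(-exponent)` for every class `n = 1..n_max`; used to
#' draw expected-PD and expected-UniFrac theory curves without committing
#' to a particular tree realization (use [powerlaw_tree()] when an actual
#' tree, e.g. for [variance_pd()], is required).
#'
#' @param exponent Power-law exponent `alpha >= 0`.
#' @param n_max Largest abundance class (the hypothetical tip count), >= 2.
#' @param scale Multiplicative scale (branch-length units), > 0.
#' @return An `ead` tibble with `N = n_max`.
#' @export
power_law_ead <- function(exponent, n_max, scale = 1) {
  if (n_max < 2 || n_max != round(n_max)) abort("n_max must be an integer >= 2")
  if (scale <= 0) abort("scale must be positive")
  if (exponent < 0) abort("exponent must be non-negative")
  n <- seq_len(n_max)
  new_ead(tibble(n = n, edge_length = scale * n^(-exponent)), N = n_max)
}

#' Octave-bin an EAD
#'
#' Groups abundance classes into Preston-style octaves: bin `k` covers
#' `[base^k, base^(k+1))`, half-open so no class is counted twice.  Bins
#' jointly cover `[1, N]`; empty bins are kept with mass 0.  The column
#' `n_classes` records how many abundance classes with positive mass fall
#' in the bin — [fit_power_law()] uses it to normalize for the sparse
#' occupancy of large-`n` classes on real trees.
#'
#' @param ead An `ead` tibble.
#' @param base Logarithmic bin base (default 2, the Preston octave).
#' @return A `binned_ead` tibble with columns `bin_lower`, `bin_upper`
#'   (half-open, `[lower, upper)`), `n_classes`, `mass`.
#' @export
bin_ead <- function(ead, base = 2) {
  if (nrow(ead) == 0L) abort("empty EAD")
  N <- ead_total_tips(ead)
  kmax <- floor(log(N) / log(base) + 1e-9)
  lowers <- base^(0:kmax)
  uppers <- base^(1:(kmax + 1))
  k <- findInterval(ead$n, lowers)
  mass <- vapply(seq_along(lowers), function(i) sum(ead$edge_length[k == i]), numeric(1))
  ncl <- vapply(seq_along(lowers), function(i) {
    sum(k == i & ead$edge_length > 0)
  }, numeric(1))
  out <- tibble(
    bin_lower = lowers, bin_upper = uppers,
    n_classes = ncl, mass = mass
  )
  class(out) <- c("binned_ead", class(out))
  attr(out, "N") <- N
  attr(out, "base") <- base
  out
}

#' Fit a power law to a binned EAD
#'
#' Ordinary least squares on the log-log binned distribution: the response
#' is `log2` of bin mass divided by a per-bin normalizer, the abscissa is
#' `log2` of the bin's lower edge (or geometric midpoint).  Bins with no
#' mass are dropped; at least 3 positive bins are required.  The returned
#' exponent is the negated slope, i.e. `alpha` in `L(n) ~ n^(-alpha)`.
#'
#' Normalization choices, exposed because octave plots in the literature
#' differ silently on this point:
#' \describe{
#'   \item{`"classes"` (default)}{divide bin mass by the number of occupied
#'     abundance classes in the bin, estimating the mean per-class
#'     `L(n)` whose log-log slope is `-alpha`.  On trees, large-`n`
#'     classes are sparsely occupied (few edges subtend many tips), and
#'     this normalizer is what keeps the estimate unbiased there.}
#'   \item{`"width"`}{divide by bin width; equivalent for EADs in which
#'     every class is occupied, biased upward on trees.}
#'   \item{`"none"`}{raw octave mass, whose slope is `1 - alpha` under a
#'     dense power law; reported exponent is then the negated raw slope.}
#' }
#'
#' @param binned A `binned_ead` tibble from [bin_ead()].
#' @param normalize One of `"classes"`, `"width"`, `"none"`.
#' @param abscissa One of `"lower"` (log2 lower bin edge, default) or
#'   `"midpoint"` (log2 geometric midpoint).
#' @return A `power_law_fit` object with elements `exponent`, `intercept`,
#'   `r_squared`, `n_bins`, and the per-bin regression `data`; has
#'   [tidy()], [glance()], [autoplot()] and print methods.
#' @export
fit_power_law <- function(binned, normalize = c("classes", "width", "none"),
                          abscissa = c("lower", "midpoint")) {
  normalize <- match.arg(normalize)
  abscissa <- match.arg(abscissa)
  keep <- binned$mass > 0
  if (sum(keep) < 3L) {
    abort(sprintf("insufficient data: %d positive bins, need at least 3", sum(keep)))
  }
  b <- binned[keep, ]
  divisor <- switch(normalize,
    classes = pmax(b$n_classes, 1),
    width = b$bin_upper - b$bin_lower,
    none = rep(1, nrow(b))
  )
  x <- switch(abscissa,
    lower = log2(b$bin_lower),
    midpoint = log2(sqrt(b$bin_lower * b$bin_upper))
  )
  y <- log2(b$mass / divisor)
  fit <- lm(y ~ x)
  r2 <- if (length(unique(y)) == 1L) 1 else summary(fit)$r.squared
  structure(
    list(
      exponent = unname(-coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r_squared = r2,
      n_bins = nrow(b),
      normalize = normalize,
      abscissa = abscissa,
      data = tibble(log2_n = x, log2_density = y)
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law EAD fit: L(n) ~ n^(-%.3f)  (R^2 = %.3f, %d octave bins, normalize = %s)\n",
    x$exponent, x$r_squared, x$n_bins, x$normalize
  ))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x A `power_law_fit` object.
#' @param ... Unused.
#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(
    term = c("exponent", "intercept"),
    estimate = c(x$exponent, x$intercept)
  )
}

#' @rdname fit_power_law
#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(
    exponent = x$exponent, intercept = x$intercept,
    r_squared = x$r_squared, n_bins = x$n_bins
  )
}

#' Write / read an EAD as TSV
#'
#' Serialization used by the command-line interface: columns
#' `n<TAB>edge_length` for an EAD, `bin_lower<TAB>bin_upper<TAB>n_classes<TAB>mass`
#' for a binned EAD.
#'
#' @param ead An `ead` tibble.
#' @param path Output path.
#' @return `path`, invisibly (`read_ead` returns the `ead`).
#' @export
write_ead <- function(ead, path) {
  readr::write_tsv(as_tibble(ead)[, c("n", "edge_length")], path)
  invisible(path)
}

#' @rdname write_ead
#' @param N Total tip count (defaults to the largest class present).
#' @export
read_ead <- function(path, N = NULL) {
  df <- readr::read_tsv(path, col_types = "dd")
  as_ead(df, N = N %||% max(df$n))
}
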