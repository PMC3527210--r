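#' Plot a binned EAD on log-log axes
#'
#' Octave mass per occupied abundance class against the bin's lower edge,
#' both on log2 axes — the standard way abundance distributions are
#' inspected for power-law behavior.
#'
#' @param object A `binned_ead` tibble from [bin_ead()].
#' @param normalize Per-bin normalizer, as in [fit_power_law()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binned_ead
#' @export
autoplot.binned_ead <- function(object, normalize = c("classes", "width", "none"), ...) {
  normalize <- match.arg(normalize)
  b <- object[object$mass > 0, ]
  divisor <- switch(normalize,
    classes = pmax(b$n_classes, 1),
    width = b$bin_upper - b$bin_lower,
    none = rep(1, nrow(b))
  )
  df <- tibble(
    log2_n = log2(b$bin_lower),
    log2_density = log2(b$mass / divisor)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_n, .data$log2_density)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "log2 descendant tips (octave lower edge)",
      y = switch(normalize,
        classes = "log2 branch length per occupied class",
        width = "log2 branch length per unit class width",
        none = "log2 octave branch length"
      )
    )
}

#' @rdname fit_power_law
#' @param object A `power_law_fit`.
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$log2_n, .data$log2_density)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = -object$exponent,
      linetype = 2
    ) +
    ggplot2::labs(
      x = "log2 descendant tips",
      y = "log2 normalized octave branch length",
      title = sprintf("L(n) ~ n^(-%.2f), R² = %.3f", object$exponent, object$r_squared)
    )
}

#' Plot an expected-PD theory curve, optionally with observed samples
#'
#' Expected PD against expected distinct tips on log-log axes, with the
#' confidence band when the curve was built from a tree; observed
#' communities from [classify_samples()] can be overlaid and are colored
#' by their clustered/random/overdispersed label.
#'
#' @param object A `pd_curve` tibble from [pd_curve()].
#' @param observed Optional tibble from [classify_sample()] /
#'   [classify_samples()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pd_curve
#' @export
autoplot.pd_curve <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$expected_tips, .data$expected_pd))
  if (!all(is.na(object$ci_low))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$ci_low, 0), ymax = .data$ci_high),
      alpha = 0.2
    )
  }
  p <- p + ggplot2::geom_line()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(
      data = observed,
      ggplot2::aes(.data$observed_tips, .data$observed_pd, color = .data$label)
    )
  }
  p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "expected distinct tips", y = "expected PD", color = NULL)
}
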