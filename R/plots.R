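#' Plot a threshold scan
#'
#' Real and randomized average clustering coefficients against the
#' correlation threshold, their difference, and the selected cut-off.
#'
#' @param object A [threshold_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot threshold_scan
#' @export
autoplot.threshold_scan <- function(object, ...) {
  sel <- select_threshold(object)
  long <- tidyr::pivot_longer(
    tidy(object)[, c("threshold", "c_real", "c_rand", "diff")],
    c("c_real", "c_rand", "diff"),
    names_to = "curve", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = sel$threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(c_real = "black", c_rand = "steelblue", diff = "firebrick"),
      labels = c(c_real = "real", c_rand = "randomized", diff = "difference")
    ) +
    ggplot2::labs(x = "correlation threshold",
                  y = "average clustering coefficient",
                  colour = NULL,
                  subtitle = sprintf("selected threshold %.2f%s", sel$threshold,
                                     if (sel$fallback) " (fallback)" else ""))
}

#' Plot a power-law fit
#'
#' Empirical complementary CDF of the degree sequence on log-log axes with
#' the fitted power law drawn from `xmin`.
#'
#' @param object A [powerlaw_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot powerlaw_fit
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  x <- sort(unique(object$degrees))
  ccdf <- vapply(x, function(v) mean(object$degrees >= v), numeric(1))
  emp <- tibble(degree = x, ccdf = ccdf)
  xs <- object$xmin:max(object$degrees)
  z <- hurwitz_zeta(object$alpha, object$xmin)
  tail_p <- rev(cumsum(rev(xs^(-object$alpha)))) / z
  scale_to <- mean(object$degrees >= object$xmin)
  fit <- tibble(degree = xs, ccdf = tail_p * scale_to / tail_p[1])
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$degree, y = .data$ccdf)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "degree x", y = "P(X ≥ x)",
      subtitle = sprintf("alpha = %.2f, xmin = %d, bootstrap p = %s",
                         object$alpha, object$xmin,
                         format(object$p_value, digits = 3))
    )
}

#' Plot a null distribution
#'
#' Histogram of the randomized statistic, optionally with the observed
#' value marked.
#'
#' @param object A `null_distribution`.
#' @param observed Optional observed value to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot null_distribution
#' @export
autoplot.null_distribution <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = object$statistic, y = "count")
  if (!is.null(observed)) {
    p <- p +
      ggplot2::geom_vline(xintercept = observed, colour = "firebrick") +
      ggplot2::labs(subtitle = sprintf("observed %.4g (z = %.1f)", observed,
                                       null_zscore(observed, object)))
  }
  p
}

#' Plot a degree-profile PCA projection
#'
#' @param object A [degree_profile_pca()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot degree_pca
#' @export
autoplot.degree_pca <- function(object, ...) {
  ev <- attr(object, "explained_variance")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                       label = .data$network)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * ev[min(2, length(ev))])
    )
}
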