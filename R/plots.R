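#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a site frequency spectrum
#'
#' @param object An [sfs_spectrum()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sfs <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = if (object$folded) "minor allele count" else "derived allele count",
      y = "sites",
      title = sprintf("SFS (n = %d, %s)", object$n,
                      if (object$folded) "folded" else "unfolded")) +
    ggplot2::theme_minimal()
}

#' Plot fitted DFE bin proportions
#'
#' @param object A `dfe_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.dfe_fit <- function(object, ...) {
  df <- tidy(object)
  df$bin <- factor(df$bin, levels = df$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Ne*s bin", y = "proportion of new mutations",
                  title = sprintf("gamma DFE: shape %.2f, E[Ne*s] %.3g",
                                  object$shape, object$mean)) +
    ggplot2::theme_minimal()
}

#' Plot alpha(x) bins and the asymptotic fit
#'
#' @param object An `asymp_mk_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.asymp_mk_fit <- function(object, ...) {
  df <- object$bins
  xx <- seq(0.02, 1, by = 0.01)
  curve <- if (!object$fallback) {
    tibble::tibble(x = xx, y = object$a + object$b * exp(-object$c * xx))
  } else {
    tibble::tibble(x = xx, y = object$a + object$b * xx)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$alpha_x)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$y),
                       color = "firebrick") +
    ggplot2::geom_hline(yintercept = object$alpha_asym, linetype = 2) +
    ggplot2::labs(x = "derived allele frequency", y = "alpha(x)",
                  title = sprintf("asymptotic MK: alpha = %.3f",
                                  object$alpha_asym)) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a CLR scan
#'
#' @param scan Tibble from [clr_scan()].
#' @param threshold Optional horizontal significance line.
#' @return A ggplot.
#' @export
plot_clr <- function(scan, threshold = NULL) {
  p <- ggplot2::ggplot(scan,
                       ggplot2::aes(x = .data$grid_pos / 1e6,
                                    y = .data$clr)) +
    ggplot2::geom_point(size = 0.8, color = "grey20") +
    ggplot2::labs(x = "position (Mb)", y = "CLR") +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 color = "firebrick")
  p
}
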