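#' Plot a value curve
#'
#' Line plot of expected value (or weighted utility) against criterion
#' location, with a drop line at the refined optimum.
#'
#' @param object An [ev_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ev_curve <- function(object, ...) {
  env <- attr(object, "environment")
  opt <- optimal_criterion(env, attr(object, "payoffs"), attr(object, "scheme"),
                           mode = attr(object, "mode"),
                           bounds = range(object$x), n = nrow(object))
  ylab <- if (attr(object, "mode") == "ev") "expected value" else "weighted utility"
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = opt$x_star, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::annotate("point", x = opt$x_star, y = opt$value, size = 2) +
    ggplot2::labs(x = paste0("criterion (", env$units, ")"), y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot an expected-value envelope
#'
#' Ribbon between the minimum and maximum curves with the mean curve and the
#' three optimal-criterion drop lines.
#'
#' @param object An [ev_envelope()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ev_envelope <- function(object, ...) {
  wide <- tidyr::pivot_wider(object$curves, names_from = "curve",
                             values_from = "value")
  env <- object$environment
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.8) +
    ggplot2::geom_vline(data = object$optima,
                        ggplot2::aes(xintercept = .data$x_star,
                                     linetype = .data$curve),
                        colour = "grey30") +
    ggplot2::labs(x = paste0("criterion (", env$units, ")"),
                  y = if (object$mode == "ev") "expected value" else "weighted utility",
                  linetype = "optimum") +
    ggplot2::theme_minimal()
}

#' Plot a perceptual environment
#'
#' The target and foil signal densities, optionally with a criterion marker.
#'
#' @param env A [perceptual_environment()].
#' @param criterion Optional criterion location to mark.
#' @param n Number of grid points.
#' @return A ggplot object.
#' @export
plot_environment <- function(env, criterion = NULL, n = 501) {
  assert_environment(env)
  x <- seq(env$domain_bounds[1], env$domain_bounds[2], length.out = n)
  dens <- dplyr::bind_rows(
    tibble(x = x, density = (1 - env$base_rate) * dnorm(x, env$mu_foil, env$sigma_foil),
           distribution = "foil"),
    tibble(x = x, density = env$base_rate * dnorm(x, env$mu_target, env$sigma_target),
           distribution = "target")
  )
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
                                          colour = .data$distribution)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = env$units, y = "base-rate-weighted density") +
    ggplot2::theme_minimal()
  if (!is.null(criterion)) {
    p <- p + ggplot2::geom_vline(xintercept = criterion, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}
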