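# ggplot2 views of chains and test results.

#' Plot the mean/over-dispersion trend of a fitted chain
#'
#' Posterior medians of log over-dispersion against log mean expression for
#' every biological gene, with the fitted global trend (posterior median of
#' the regression coefficients evaluated over the observed log-mean range).
#'
#' @param chain a regression-variant `sc_chain`
#' @return a ggplot
#' @export
plot_trend <- function(chain) {
  if (is.null(chain$cfg)) stop("trend plot requires a regression-variant chain")
  d <- tibble::tibble(
    log_mu = log(apply(chain$draws$mu, 2, stats::median)),
    log_delta = log(apply(chain$draws$delta, 2, stats::median)))
  beta_med <- apply(chain$draws$beta, 2, stats::median)
  grid <- seq(min(d$log_mu), max(d$log_mu), length.out = 200)
  tr <- tibble::tibble(log_mu = grid,
                       log_delta = predict_trend(grid, beta_med, chain$cfg))
  ggplot2::ggplot(d, ggplot2::aes(.data$log_mu, .data$log_delta)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = tr, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "log mean expression", y = "log over-dispersion",
                  title = "Mean/over-dispersion trend") +
    ggplot2::theme_minimal()
}

#' Plot residual over-dispersion against mean expression
#'
#' Residual over-dispersion (epsilon) is decorrelated from the mean by
#' construction; this view makes that visible.
#'
#' @param chain a regression-variant `sc_chain`
#' @return a ggplot
#' @export
plot_epsilon <- function(chain) {
  if (is.null(chain$draws$epsilon))
    stop("epsilon plot requires a regression-variant chain")
  d <- tibble::tibble(
    log_mu = log(apply(chain$draws$mu, 2, stats::median)),
    epsilon = apply(chain$draws$epsilon, 2, stats::median))
  ggplot2::ggplot(d, ggplot2::aes(.data$log_mu, .data$epsilon)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log mean expression", y = "residual over-dispersion",
                  title = "Residual over-dispersion vs mean") +
    ggplot2::theme_minimal()
}

#' @rdname plot_trend
#' @param object a `sc_chain`
#' @param ... unused
#' @export
autoplot.sc_chain <- function(object, ...) {
  if (!is.null(object$cfg)) plot_trend(object) else {
    d <- tibble::tibble(
      log_mu = log(apply(object$draws$mu, 2, stats::median)),
      log_delta = log(apply(object$draws$delta, 2, stats::median)))
    ggplot2::ggplot(d, ggplot2::aes(.data$log_mu, .data$log_delta)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::labs(x = "log mean expression", y = "log over-dispersion") +
      ggplot2::theme_minimal()
  }
}

#' Volcano-style view of a differential test
#'
#' Point estimate against tail posterior probability, coloured by call;
#' the calibrated probability cutoff is drawn as a horizontal line.
#'
#' @param object an `sc_de_result`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.sc_de_result <- function(object, ...) {
  d <- tibble::tibble(estimate = object$estimate,
                      tail_prob = object$tail_prob,
                      call = object$call)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$tail_prob,
                                       colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = paste0("estimate (", attr(object, "test"), " test)"),
                  y = "tail posterior probability") +
    ggplot2::theme_minimal()
  if (!is.na(attr(object, "alpha")))
    p <- p + ggplot2::geom_hline(yintercept = attr(object, "alpha"),
                                 linetype = 2)
  p
}
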