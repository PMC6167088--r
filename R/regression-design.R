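#' Configuration of the mean/over-dispersion trend basis
#'
#' The global trend f(mu) relating log over-dispersion to log mean
#' expression is modelled semi-parametrically as an intercept, a linear term
#' in log(mu), and `L` Gaussian radial basis function (GRBF) kernels with
#' equally spaced locations spanning the current range of log(mu). Kernel
#' widths are tied to the spacing, h = c * delta_m, so `c` controls the
#' locality of the fit (narrow kernels, c < 0.5, are best avoided).
#'
#' @param L number of GRBF kernels (default 10).
#' @param c width proportionality constant (default 1.2).
#' @param eta Student-t degrees of freedom for the trend residuals
#'   (default 5; fixed, never sampled).
#' @param locations,scales optional explicit kernel locations/scales;
#'   normally populated from data via [kernel_locations()].
#' @return a list of class `regression_config`
#' @export
regression_config <- function(L = 10, c = 1.2, eta = 5,
                              locations = NULL, scales = NULL) {
  if (L < 2) stop("L must be >= 2")
  if (c <= 0) stop("c must be positive")
  cfg <- list(L = as.integer(L), c = c, eta = eta,
              locations = locations, scales = scales,
              range = if (is.null(locations)) NULL else range(locations))
  class(cfg) <- "regression_config"
  cfg
}

#' Equally spaced kernel locations over the log-mean range
#'
#' m_l = a + (l - 1) (b - a) / (L - 1) with a = min(logmu), b = max(logmu).
#'
#' @param logmu finite numeric vector of log mean-expression values.
#' @param L number of kernels (>= 2).
#' @return numeric vector of length `L`
#' @export
kernel_locations <- function(logmu, L) {
  if (!length(logmu) || any(!is.finite(logmu)))
    stop("logmu must be non-empty and finite")
  if (L < 2) stop("L must be >= 2")
  a <- min(logmu); b <- max(logmu)
  if (a == b) stop("degenerate log-mean range (all values equal)")
  a + (seq_len(L) - 1) * (b - a) / (L - 1)
}

#' Gaussian radial basis kernel
#'
#' g(x) = exp(-((x - m) / h)^2 / 2); bounded in (0, 1], equal to 1 at the
#' kernel centre.
#'
#' @param x evaluation point(s)
#' @param m kernel location
#' @param h kernel scale (> 0)
#' @return numeric of the same length as `x`
#' @export
grbf <- function(x, m, h) {
  if (any(h <= 0)) stop("kernel scale h must be positive")
  exp(-0.5 * ((x - m) / h)^2)
}

# populate locations/scales from a log-mean vector; a degenerate range
# (possible at initialization from empty data) falls back to a unit window
set_kernels <- function(cfg, logmu) {
  if (min(logmu) == max(logmu)) logmu <- c(logmu[1] - 1, logmu[1] + 1)
  loc <- kernel_locations(logmu, cfg$L)
  dm <- loc[2] - loc[1]
  cfg$locations <- loc
  cfg$scales <- rep(cfg$c * dm, cfg$L)
  cfg$range <- c(min(logmu), max(logmu))
  cfg
}

#' Design matrix of the trend regression
#'
#' Row i is (1, log(mu_i), g_1(log(mu_i)), ..., g_L(log(mu_i))), giving a
#' q0 x (L + 2) matrix so that f(mu) = X beta.
#'
#' @param logmu numeric vector of log mean-expression values.
#' @param cfg a [regression_config()] with populated locations/scales.
#' @return numeric matrix, `length(logmu)` rows and `cfg$L + 2` columns
#' @export
design_matrix <- function(logmu, cfg) {
  if (is.null(cfg$locations)) stop("regression_config has no kernel locations yet")
  bad <- which(!is.finite(logmu))
  if (length(bad)) stop("non-finite log-mean for gene index ", bad[1])
  K <- vapply(seq_len(cfg$L),
              function(l) grbf(logmu, cfg$locations[l], cfg$scales[l]),
              numeric(length(logmu)))
  if (length(logmu) == 1L) K <- matrix(K, nrow = 1L)
  cbind(1, logmu, K, deparse.level = 0)
}

#' Evaluate the fitted trend f(mu) = X beta
#'
#' @param logmu numeric vector of log mean-expression values.
#' @param beta coefficient vector of length `cfg$L + 2`.
#' @param cfg a populated [regression_config()].
#' @return numeric vector of trend values
#' @export
predict_trend <- function(logmu, beta, cfg) {
  X <- design_matrix(logmu, cfg)
  if (ncol(X) != length(beta))
    stop("beta length ", length(beta), " does not match design width ", ncol(X))
  drop(X %*% beta)
}

#' Refresh kernel locations during burn-in
#'
#' The range (a, b) of log(mu) is unknown before sampling, so kernel
#' locations and scales are recomputed from the current state every 50
#' iterations during burn-in and frozen thereafter. A degenerate range
#' (all log-means equal) keeps the previous kernels with a warning rather
#' than aborting a running chain.
#'
#' @param cfg current `regression_config`
#' @param logmu_current current log mean-expression vector
#' @param iteration 0-based iteration counter
#' @param burn_in number of burn-in iterations
#' @return possibly updated `regression_config`
#' @export
refresh_locations <- function(cfg, logmu_current, iteration, burn_in) {
  if (iteration >= burn_in || iteration %% 50L != 0L) return(cfg)
  if (min(logmu_current) == max(logmu_current)) {
    warning("degenerate log-mean range at iteration ", iteration,
            "; keeping previous kernel locations")
    return(cfg)
  }
  set_kernels(cfg, logmu_current)
}
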