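#' Model hyper-parameters and test defaults
#'
#' Collects every fixed hyper-parameter of the hierarchical model and the
#' default tolerance thresholds of the differential tests.
#'
#' * `a_mu2` — prior variance of log mean expression (log-Normal(0, a_mu2)).
#'   Not dictated by the model itself; 0.5 is a weakly-informative default.
#' * `a_delta2` — prior variance of log over-dispersion under the
#'   non-regression (independent) prior.
#' * `a_s`, `b_s` — Gamma(shape, rate) prior for the cell scale s_j, chosen
#'   so that E(s_j) = 1 a priori.
#' * `a_phi` — Dirichlet concentration for the mRNA-content parameters
#'   phi (spikes model; the phi vector is scaled to sum to n).
#' * `a_theta`, `b_theta` — Gamma prior for the technical noise theta.
#' * `m_beta`, `V_beta` — Normal prior mean / covariance of the regression
#'   coefficients (defaults: zero vector, identity).
#' * `a_sigma2`, `b_sigma2` — Inverse-Gamma prior for the residual scale
#'   sigma^2 of the mean/over-dispersion trend.
#' * `eta` — Student-t degrees of freedom of the trend residuals; fixed a
#'   priori (default 5: heavy enough tails to resist outlier genes).
#' * `tau0`, `omega0` — minimum log2 fold-change tolerances for the mean
#'   and over-dispersion tests; default log2(1.5).
#' * `psi0` — minimum |difference| tolerance for the residual
#'   over-dispersion test, on the natural-log scale; default
#'   log2(1.5)/log2(e) = ln(1.5), i.e. a 50% change in over-dispersion.
#' * `efdr_target` — expected false discovery rate target (default 0.10).
#'
#' @param ... named overrides of any default listed above.
#' @return a list of class `hyper_params`
#' @export
hyper_params <- function(...) {
  hp <- list(
    a_mu2 = 0.5, a_delta2 = 0.5,
    a_s = 1, b_s = 1,
    a_phi = 1,
    a_theta = 1, b_theta = 1,
    m_beta = NULL, V_beta = NULL,   # resolved once L is known
    a_sigma2 = 2, b_sigma2 = 2,
    eta = 5,
    tau0 = log2(1.5), omega0 = log2(1.5), psi0 = log2(1.5) / log2(exp(1)),
    efdr_target = 0.10)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(hp))
  if (length(unknown)) stop("unknown hyper-parameter(s): ",
                            paste(unknown, collapse = ", "))
  hp[names(dots)] <- dots
  for (nm in c("a_mu2", "a_delta2", "a_s", "b_s", "a_theta", "b_theta",
               "a_sigma2", "b_sigma2"))
    if (hp[[nm]] <= 0) stop(nm, " must be strictly positive")
  if (hp$eta < 1) stop("eta must be >= 1")
  if (hp$efdr_target <= 0 || hp$efdr_target >= 1)
    stop("efdr_target must lie in (0, 1)")
  if (hp$tau0 < 0 || hp$omega0 < 0 || hp$psi0 < 0)
    stop("tolerance thresholds must be >= 0")
  class(hp) <- "hyper_params"
  hp
}

# fill the beta prior once the design width (L + 2) is known
resolve_beta_prior <- function(hp, L) {
  p <- L + 2L
  if (is.null(hp$m_beta)) hp$m_beta <- rep(0, p)
  if (is.null(hp$V_beta)) hp$V_beta <- diag(p)
  stopifnot(length(hp$m_beta) == p, all(dim(hp$V_beta) == p))
  hp
}
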