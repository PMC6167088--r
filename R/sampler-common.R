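# Shared MCMC machinery: generalized-inverse-Gaussian draws, adaptive
# random-walk scales, likelihood building blocks, and the full joint
# log-posterior used as an independent oracle in the test suite.

#' Draw from a generalized inverse Gaussian distribution
#'
#' Density proportional to x^(p-1) exp(-(a x + b / x) / 2) on (0, Inf),
#' a > 0, b > 0, any real index p. Sampling is by ratio-of-uniforms on the
#' standardized two-parameter form (omega = sqrt(ab)), with the reflection
#' 1/X ~ GIG(-p, b, a) for negative index. Exact (rejection-based), used for
#' the cell-scale parameters whose full conditional has this shape.
#'
#' @param n number of draws
#' @param p index
#' @param a rate on x
#' @param b rate on 1/x
#' @return numeric vector of positive draws
#' @export
rgig <- function(n, p, a, b) {
  stopifnot(length(p) %in% c(1L, n), length(a) %in% c(1L, n),
            length(b) %in% c(1L, n))
  p <- rep_len(p, n); a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(a <= 0) || any(b <= 0))
    stop("rgig requires a > 0 and b > 0")
  alpha <- sqrt(b / a)
  omega <- sqrt(a * b)
  flip <- p < 0
  pp <- abs(p)
  # standardized density g(z) = z^(pp-1) exp(-omega (z + 1/z) / 2)
  lg <- function(z, pp, om) (pp - 1) * log(z) - 0.5 * om * (z + 1 / z)
  zm <- ((pp - 1) + sqrt((pp - 1)^2 + omega^2)) / omega     # mode of g
  z2 <- ((pp + 1) + sqrt((pp + 1)^2 + omega^2)) / omega     # mode of z^2 g
  lgm <- lg(zm, pp, omega)
  lvmax <- 0.5 * (lg(z2, pp, omega) + 2 * log(z2) - lgm)    # log(vmax / sqrt(g(zm)))
  out <- numeric(n)
  todo <- seq_len(n)
  guard <- 0L
  while (length(todo)) {
    m <- length(todo)
    u <- stats::runif(m)
    v <- stats::runif(m)
    z <- (v / u) * exp(lvmax[todo])
    ok <- 2 * log(u) <= lg(z, pp[todo], omega[todo]) - lgm[todo]
    out[todo[ok]] <- z[ok]
    todo <- todo[!ok]
    guard <- guard + 1L
    if (guard > 10000L) stop("rgig: rejection sampler failed to accept")
  }
  out <- ifelse(flip, 1 / out, out)
  out * alpha
}

# --- adaptive random-walk scales -------------------------------------------

# One adaptation step for a vector of log proposal sds. `acc` is the count
# of acceptances over the last `window` iterations; increments shrink as
# 1/sqrt(iteration) so adaptation vanishes (and it only runs during burn-in).
adapt_logsd <- function(ls, acc, window, iteration, target = 0.44) {
  step <- min(0.05, 1 / sqrt(iteration + 1))
  ls + step * sign(acc / window - target)
}

# --- likelihood building blocks (spikes model) -----------------------------

# Per-gene negative binomial log-likelihood terms for biological genes.
# counts: q0 x n, mu: q0, delta: q0, cellfac: n (phi_j nu_j, or nu_jk).
# Returns a q0-vector of log-likelihood contributions (constants included).
nb_loglik_genes <- function(counts, mu, delta, cellfac) {
  idelta <- 1 / delta
  rate <- outer(mu, cellfac)                  # q0 x n
  denom <- log(rate + idelta)                 # length-q0 vector adds row-wise
  lg <- lgamma(counts + idelta) - lgamma(idelta) - lgamma(counts + 1)
  term <- lg + counts * (log(rate) - denom) +
    idelta * (log(idelta) - denom)
  rowSums(term)
}

# Poisson log-likelihood terms for spike-in genes (mean nu_j * mu_i).
pois_loglik_genes <- function(counts, mu_spike, nu) {
  if (!length(mu_spike)) return(numeric(0))
  rate <- outer(mu_spike, nu)
  rowSums(counts * log(rate) - rate - lgamma(counts + 1))
}

# log density of the nu random effects: nu_j ~ Gamma(1/theta, 1/(s_j theta))
nu_logprior <- function(nu, s, theta) {
  stats::dgamma(nu, shape = 1 / theta, rate = 1 / (s * theta), log = TRUE)
}

# inverse-gamma log density
dinvgamma_log <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

# --- joint log posterior (oracle) ------------------------------------------

#' Joint log posterior density of the spikes model
#'
#' Written independently of the samplers, term by term from the marginal
#' likelihood (negative binomial for biological genes, Poisson for
#' spike-ins, Gamma for the technical random effects) and every prior. Used
#' by the test suite to check that each Metropolis block targets the right
#' conditional: the difference of this function under a single-block change
#' must equal the block's log acceptance ratio.
#'
#' @param state list with elements mu, delta, lambda, phi, s, nu, theta,
#'   beta, sigma2 (and mu_spike implicitly from `ds`)
#' @param ds an `expression_dataset` (spikes variant)
#' @param hp [hyper_params()]
#' @param cfg populated [regression_config()] or `NULL` for the
#'   non-regression (independent prior) variant
#' @return scalar log density (up to a constant not depending on parameters)
#' @export
joint_log_post_spikes <- function(state, ds, hp, cfg = NULL) {
  bio <- bio_counts(ds)
  spk <- spike_counts(ds)
  mu_spike <- ds$genes$spike_input[ds$genes$is_spike]
  cf <- state$phi * state$nu
  ll <- sum(nb_loglik_genes(bio, state$mu, state$delta, cf)) +
    sum(pois_loglik_genes(spk, mu_spike, state$nu)) +
    sum(nu_logprior(state$nu, state$s, state$theta))
  lmu <- log(state$mu)
  lp <- sum(stats::dnorm(lmu, 0, sqrt(hp$a_mu2), log = TRUE) - lmu)
  ldelta <- log(state$delta)
  if (!is.null(cfg)) {
    f <- predict_trend(lmu, state$beta, cfg)
    lp <- lp + sum(stats::dnorm(ldelta, f, sqrt(state$sigma2 / state$lambda),
                                log = TRUE) - ldelta)
    lp <- lp + sum(stats::dgamma(state$lambda, shape = cfg$eta / 2,
                                 rate = cfg$eta / 2, log = TRUE))
    hp <- resolve_beta_prior(hp, cfg$L)
    db <- state$beta - hp$m_beta
    Vinv <- solve(hp$V_beta)
    p <- length(state$beta)
    lp <- lp - 0.5 * p * log(2 * pi * state$sigma2) -
      0.5 * as.numeric(determinant(hp$V_beta)$modulus) -
      drop(t(db) %*% Vinv %*% db) / (2 * state$sigma2)
    lp <- lp + dinvgamma_log(state$sigma2, hp$a_sigma2, hp$b_sigma2)
  } else {
    lp <- lp + sum(stats::dnorm(ldelta, 0, sqrt(hp$a_delta2), log = TRUE) - ldelta)
  }
  n <- length(state$phi)
  lp <- lp + sum(stats::dgamma(state$s, hp$a_s, rate = hp$b_s, log = TRUE))
  aphi <- rep_len(hp$a_phi, n)
  lp <- lp + sum((aphi - 1) * log(state$phi / n)) +
    lgamma(sum(aphi)) - sum(lgamma(aphi))
  lp <- lp + stats::dgamma(state$theta, hp$a_theta, rate = hp$b_theta, log = TRUE)
  unname(as.numeric(ll + lp))
}

#' Joint log posterior density of the no-spikes model
#'
#' Independent oracle for the horizontal-integration sampler. The correlated
#' prior on the constrained log means is evaluated through its
#' non-degenerate (q_c - 1)-dimensional marginal for log(mu[-r]) (the
#' reference gene is a deterministic function of the rest), with inverse
#' covariance (I + 11')/a_mu2 on that subspace.
#'
#' @param state list with mu, delta, lambda, s, nu, theta (length-K), beta,
#'   sigma2, plus `reference` (gene index) and `constrained` (logical)
#' @param ds an `expression_dataset` (no spike-ins, >= 2 batches)
#' @param hp [hyper_params()]
#' @param cfg populated [regression_config()] or `NULL`
#' @param mu0 geometric-mean anchor
#' @return scalar log density (up to an additive constant)
#' @export
joint_log_post_nospikes <- function(state, ds, hp, cfg = NULL, mu0) {
  counts <- ds$counts
  batch <- ds$cells$batch
  bl <- unique(batch)
  theta_cell <- state$theta[match(batch, bl)]
  ll <- sum(nb_loglik_genes(counts, state$mu, state$delta, state$nu)) +
    sum(stats::dgamma(state$nu, shape = 1 / theta_cell,
                      rate = 1 / (state$s * theta_cell), log = TRUE))
  lmu <- log(state$mu)
  cset <- state$constrained
  r <- state$reference
  free <- which(cset & seq_along(lmu) != r)
  z <- lmu[free] - log(mu0)
  qc <- sum(cset)
  # N_{qc-1}(0, a_mu2 (I - 11'/qc)) with inverse (I + 11') / a_mu2
  lp <- -(sum(z^2) + sum(z)^2) / (2 * hp$a_mu2) - sum(lmu[cset])
  if (any(!cset))
    lp <- lp + sum(stats::dnorm(lmu[!cset], 0, sqrt(hp$a_mu2), log = TRUE) -
                     lmu[!cset])
  ldelta <- log(state$delta)
  if (!is.null(cfg)) {
    f <- predict_trend(lmu, state$beta, cfg)
    lp <- lp + sum(stats::dnorm(ldelta, f, sqrt(state$sigma2 / state$lambda),
                                log = TRUE) - ldelta)
    lp <- lp + sum(stats::dgamma(state$lambda, shape = cfg$eta / 2,
                                 rate = cfg$eta / 2, log = TRUE))
    hp <- resolve_beta_prior(hp, cfg$L)
    db <- state$beta - hp$m_beta
    p <- length(state$beta)
    lp <- lp - 0.5 * p * log(2 * pi * state$sigma2) -
      drop(t(db) %*% solve(hp$V_beta) %*% db) / (2 * state$sigma2)
    lp <- lp + dinvgamma_log(state$sigma2, hp$a_sigma2, hp$b_sigma2)
  } else {
    lp <- lp + sum(stats::dnorm(ldelta, 0, sqrt(hp$a_delta2), log = TRUE) - ldelta)
  }
  lp <- lp + sum(stats::dgamma(state$s, hp$a_s, rate = hp$b_s, log = TRUE))
  lp <- lp + sum(stats::dgamma(state$theta, hp$a_theta, rate = hp$b_theta,
                               log = TRUE))
  unname(as.numeric(ll + lp))
}

#' Marginal log-likelihood of the spikes model
#'
#' The likelihood with the gene-cell biological random effects integrated
#' out: negative binomial terms (size 1/delta_i, mean phi_j nu_j mu_i) for
#' biological genes, Poisson terms (mean nu_j mu_i) for spike-ins, and the
#' Gamma density of the technical random effects nu_j.
#'
#' @param ds an `expression_dataset` with spike-ins
#' @param mu,delta biological gene parameters (length q0)
#' @param phi,s,nu cell parameters (length n)
#' @param theta technical noise parameter (scalar)
#' @return scalar log-likelihood
#' @export
marginal_loglik <- function(ds, mu, delta, phi, s, nu, theta) {
  val <- sum(nb_loglik_genes(bio_counts(ds), mu, delta, phi * nu)) +
    sum(pois_loglik_genes(spike_counts(ds),
                          ds$genes$spike_input[ds$genes$is_spike], nu)) +
    sum(nu_logprior(nu, s, theta))
  if (!is.finite(val)) {
    pg <- nb_loglik_genes(bio_counts(ds), mu, delta, phi * nu)
    bad <- which(!is.finite(pg))
    if (length(bad))
      stop("non-finite likelihood for gene ",
           ds$genes$gene_id[!ds$genes$is_spike][bad[1]])
    stop("non-finite likelihood in spike-in or cell terms")
  }
  val
}

# --- initialization --------------------------------------------------------

# Empirical starting values. Size factors are library-size based; delta
# starts at the NB method-of-moments estimate (var = m + delta m^2), floored.
init_state_common <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0)) tot[tot == 0] <- 1
  sf <- tot / exp(mean(log(tot)))
  norm <- sweep(counts, 2, sf, "/")
  m <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  mu <- pmax(m, 1e-3)
  delta <- pmax((v - m) / m^2, 1e-3)
  delta[!is.finite(delta)] <- 1e-3
  list(mu = unname(mu), delta = unname(delta), sf = unname(sf))
}
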