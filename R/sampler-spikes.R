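# Adaptive Metropolis-within-Gibbs sampler for the spike-in (vertical
# integration) model. All gene blocks are updated jointly (their full
# conditionals are mutually independent given the cell parameters), cell
# blocks likewise; phi is proposed as a block on the simplex.
#
# Every Metropolis block works on the log scale; the block log-target
# functions below INCLUDE the log-scale Jacobian, so the acceptance ratio is
# exp(target(proposed) - target(current)). The test suite checks each one
# against the independently written joint log posterior.

# -- block log-targets (spikes) ---------------------------------------------
# pre$rs      rowSums of biological counts (q0)
# pre$counts  biological counts (q0 x n)

mu_block_target <- function(lmu, ldelta, lambda, beta, sigma2, cellfac,
                            pre, hp, cfg) {
  idelta <- exp(-ldelta)
  denom <- log(outer(exp(lmu), cellfac) + idelta)
  val <- pre$rs * lmu - rowSums((pre$counts + idelta) * denom) -
    lmu^2 / (2 * hp$a_mu2)
  if (!is.null(cfg)) {
    f <- predict_trend(lmu, beta, cfg)
    val <- val - lambda * (ldelta - f)^2 / (2 * sigma2)
  }
  unname(val)
}

delta_block_target <- function(ldelta, lmu, lambda, beta, sigma2, cellfac,
                               pre, hp, cfg) {
  idelta <- exp(-ldelta)
  n <- length(cellfac)
  denom <- log(outer(exp(lmu), cellfac) + idelta)
  val <- rowSums(lgamma(pre$counts + idelta)) - n * lgamma(idelta) -
    n * idelta * ldelta - rowSums((pre$counts + idelta) * denom)
  unname(if (!is.null(cfg)) {
    f <- predict_trend(lmu, beta, cfg)
    val - lambda * (ldelta - f)^2 / (2 * sigma2)
  } else {
    val - ldelta^2 / (2 * hp$a_delta2)
  })
}

phi_block_target <- function(phi, mu, delta, nu, pre, hp) {
  idelta <- 1 / delta
  rate <- outer(mu, phi * nu)
  n <- length(phi)
  aphi <- rep_len(hp$a_phi, n)
  sum(pre$counts * log(rate) - (pre$counts + idelta) * log(rate + idelta)) +
    sum((aphi - 1) * log(phi / n))
}

# per-cell target for nu (spikes variant); includes Jacobian
nu_block_target_spikes <- function(lnu, mu, delta, phi, s, theta,
                                   pre, spike_pre) {
  nu <- exp(lnu)
  idelta <- 1 / delta
  denom <- log(outer(mu, phi * nu) + idelta)
  unname(pre$cs * lnu - colSums((pre$counts + idelta) * denom) +
    spike_pre$cs * lnu - nu * spike_pre$musum +
    (1 / theta) * lnu - nu / (s * theta))
}

theta_block_target <- function(ltheta, nu, s, hp) {
  theta <- exp(ltheta)
  n <- length(nu)
  it <- 1 / theta
  sum(-it * log(s * theta) + it * log(nu) - nu / (s * theta)) -
    n * lgamma(it) + hp$a_theta * ltheta - hp$b_theta * theta
}

# Gibbs draw for the Student-t augmentation weights:
# lambda_i ~ Gamma((eta + 1) / 2, (eta + (log delta_i - f(mu_i))^2 / sigma2) / 2)
draw_lambda <- function(ldelta, f, sigma2, eta) {
  stopifnot(sigma2 > 0)
  stats::rgamma(length(ldelta), shape = (eta + 1) / 2,
                rate = (eta + (ldelta - f)^2 / sigma2) / 2)
}

# Exact joint draw of (sigma2, beta): sigma2 from its marginal conditional
# (beta integrated out), then beta | sigma2 ~ N(m_star, sigma2 V_star).
draw_beta_sigma2 <- function(X, Y, lambda, hp) {
  p <- ncol(X)
  Vinv <- solve(hp$V_beta)
  A <- crossprod(X, X * lambda) + Vinv           # X' Lambda X + V^-1
  ch <- chol(A)
  rhs <- crossprod(X, Y * lambda) + Vinv %*% hp$m_beta
  m_star <- backsolve(ch, forwardsolve(t(ch), rhs))
  b_star <- hp$b_sigma2 + 0.5 * (sum(Y^2 * lambda) +
    drop(t(hp$m_beta) %*% Vinv %*% hp$m_beta) -
    drop(t(m_star) %*% A %*% m_star))
  a_star <- hp$a_sigma2 + length(Y) / 2
  sigma2 <- 1 / stats::rgamma(1, shape = a_star, rate = b_star)
  beta <- drop(m_star + sqrt(sigma2) * backsolve(ch, stats::rnorm(p)))
  list(beta = beta, sigma2 = sigma2, m_star = drop(m_star), A = A,
       a_star = a_star, b_star = b_star)
}

# Dirichlet-perturbation proposal for phi (global simplex constraint):
# p' ~ Dirichlet(kappa p), phi' = n p'. Returns the proposal and the log
# proposal-density correction log q(p | p') - log q(p' | p).
propose_phi <- function(phi, kappa) {
  n <- length(phi)
  p <- phi / n
  g <- stats::rgamma(n, shape = kappa * p, rate = 1)
  if (any(g == 0) || !all(is.finite(g))) return(NULL)
  pn <- g / sum(g)
  ldir <- function(x, a) lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(x))
  list(phi = n * pn,
       lqcorr = ldir(p, kappa * pn) - ldir(pn, kappa * p))
}

#' Fit the spike-in (vertical integration) model
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler for the hierarchical
#' count model with spike-in genes: per-gene mean (mu) and over-dispersion
#' (delta), per-cell mRNA content (phi), scale (s) and technical noise (nu)
#' parameters, a global technical variability parameter (theta), and — when
#' `regression = TRUE` — the joint prior linking log(delta) to a
#' semi-parametric trend in log(mu) with Student-t residuals, which yields
#' the residual over-dispersion parameters epsilon.
#'
#' Sweep order is mu, delta, lambda, (beta, sigma2), phi, s, nu, theta.
#' Random-walk scales adapt every 50 iterations during burn-in toward an
#' acceptance rate of 0.44 (with increments shrinking as 1/sqrt(iteration));
#' GRBF kernel locations refresh every 50 iterations during burn-in and are
#' frozen afterwards.
#'
#' @param ds an [expression_dataset()] containing spike-in genes with known
#'   input quantities.
#' @param hp [hyper_params()].
#' @param regression use the joint mean/over-dispersion prior (default) or
#'   independent log-Normal priors.
#' @param cfg [regression_config()]; kernel locations are populated from the
#'   data at initialization.
#' @param n_iter,burn_in,thin MCMC schedule; `(n_iter - burn_in)` must be a
#'   positive multiple of `thin`.
#' @param seed integer seed; chains with the same seed are bit-identical.
#' @return an object of class `sc_chain`; see [tidy.sc_chain()].
#' @export
fit_spikes <- function(ds, hp = hyper_params(), regression = TRUE,
                       cfg = regression_config(eta = hp$eta),
                       n_iter = 20000, burn_in = 10000, thin = 10, seed = 1) {
  validate_dataset(ds, "spikes")
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1,
            (n_iter - burn_in) %% thin == 0)
  set.seed(seed)
  counts <- bio_counts(ds)
  spk <- spike_counts(ds)
  dimnames(counts) <- NULL
  dimnames(spk) <- NULL
  mu_spike <- ds$genes$spike_input[ds$genes$is_spike]
  q0 <- nrow(counts); n <- ncol(counts)
  pre <- list(counts = counts, rs = rowSums(counts), cs = colSums(counts))
  spike_pre <- list(cs = colSums(spk), musum = sum(mu_spike))

  ini <- init_state_common(counts)
  lmu <- log(ini$mu); ldelta <- log(ini$delta)
  bio_tot <- colSums(counts)
  phi <- n * pmax(bio_tot, 0.5) / sum(pmax(bio_tot, 0.5))
  s <- rep(1, n); nu <- s; theta <- 0.5
  lambda <- rep(1, q0); sigma2 <- 1
  if (regression) {
    cfg <- set_kernels(cfg, lmu)
    hp <- resolve_beta_prior(hp, cfg$L)
    beta <- rep(0, cfg$L + 2)
  } else {
    cfg <- NULL
    beta <- NULL
  }

  n_store <- (n_iter - burn_in) %/% thin
  dr <- list(mu = matrix(NA_real_, n_store, q0),
             delta = matrix(NA_real_, n_store, q0),
             epsilon = if (regression) matrix(NA_real_, n_store, q0) else NULL,
             lambda = if (regression) matrix(NA_real_, n_store, q0) else NULL,
             phi = matrix(NA_real_, n_store, n),
             s = matrix(NA_real_, n_store, n),
             nu = matrix(NA_real_, n_store, n),
             theta = matrix(NA_real_, n_store, 1),
             beta = if (regression) matrix(NA_real_, n_store, cfg$L + 2) else NULL,
             sigma2 = if (regression) rep(NA_real_, n_store) else NULL)

  ls_mu <- rep(log(0.5), q0); ls_delta <- rep(log(0.5), q0)
  ls_nu <- rep(log(0.3), n); ls_theta <- log(0.3)
  lkappa <- log(100 * n)  # Dirichlet proposal precision; adapted during burn-in
  acc <- list(mu = numeric(q0), delta = numeric(q0), nu = numeric(n),
              theta = 0, phi = 0)
  tot_acc <- list(mu = 0, delta = 0, nu = 0, theta = 0, phi = 0)
  window <- 50L

  for (iter in seq_len(n_iter)) {
    cellfac <- phi * nu

    # mu (all biological genes at once; conditionals are independent)
    prop <- lmu + stats::rnorm(q0) * exp(ls_mu)
    cur_t <- mu_block_target(lmu, ldelta, lambda, beta, sigma2, cellfac,
                             pre, hp, cfg)
    new_t <- mu_block_target(prop, ldelta, lambda, beta, sigma2, cellfac,
                             pre, hp, cfg)
    ok <- log(stats::runif(q0)) < new_t - cur_t
    lmu[ok] <- prop[ok]
    acc$mu <- acc$mu + ok

    # delta
    prop <- ldelta + stats::rnorm(q0) * exp(ls_delta)
    cur_t <- delta_block_target(ldelta, lmu, lambda, beta, sigma2, cellfac,
                                pre, hp, cfg)
    new_t <- delta_block_target(prop, lmu, lambda, beta, sigma2, cellfac,
                                pre, hp, cfg)
    ok <- log(stats::runif(q0)) < new_t - cur_t
    ldelta[ok] <- prop[ok]
    acc$delta <- acc$delta + ok

    if (regression) {
      f <- predict_trend(lmu, beta, cfg)
      lambda <- draw_lambda(ldelta, f, sigma2, cfg$eta)
      bs <- draw_beta_sigma2(design_matrix(lmu, cfg), ldelta, lambda, hp)
      beta <- bs$beta; sigma2 <- bs$sigma2
    }

    # phi (block Metropolis on the simplex, sum preserved exactly)
    pp <- propose_phi(phi, exp(lkappa))
    if (!is.null(pp)) {
      lr <- phi_block_target(pp$phi, exp(lmu), exp(ldelta), nu, pre, hp) -
        phi_block_target(phi, exp(lmu), exp(ldelta), nu, pre, hp) + pp$lqcorr
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        phi <- pp$phi
        acc$phi <- acc$phi + 1
      }
    }

    # s (exact generalized-inverse-Gaussian draw)
    s <- rgig(n, p = hp$a_s - 1 / theta, a = 2 * hp$b_s, b = 2 * nu / theta)

    # nu (per cell)
    lnu <- log(nu)
    prop <- lnu + stats::rnorm(n) * exp(ls_nu)
    cur_t <- nu_block_target_spikes(lnu, exp(lmu), exp(ldelta), phi, s, theta,
                                    pre, spike_pre)
    new_t <- nu_block_target_spikes(prop, exp(lmu), exp(ldelta), phi, s, theta,
                                    pre, spike_pre)
    ok <- log(stats::runif(n)) < new_t - cur_t
    lnu[ok] <- prop[ok]
    nu <- exp(lnu)
    acc$nu <- acc$nu + ok

    # theta
    lth <- log(theta)
    prop <- lth + stats::rnorm(1) * exp(ls_theta)
    lr <- theta_block_target(prop, nu, s, hp) - theta_block_target(lth, nu, s, hp)
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      theta <- exp(prop)
      acc$theta <- acc$theta + 1
    }

    # burn-in bookkeeping: kernel refresh + proposal adaptation
    if (iter <= burn_in && iter %% window == 0L) {
      if (regression) cfg <- refresh_locations(cfg, lmu, iter, burn_in)
      ls_mu <- adapt_logsd(ls_mu, acc$mu, window, iter)
      ls_delta <- adapt_logsd(ls_delta, acc$delta, window, iter)
      ls_nu <- adapt_logsd(ls_nu, acc$nu, window, iter)
      ls_theta <- adapt_logsd(ls_theta, acc$theta, window, iter)
      # phi: rejections call for MORE proposal precision (larger kappa)
      lkappa <- lkappa - 5 * adapt_logsd(0, acc$phi, window, iter)
      for (nm in names(acc)) tot_acc[[nm]] <- tot_acc[[nm]] + sum(acc[[nm]])
      acc <- list(mu = numeric(q0), delta = numeric(q0), nu = numeric(n),
                  theta = 0, phi = 0)
    }

    if (iter > burn_in && (iter - burn_in) %% thin == 0L) {
      k <- (iter - burn_in) %/% thin
      dr$mu[k, ] <- exp(lmu)
      dr$delta[k, ] <- exp(ldelta)
      dr$phi[k, ] <- phi
      dr$s[k, ] <- s
      dr$nu[k, ] <- nu
      dr$theta[k, 1] <- theta
      if (regression) {
        dr$lambda[k, ] <- lambda
        dr$beta[k, ] <- beta
        dr$sigma2[k] <- sigma2
        dr$epsilon[k, ] <- ldelta - predict_trend(lmu, beta, cfg)
      }
    }
  }
  for (nm in names(acc)) tot_acc[[nm]] <- tot_acc[[nm]] + sum(acc[[nm]])
  denom <- n_iter
  acc_rates <- c(mu = tot_acc$mu / (q0 * denom),
                 delta = tot_acc$delta / (q0 * denom),
                 nu = tot_acc$nu / (n * denom),
                 theta = tot_acc$theta / denom,
                 phi = tot_acc$phi / denom)

  new_sc_chain(
    draws = dr,
    variant = if (regression) "spikes-regression" else "spikes-nonregression",
    gene_ids = ds$genes$gene_id[!ds$genes$is_spike],
    cell_ids = ds$cells$cell_id,
    batches = ds$cells$batch,
    n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
    cfg = cfg, hp = hp, acceptance = acc_rates)
}
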