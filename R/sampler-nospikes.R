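# Sampler for the no-spikes (horizontal integration) model. Without
# spike-ins the scale of mu and the cell factors is not identified, so the
# geometric mean of the constrained mean-expression parameters is fixed to
# an empirical anchor mu0; the reference gene whose value is determined by
# the constraint is re-drawn uniformly at every sweep.

#' Empirical geometric-mean anchor mu0
#'
#' Geometric mean of per-gene average normalized counts. Normalization uses
#' library-size factors (cell total counts over their geometric mean);
#' genes with zero total counts are always excluded (their empirical mean
#' is 0 and would make the geometric mean degenerate).
#'
#' @param ds an `expression_dataset`
#' @param genes optional logical mask restricting which genes enter the
#'   computation (the sampler passes the constraint set)
#' @return positive scalar
#' @export
compute_mu0 <- function(ds, genes = NULL) {
  counts <- ds$counts
  tot <- rowSums(counts)
  keep <- tot > 0
  if (!is.null(genes)) keep <- keep & genes
  if (!any(keep)) stop("no genes with positive total counts")
  ctot <- colSums(counts)
  if (any(ctot == 0)) ctot[ctot == 0] <- 1
  sf <- ctot / exp(mean(log(ctot)))
  m <- rowMeans(sweep(counts, 2, sf, "/"))[keep]
  exp(mean(log(m)))
}

#' Constraint-set membership
#'
#' A gene participates in the geometric-mean identifiability constraint iff
#' its average count across all cells is at least 1 (genes averaging less
#' than 1 count per cell are excluded and receive an independent log-Normal
#' prior instead).
#'
#' @param ds an `expression_dataset`
#' @return logical vector, one entry per gene
#' @export
constraint_set <- function(ds) {
  cs <- unname(rowMeans(ds$counts) >= 1)
  if (!any(cs)) stop("constraint set is empty (no gene averages >= 1 count/cell)")
  cs
}

#' Reference-gene value under the identifiability constraint
#'
#' The reference gene's log mean is the deterministic point mass
#' log(mu_r) = q_c log(mu0) - sum of the other constrained log means.
#'
#' @param mu_others mean parameters of the other constrained genes
#' @param mu0 anchor
#' @param q_c constraint-set size (defaults to `length(mu_others) + 1`)
#' @return positive scalar mu_r
#' @export
reference_value <- function(mu_others, mu0, q_c = length(mu_others) + 1L) {
  lr <- q_c * log(mu0) - sum(log(mu_others))
  if (!is.finite(lr) || abs(lr) > 700) stop("reference value overflow")
  exp(lr)
}

#' Conditional prior of one constrained log mean
#'
#' Under the correlated (rank-deficient) Gaussian prior on the constrained
#' log means, the conditional of log(mu_i) given all constrained genes
#' except i and the reference r is Normal with mean
#' (q_c log(mu0) - sum(log mu_{-i,r})) / 2 and variance a_mu2 / 2.
#'
#' @param i gene index (must differ from the reference)
#' @param mu vector of mean parameters over the constraint set
#' @param r reference index within the same vector
#' @param mu0 anchor
#' @param a_mu2 marginal prior variance
#' @return list with `mean` and `variance` of log(mu_i)
#' @export
conditional_prior_mu <- function(i, mu, r, mu0, a_mu2) {
  if (i == r) stop("conditional prior is undefined for the reference gene")
  q_c <- length(mu)
  m <- (q_c * log(mu0) - sum(log(mu[-c(i, r)]))) / 2
  list(mean = m, variance = a_mu2 / 2)
}

#' Draw the reference gene
#'
#' Uniform draw over the constraint set; re-drawn at every MCMC sweep so no
#' single gene's posterior inherits the distortion a fixed reference causes.
#'
#' @param constrained logical constraint-set mask
#' @return gene index
#' @export
pick_reference <- function(constrained) {
  idx <- which(constrained)
  if (!length(idx)) stop("constraint set is empty")
  if (length(idx) == 1L) return(idx)
  idx[sample.int(length(idx), 1L)]
}

# fast single-point trend evaluation (avoids matrix construction in the
# gene-sequential mu loop)
trend_point <- function(x, beta, cfg) {
  beta[1] + beta[2] * x +
    sum(beta[-(1:2)] * exp(-0.5 * ((x - cfg$locations) / cfg$scales)^2))
}

# -- block log-targets (no spikes; log-scale, Jacobian included) ------------

# single-gene mu target; `lsum_others` = sum of constrained log-means
# excluding genes i and r (ignored for unconstrained genes)
mu_target_nospikes_i <- function(lmu_i, x_i, xsum_i, idelta_i, nu,
                                 constrained_i, lsum_others, q_c, lmu0,
                                 ldelta_i, lambda_i, f_i, sigma2, hp,
                                 regression) {
  val <- xsum_i * lmu_i -
    sum((x_i + idelta_i) * log(nu * exp(lmu_i) + idelta_i))
  if (constrained_i) {
    m <- (q_c * lmu0 - lsum_others) / 2
    val <- val - (lmu_i - m)^2 / hp$a_mu2        # variance a_mu2/2
  } else {
    val <- val - lmu_i^2 / (2 * hp$a_mu2)
  }
  if (regression) val <- val - lambda_i * (ldelta_i - f_i)^2 / (2 * sigma2)
  val
}

delta_block_target_nospikes <- function(ldelta, lmu, lambda, beta, sigma2,
                                        nu, pre, hp, cfg) {
  delta_block_target(ldelta, lmu, lambda, beta, sigma2, nu, pre, hp, cfg)
}

nu_block_target_nospikes <- function(lnu, mu, delta, s, theta_cell, pre) {
  nu <- exp(lnu)
  idelta <- 1 / delta
  denom <- log(outer(mu, nu) + idelta)
  unname(pre$cs * lnu - colSums((pre$counts + idelta) * denom) +
    (1 / theta_cell) * lnu - nu / (s * theta_cell))
}

theta_block_target_k <- function(ltheta, nu_k, s_k, hp) {
  theta_block_target(ltheta, nu_k, s_k, hp)
}

#' Fit the no-spikes (horizontal integration) model
#'
#' Variant of the sampler for datasets without spike-in genes: technical
#' noise is identified through replication across `K >= 2` batches, with
#' batch-specific technical parameters theta_k, and the scale of the mean
#' parameters is pinned by fixing the geometric mean of the constrained mu
#' to the empirical anchor mu0 (held exactly in every draw, via a reference
#' gene re-drawn each sweep).
#'
#' @inheritParams fit_spikes
#' @param ds an [expression_dataset()] with biological genes only and batch
#'   labels; a single batch triggers a warning (technical and biological
#'   variability are then not separately identified).
#' @return an `sc_chain` carrying `mu0`, the constraint mask and the
#'   per-draw reference gene in addition to the parameter draws.
#' @export
fit_nospikes <- function(ds, hp = hyper_params(), regression = TRUE,
                         cfg = regression_config(eta = hp$eta),
                         n_iter = 20000, burn_in = 10000, thin = 10, seed = 1) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (any(ds$genes$is_spike))
    stop("no-spikes model expects biological genes only; drop spike-in rows first")
  batches <- unique(ds$cells$batch)
  K <- length(batches)
  if (K < 2)
    warning("single batch: technical and biological variability are not ",
            "separately identified in the no-spikes model")
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1,
            (n_iter - burn_in) %% thin == 0)
  set.seed(seed)
  counts <- ds$counts
  dimnames(counts) <- NULL
  q <- nrow(counts); n <- ncol(counts)
  bidx <- match(ds$cells$batch, batches)
  cset <- constraint_set(ds)
  q_c <- sum(cset)
  mu0 <- compute_mu0(ds, genes = cset)
  lmu0 <- log(mu0)
  pre <- list(counts = counts, rs = rowSums(counts), cs = colSums(counts))
  tcounts <- t(counts)                       # column access per gene

  ini <- init_state_common(counts)
  lmu <- log(ini$mu); ldelta <- log(ini$delta)
  # rescale the constrained block so the identifiability restriction holds
  lmu[cset] <- lmu[cset] - mean(lmu[cset]) + lmu0
  s <- rep(1, n); nu <- s
  theta <- rep(0.5, K)
  lambda <- rep(1, q); sigma2 <- 1
  if (regression) {
    cfg <- set_kernels(cfg, lmu)
    hp <- resolve_beta_prior(hp, cfg$L)
    beta <- rep(0, cfg$L + 2)
  } else {
    cfg <- NULL
    beta <- NULL
  }

  n_store <- (n_iter - burn_in) %/% thin
  dr <- list(mu = matrix(NA_real_, n_store, q),
             delta = matrix(NA_real_, n_store, q),
             epsilon = if (regression) matrix(NA_real_, n_store, q) else NULL,
             lambda = if (regression) matrix(NA_real_, n_store, q) else NULL,
             s = matrix(NA_real_, n_store, n),
             nu = matrix(NA_real_, n_store, n),
             theta = matrix(NA_real_, n_store, K),
             beta = if (regression) matrix(NA_real_, n_store, cfg$L + 2) else NULL,
             sigma2 = if (regression) rep(NA_real_, n_store) else NULL)
  ref_draws <- integer(n_store)

  ls_mu <- rep(log(0.5), q); ls_delta <- rep(log(0.5), q)
  ls_nu <- rep(log(0.3), n); ls_theta <- rep(log(0.3), K)
  acc <- list(mu = numeric(q), delta = numeric(q), nu = numeric(n),
              theta = numeric(K))
  tot_acc <- list(mu = 0, delta = 0, nu = 0, theta = 0)
  window <- 50L
  idelta <- exp(-ldelta)
  theta_cell <- theta[bidx]

  for (iter in seq_len(n_iter)) {
    r <- pick_reference(cset)

    # mu: gene-sequential (constrained genes couple through the log-sum)
    f_all <- if (regression) predict_trend(lmu, beta, cfg) else NULL
    for (i in seq_len(q)) {
      if (i == r) next
      prop <- lmu[i] + stats::rnorm(1) * exp(ls_mu[i])
      lsum_others <- if (cset[i]) sum(lmu[cset]) - lmu[i] - lmu[r] else 0
      f_cur <- if (regression) f_all[i] else NULL
      f_prop <- if (regression)
        trend_point(prop, beta, cfg) else NULL
      x_i <- tcounts[, i]
      cur_t <- mu_target_nospikes_i(lmu[i], x_i, pre$rs[i], idelta[i], nu,
                                    cset[i], lsum_others, q_c, lmu0,
                                    ldelta[i], lambda[i], f_cur, sigma2,
                                    hp, regression)
      new_t <- mu_target_nospikes_i(prop, x_i, pre$rs[i], idelta[i], nu,
                                    cset[i], lsum_others, q_c, lmu0,
                                    ldelta[i], lambda[i], f_prop, sigma2,
                                    hp, regression)
      if (log(stats::runif(1)) < new_t - cur_t) {
        lmu[i] <- prop
        acc$mu[i] <- acc$mu[i] + 1
        if (regression) f_all[i] <- f_prop
        if (cset[i]) {
          lmu[r] <- q_c * lmu0 - (sum(lmu[cset]) - lmu[r])
          if (regression) f_all[r] <- trend_point(lmu[r], beta, cfg)
        }
      }
    }

    # delta (vectorized; conditionals independent given mu, nu)
    prop <- ldelta + stats::rnorm(q) * exp(ls_delta)
    cur_t <- delta_block_target_nospikes(ldelta, lmu, lambda, beta, sigma2,
                                         nu, pre, hp, cfg)
    new_t <- delta_block_target_nospikes(prop, lmu, lambda, beta, sigma2,
                                         nu, pre, hp, cfg)
    ok <- log(stats::runif(q)) < new_t - cur_t
    ldelta[ok] <- prop[ok]
    idelta <- exp(-ldelta)
    acc$delta <- acc$delta + ok

    if (regression) {
      f <- predict_trend(lmu, beta, cfg)
      lambda <- draw_lambda(ldelta, f, sigma2, cfg$eta)
      bs <- draw_beta_sigma2(design_matrix(lmu, cfg), ldelta, lambda, hp)
      beta <- bs$beta; sigma2 <- bs$sigma2
    }

    # s (exact GIG draw, batch-specific theta)
    s <- rgig(n, p = hp$a_s - 1 / theta_cell, a = 2 * hp$b_s,
              b = 2 * nu / theta_cell)

    # nu (per cell)
    lnu <- log(nu)
    prop <- lnu + stats::rnorm(n) * exp(ls_nu)
    cur_t <- nu_block_target_nospikes(lnu, exp(lmu), exp(ldelta), s,
                                      theta_cell, pre)
    new_t <- nu_block_target_nospikes(prop, exp(lmu), exp(ldelta), s,
                                      theta_cell, pre)
    ok <- log(stats::runif(n)) < new_t - cur_t
    lnu[ok] <- prop[ok]
    nu <- exp(lnu)
    acc$nu <- acc$nu + ok

    # theta_k (per batch)
    for (k in seq_len(K)) {
      cells_k <- bidx == k
      lth <- log(theta[k])
      prop <- lth + stats::rnorm(1) * exp(ls_theta[k])
      lr <- theta_block_target_k(prop, nu[cells_k], s[cells_k], hp) -
        theta_block_target_k(lth, nu[cells_k], s[cells_k], hp)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        theta[k] <- exp(prop)
        acc$theta[k] <- acc$theta[k] + 1
      }
    }
    theta_cell <- theta[bidx]

    if (iter <= burn_in && iter %% window == 0L) {
      if (regression) cfg <- refresh_locations(cfg, lmu, iter, burn_in)
      ls_mu <- adapt_logsd(ls_mu, acc$mu, window, iter)
      ls_delta <- adapt_logsd(ls_delta, acc$delta, window, iter)
      ls_nu <- adapt_logsd(ls_nu, acc$nu, window, iter)
      ls_theta <- adapt_logsd(ls_theta, acc$theta, window, iter)
      for (nm in names(acc)) tot_acc[[nm]] <- tot_acc[[nm]] + sum(acc[[nm]])
      acc <- list(mu = numeric(q), delta = numeric(q), nu = numeric(n),
                  theta = numeric(K))
    }

    if (iter > burn_in && (iter - burn_in) %% thin == 0L) {
      k <- (iter - burn_in) %/% thin
      dr$mu[k, ] <- exp(lmu)
      dr$delta[k, ] <- exp(ldelta)
      dr$s[k, ] <- s
      dr$nu[k, ] <- nu
      dr$theta[k, ] <- theta
      ref_draws[k] <- r
      if (regression) {
        dr$lambda[k, ] <- lambda
        dr$beta[k, ] <- beta
        dr$sigma2[k] <- sigma2
        dr$epsilon[k, ] <- ldelta - predict_trend(lmu, beta, cfg)
      }
    }
  }
  for (nm in names(acc)) tot_acc[[nm]] <- tot_acc[[nm]] + sum(acc[[nm]])
  acc_rates <- c(mu = tot_acc$mu / ((q - 1) * n_iter),
                 delta = tot_acc$delta / (q * n_iter),
                 nu = tot_acc$nu / (n * n_iter),
                 theta = tot_acc$theta / (K * n_iter))

  new_sc_chain(
    draws = dr,
    variant = if (regression) "nospikes-regression" else "nospikes-nonregression",
    gene_ids = ds$genes$gene_id, cell_ids = ds$cells$cell_id,
    batches = ds$cells$batch,
    n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
    cfg = cfg, hp = hp, acceptance = acc_rates,
    mu0 = mu0, constrained = cset, reference_draws = ref_draws)
}
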