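test_that("marginal log-likelihood matches a term-by-term oracle", {
  # 2 bio genes x 2 cells + 1 spike, all parameters 1, all counts 0
  counts <- matrix(0L, 3, 2)
  ds <- expression_dataset(counts, gene_ids = c("g1", "g2", "sp"),
                           is_spike = c(FALSE, FALSE, TRUE),
                           spike_input = c(NA, NA, 1))
  one <- rep(1, 2)
  got <- marginal_loglik(ds, mu = one, delta = one, phi = one, s = one,
                         nu = one, theta = 1)
  expected <- 4 * dnbinom(0, size = 1, mu = 1, log = TRUE) +
    2 * dpois(0, 1, log = TRUE) +
    2 * dgamma(1, shape = 1, rate = 1, log = TRUE)
  expect_equal(got, expected, tolerance = 1e-12)

  # permuting cells leaves the likelihood unchanged
  ds2 <- tiny_spikes_ds()
  st <- tiny_spikes_state()
  perm <- c(3, 1, 2)
  v1 <- marginal_loglik(ds2, st$mu, st$delta, st$phi, st$s, st$nu, st$theta)
  ds_p <- expression_dataset(ds2$counts[, perm],
                             gene_ids = ds2$genes$gene_id,
                             is_spike = ds2$genes$is_spike,
                             spike_input = ds2$genes$spike_input)
  v2 <- marginal_loglik(ds_p, st$mu, st$delta, st$phi[perm], st$s[perm],
                        st$nu[perm], st$theta)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("the negative binomial terms reach the Poisson limit", {
  counts <- matrix(c(0L, 3L, 7L, 1L), 2, 2)
  mu <- c(2, 5); cellfac <- c(1.1, 0.8)
  nb <- scdv:::nb_loglik_genes(counts, mu, delta = rep(1e-8, 2), cellfac)
  pois <- rowSums(dpois(counts, outer(mu, cellfac), log = TRUE))
  expect_equal(nb, pois, tolerance = 1e-4)
})

test_that("every Metropolis block targets the joint posterior (spikes)", {
  ds <- tiny_spikes_ds()
  st <- tiny_spikes_state()
  hp <- scdv:::resolve_beta_prior(hyper_params(), 10)
  cfg <- scdv:::set_kernels(regression_config(), c(-1, 2))
  pre <- precomp(scdv:::bio_counts(ds))
  spre <- list(cs = colSums(scdv:::spike_counts(ds)),
               musum = sum(ds$genes$spike_input[ds$genes$is_spike]))
  jp <- function(s) joint_log_post_spikes(s, ds, hp, cfg)
  lmu <- log(st$mu); ld <- log(st$delta); cf <- st$phi * st$nu

  # mu, each gene
  for (i in 1:2) {
    prop <- lmu; prop[i] <- lmu[i] + 0.37
    st2 <- st; st2$mu <- exp(prop)
    block <- scdv:::mu_block_target(prop, ld, st$lambda, st$beta, st$sigma2,
                                    cf, pre, hp, cfg) -
      scdv:::mu_block_target(lmu, ld, st$lambda, st$beta, st$sigma2,
                             cf, pre, hp, cfg)
    expect_equal(block[i], jp(st2) - jp(st) + 0.37, tolerance = 1e-10)
  }
  # delta, each gene
  for (i in 1:2) {
    prop <- ld; prop[i] <- ld[i] - 0.41
    st2 <- st; st2$delta <- exp(prop)
    block <- scdv:::delta_block_target(prop, lmu, st$lambda, st$beta,
                                       st$sigma2, cf, pre, hp, cfg) -
      scdv:::delta_block_target(ld, lmu, st$lambda, st$beta, st$sigma2,
                                cf, pre, hp, cfg)
    expect_equal(block[i], jp(st2) - jp(st) - 0.41, tolerance = 1e-10)
  }
  # nu, each cell
  lnu <- log(st$nu)
  for (j in 1:3) {
    prop <- lnu; prop[j] <- lnu[j] + 0.29
    st2 <- st; st2$nu <- exp(prop)
    block <- scdv:::nu_block_target_spikes(prop, st$mu, st$delta, st$phi,
                                           st$s, st$theta, pre, spre) -
      scdv:::nu_block_target_spikes(lnu, st$mu, st$delta, st$phi, st$s,
                                    st$theta, pre, spre)
    expect_equal(block[j], jp(st2) - jp(st) + 0.29, tolerance = 1e-10)
  }
  # theta
  st2 <- st; st2$theta <- st$theta * 1.4
  block <- scdv:::theta_block_target(log(st2$theta), st$nu, st$s, hp) -
    scdv:::theta_block_target(log(st$theta), st$nu, st$s, hp)
  expect_equal(block, jp(st2) - jp(st) + log(1.4), tolerance = 1e-10)
  # phi (block move on the simplex; no Jacobian, target in phi directly)
  p2 <- st$phi * c(1.13, 0.95, 0.92); p2 <- 3 * p2 / sum(p2)
  st2 <- st; st2$phi <- p2
  block <- scdv:::phi_block_target(p2, st$mu, st$delta, st$nu, pre, hp) -
    scdv:::phi_block_target(st$phi, st$mu, st$delta, st$nu, pre, hp)
  expect_equal(block, jp(st2) - jp(st), tolerance = 1e-10)
  # s conditional has the generalized-inverse-Gaussian shape
  st2 <- st; st2$s[1] <- st$s[1] * 1.5
  gig_ld <- function(s, p, a, b) (p - 1) * log(s) - 0.5 * (a * s + b / s)
  p <- hp$a_s - 1 / st$theta; a <- 2 * hp$b_s; b <- 2 * st$nu[1] / st$theta
  expect_equal(gig_ld(st2$s[1], p, a, b) - gig_ld(st$s[1], p, a, b),
               jp(st2) - jp(st), tolerance = 1e-10)
})

test_that("the delta conditional is proper for a single zero-count cell", {
  # one cell with count 0: the unnormalized conditional must integrate
  # finitely over (0, 100]
  cfg <- NULL
  hp <- hyper_params()
  pre <- precomp(matrix(0L, 1, 1))
  f <- function(delta) {
    vapply(delta, function(d)
      exp(scdv:::delta_block_target(log(d), lmu = log(2), lambda = 1,
                                    beta = NULL, sigma2 = 1, cellfac = 1,
                                    pre = pre, hp = hp, cfg = NULL)),
      numeric(1))
  }
  z <- integrate(f, 1e-8, 100)
  expect_true(is.finite(z$value) && z$value > 0)
})

test_that("lambda Gibbs draws follow the conjugate Gamma", {
  set.seed(11)
  eta <- 5; sigma2 <- 0.8
  # residual zero: Gamma((eta+1)/2, eta/2) with mean (eta+1)/eta
  d <- scdv:::draw_lambda(rep(0, 40000), rep(0, 40000), sigma2, eta)
  expect_equal(mean(d), (eta + 1) / eta, tolerance = 0.02)
  expect_equal(var(d), ((eta + 1) / 2) / (eta / 2)^2, tolerance = 0.05)
  # general residuals match the derived rate
  resid <- c(0.5, -1.2, 2)
  d2 <- replicate(20000, scdv:::draw_lambda(resid, rep(0, 3), sigma2, eta))
  a_star <- (eta + 1) / 2
  b_star <- (eta + resid^2 / sigma2) / 2
  expect_equal(rowMeans(d2), a_star / b_star, tolerance = 0.03)
  # Student-t -> Normal limit: lambda concentrates at 1
  d3 <- scdv:::draw_lambda(rep(0.3, 10000), rep(0, 10000), 1, 1e6)
  expect_lt(var(d3), 0.01)
  expect_error(scdv:::draw_lambda(0, 0, -1, 5), "sigma2")
})

test_that("beta/sigma2 joint draw matches ridge regression and its moments", {
  set.seed(12)
  q0 <- 30; L <- 4
  X <- cbind(1, rnorm(q0), matrix(runif(q0 * L), q0))
  Y <- rnorm(q0)
  hp <- scdv:::resolve_beta_prior(hyper_params(), L)
  # lambda = 1, V = I, m = 0: conditional mean is the ridge solution
  d <- scdv:::draw_beta_sigma2(X, Y, rep(1, q0), hp)
  ridge <- solve(crossprod(X) + diag(L + 2), crossprod(X, Y))
  expect_equal(d$m_star, drop(ridge), tolerance = 1e-10)
  expect_equal(d$a_star, hp$a_sigma2 + q0 / 2)
  # repeated draws: sample mean converges to m_star
  B <- vapply(1:4000, function(i)
    scdv:::draw_beta_sigma2(X, Y, rep(1, q0), hp)$beta, numeric(L + 2))
  expect_equal(rowMeans(B), drop(ridge), tolerance = 0.05)
  # fewer genes than coefficients: prior keeps the draw proper
  Xs <- X[1:3, ]
  d2 <- scdv:::draw_beta_sigma2(Xs, Y[1:3], rep(1, 3), hp)
  expect_true(all(is.finite(d2$beta)) && d2$sigma2 > 0)
})

test_that("GIG sampler matches numerically integrated moments", {
  gig_ld <- function(x, p, a, b) (p - 1) * log(x) - 0.5 * (a * x + b / x)
  cases <- list(c(p = -1.5, a = 2, b = 3), c(p = 0.5, a = 1, b = 0.4),
                c(p = 2, a = 0.5, b = 5))
  set.seed(13)
  for (cs in cases) {
    x <- rgig(100000, cs["p"], cs["a"], cs["b"])
    norm <- integrate(function(t) exp(gig_ld(t, cs["p"], cs["a"], cs["b"])),
                      0, Inf)$value
    m1 <- integrate(function(t) t * exp(gig_ld(t, cs["p"], cs["a"], cs["b"])),
                    0, Inf)$value / norm
    m2 <- integrate(function(t) t^2 * exp(gig_ld(t, cs["p"], cs["a"], cs["b"])),
                    0, Inf)$value / norm
    expect_equal(mean(x), m1, tolerance = 0.02)
    expect_equal(mean(x^2), m2, tolerance = 0.05)
  }
  expect_error(rgig(1, 1, -1, 1), "a > 0")
})

test_that("chain bookkeeping: schedule, determinism, stored invariants", {
  set.seed(14)
  tr <- simulation_truth(n_genes = 8, n_cells = 6, n_spikes = 2, seed = 3)
  ds <- simulate_spikes(tr, seed = 4)
  ch <- fit_spikes(ds, n_iter = 400, burn_in = 200, thin = 4, seed = 9)
  expect_equal(n_draws(ch), 50)
  expect_true(all(ch$draws$mu > 0) && all(ch$draws$delta > 0) &&
                all(ch$draws$lambda > 0) && all(ch$draws$s > 0) &&
                all(ch$draws$nu > 0) && all(ch$draws$theta > 0) &&
                all(ch$draws$sigma2 > 0))
  # epsilon = log(delta) - f(mu) in every stored draw
  for (k in c(1, 25, 50)) {
    expect_equal(ch$draws$epsilon[k, ],
                 log(ch$draws$delta[k, ]) -
                   predict_trend(log(ch$draws$mu[k, ]), ch$draws$beta[k, ],
                                 ch$cfg),
                 tolerance = 1e-12)
  }
  # phi preserves its sum in every draw
  expect_equal(rowSums(ch$draws$phi), rep(6, 50), tolerance = 1e-10)
  # same seed -> identical chain; different seed -> different
  ch2 <- fit_spikes(ds, n_iter = 400, burn_in = 200, thin = 4, seed = 9)
  expect_identical(ch$draws, ch2$draws)
  ch3 <- fit_spikes(ds, n_iter = 400, burn_in = 200, thin = 4, seed = 10)
  expect_false(identical(ch$draws$mu, ch3$draws$mu))
  # schedule validation
  expect_error(fit_spikes(ds, n_iter = 100, burn_in = 200), "n_iter")
  expect_error(fit_spikes(ds, n_iter = 403, burn_in = 200, thin = 4))
})

test_that("zero counts pull the posterior of mu toward small values", {
  counts <- matrix(0L, 3, 8)
  counts[3, ] <- 5L  # spike-in detected so nu stays identified
  ds <- expression_dataset(counts, gene_ids = c("g1", "g2", "sp"),
                           is_spike = c(FALSE, FALSE, TRUE),
                           spike_input = c(NA, NA, 5))
  ch <- fit_spikes(ds, n_iter = 2000, burn_in = 1000, thin = 2, seed = 2)
  expect_lt(median(ch$draws$mu[, 1]), 1)
})

test_that("regression prior shrinks over-dispersion errors for sparse genes", {
  tr <- simulation_truth(n_genes = 200, n_cells = 50, seed = 21)
  ds <- simulate_spikes(tr, seed = 22)
  ch_reg <- fit_spikes(ds, regression = TRUE, n_iter = 1500, burn_in = 750,
                       thin = 3, seed = 23)
  ch_non <- fit_spikes(ds, regression = FALSE, n_iter = 1500, burn_in = 750,
                       thin = 3, seed = 23)
  low <- tr$mu <= quantile(tr$mu, 1 / 3)
  mae <- function(ch) {
    est <- log(apply(ch$draws$delta[, low], 2, median))
    mean(abs(est - log(tr$delta[low])))
  }
  expect_lte(mae(ch_reg), mae(ch_non))
})

test_that("chain serialization round-trips through the directory container", {
  tr <- simulation_truth(n_genes = 8, n_cells = 5, n_spikes = 2, seed = 31)
  ds <- simulate_spikes(tr, seed = 32)
  ch <- fit_spikes(ds, n_iter = 200, burn_in = 100, thin = 2, seed = 33)
  dir <- file.path(withr::local_tempdir(), "chain")
  write_chain(ch, dir)
  back <- read_chain(dir)
  expect_equal(back$draws$mu, ch$draws$mu, tolerance = 1e-12)
  expect_equal(back$draws$epsilon, ch$draws$epsilon, tolerance = 1e-12)
  expect_equal(back$seed, ch$seed)
  expect_equal(back$variant, ch$variant)
  expect_equal(back$cfg$locations, ch$cfg$locations, tolerance = 1e-12)
  expect_equal(glance(back)$n_draws, n_draws(ch))
})
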