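test_that("mu0 is the geometric mean of normalized per-gene means", {
  # equal library sizes: size factors are 1, means are row means
  ds <- expression_dataset(rbind(c(1, 1), c(4, 4)), batch = c("b1", "b2"))
  expect_equal(compute_mu0(ds), 2)
  # all-zero genes are excluded
  ds2 <- expression_dataset(rbind(c(1, 1), c(4, 4), c(0, 0)),
                            batch = c("b1", "b2"))
  expect_equal(compute_mu0(ds2), 2)
  expect_error(compute_mu0(expression_dataset(matrix(0L, 2, 2))), "positive")
  # equal scaling of all counts scales mu0 accordingly
  ds3 <- expression_dataset(rbind(c(3, 3), c(12, 12)), batch = c("b1", "b2"))
  expect_equal(compute_mu0(ds3), 6)
})

test_that("constraint set uses the 1-count-per-cell boundary inclusively", {
  counts <- rbind(c(1, 1, 1, 1),   # mean 1.0 -> included
                  c(1, 1, 1, 0),   # mean 0.75 -> excluded
                  c(9, 9, 9, 9))
  ds <- expression_dataset(counts, batch = c("b1", "b1", "b2", "b2"))
  expect_equal(constraint_set(ds), c(TRUE, FALSE, TRUE))
  ds_all <- expression_dataset(matrix(2L, 3, 4), batch = rep(c("b1", "b2"), 2))
  expect_true(all(constraint_set(ds_all)))
})

test_that("reference value is the deterministic point mass", {
  expect_equal(reference_value(mu_others = 1, mu0 = 2, q_c = 2), 4)
  expect_equal(reference_value(rep(3, 9), mu0 = 3, q_c = 10), 3)
  expect_error(reference_value(1e-300, mu0 = 1e300, q_c = 2), "overflow")
})

test_that("conditional prior matches the degenerate-normal linear algebra", {
  # variance is a_mu2/2 regardless of the values
  out <- conditional_prior_mu(1, mu = c(2, 5, 0.3, 7), r = 2, mu0 = 1.7,
                              a_mu2 = 0.8)
  expect_equal(out$variance, 0.4)
  # symmetric case: all other log-means zero, mu0 = 1 -> mean 0
  out2 <- conditional_prior_mu(1, mu = c(5, 1, 1, 1), r = 2, mu0 = 1,
                               a_mu2 = 0.5)
  expect_equal(out2$mean, 0)
  expect_error(conditional_prior_mu(2, mu = c(1, 1, 1), r = 2, mu0 = 1,
                                    a_mu2 = 1), "reference")

  # oracle at q = 10: condition the non-degenerate marginal of log(mu[-r])
  # (covariance a (I - 11'/q)) on all components but i
  q <- 10; a <- 0.7; lmu0 <- log(1.3)
  set.seed(4)
  lmu <- rnorm(q)
  r <- 4; i <- 6
  S <- a * (diag(q - 1) - matrix(1, q - 1, q - 1) / q)  # cov of log mu[-r]
  keep <- setdiff(seq_len(q), r)
  ii <- which(keep == i)
  rest <- setdiff(seq_along(keep), ii)
  m_cond <- lmu0 + S[ii, rest] %*% solve(S[rest, rest],
                                         lmu[keep[rest]] - lmu0)
  v_cond <- S[ii, ii] - S[ii, rest] %*% solve(S[rest, rest], S[rest, ii])
  got <- conditional_prior_mu(i, mu = exp(lmu), r = r, mu0 = exp(lmu0),
                              a_mu2 = a)
  expect_equal(got$mean, drop(m_cond), tolerance = 1e-10)
  expect_equal(got$variance, drop(v_cond), tolerance = 1e-10)

  # reference-gene conditional variance is identically zero
  Sfull <- a * (diag(q) - matrix(1, q, q) / q)
  vr <- Sfull[r, r] - Sfull[r, -r] %*% MASS::ginv(Sfull[-r, -r]) %*% Sfull[-r, r]
  expect_equal(drop(vr), 0, tolerance = 1e-10)
})

test_that("constructive prior sampling reproduces the correlated covariance", {
  # sample independent log-Normals, project onto the constraint surface
  q <- 6; a <- 0.5; lmu0 <- 0.3
  set.seed(5)
  z <- matrix(rnorm(30000 * q, 0, sqrt(a)), ncol = q)
  proj <- z - rowMeans(z) + lmu0
  target <- a * (diag(q) - matrix(1, q, q) / q)
  expect_lt(norm(cov(proj) - target, "F"), 0.05)
  expect_equal(colMeans(proj), rep(lmu0, q), tolerance = 0.02)
  # every projected draw satisfies the restriction exactly
  expect_equal(rowMeans(proj)[1:100], rep(lmu0, 100), tolerance = 1e-12)
})

test_that("the stochastic reference is uniform over the constraint set", {
  cset <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  set.seed(6)
  draws <- replicate(10000, pick_reference(cset))
  expect_true(all(draws %in% which(cset)))
  freq <- table(factor(draws, levels = which(cset))) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 3 * se + 0.005))
  expect_equal(pick_reference(c(FALSE, TRUE, FALSE)), 2)
  expect_error(pick_reference(rep(FALSE, 3)), "empty")
})

test_that("every no-spikes Metropolis block targets the joint posterior", {
  ds <- tiny_nospikes_ds()
  hp <- scdv:::resolve_beta_prior(hyper_params(), 10)
  cfg <- scdv:::set_kernels(regression_config(), c(-1, 2))
  cset <- constraint_set(ds)
  mu0 <- compute_mu0(ds, genes = cset)
  r <- 2
  set.seed(8)
  st <- list(mu = c(4, 3, 6), delta = c(0.4, 0.8, 0.3),
             lambda = c(1, 0.9, 1.2), s = c(1, 0.9, 1.1, 1),
             nu = c(1.1, 0.8, 1, 1.2), theta = c(0.3, 0.5),
             beta = rnorm(12) * 0.1, sigma2 = 0.8,
             reference = r, constrained = cset)
  lmu <- log(st$mu)
  lmu[r] <- sum(cset) * log(mu0) - sum(lmu[cset][-r])
  st$mu <- exp(lmu)
  ld <- log(st$delta)
  pre <- precomp(ds$counts)
  tc <- st$theta[c(1, 1, 2, 2)]
  jp <- function(s) joint_log_post_nospikes(s, ds, hp, cfg, mu0)

  # constrained mu (gene 1; reference held fixed during the step)
  for (i in c(1, 3)) {
    prop <- lmu[i] + 0.31
    lsum <- sum(lmu[cset]) - lmu[i] - lmu[r]
    b1 <- scdv:::mu_target_nospikes_i(
      prop, ds$counts[i, ], pre$rs[i], 1 / st$delta[i], st$nu, TRUE, lsum,
      sum(cset), log(mu0), ld[i], st$lambda[i],
      scdv:::trend_point(prop, st$beta, cfg), st$sigma2, hp, TRUE)
    b0 <- scdv:::mu_target_nospikes_i(
      lmu[i], ds$counts[i, ], pre$rs[i], 1 / st$delta[i], st$nu, TRUE, lsum,
      sum(cset), log(mu0), ld[i], st$lambda[i],
      scdv:::trend_point(lmu[i], st$beta, cfg), st$sigma2, hp, TRUE)
    st2 <- st; lmu2 <- lmu; lmu2[i] <- prop; st2$mu <- exp(lmu2)
    expect_equal(b1 - b0, jp(st2) - jp(st) + 0.31, tolerance = 1e-10)
  }
  # delta
  for (i in 1:3) {
    propd <- ld; propd[i] <- ld[i] + 0.47
    st2 <- st; st2$delta <- exp(propd)
    blk <- scdv:::delta_block_target_nospikes(propd, lmu, st$lambda, st$beta,
                                              st$sigma2, st$nu, pre, hp, cfg) -
      scdv:::delta_block_target_nospikes(ld, lmu, st$lambda, st$beta,
                                         st$sigma2, st$nu, pre, hp, cfg)
    expect_equal(blk[i], jp(st2) - jp(st) + 0.47, tolerance = 1e-10)
  }
  # nu
  lnu <- log(st$nu)
  for (j in 1:4) {
    propn <- lnu; propn[j] <- lnu[j] - 0.21
    st2 <- st; st2$nu <- exp(propn)
    blk <- scdv:::nu_block_target_nospikes(propn, st$mu, st$delta, st$s, tc,
                                           pre) -
      scdv:::nu_block_target_nospikes(lnu, st$mu, st$delta, st$s, tc, pre)
    expect_equal(blk[j], jp(st2) - jp(st) - 0.21, tolerance = 1e-10)
  }
  # theta per batch
  for (k in 1:2) {
    cells <- if (k == 1) 1:2 else 3:4
    st2 <- st; st2$theta[k] <- st$theta[k] * 1.3
    blk <- scdv:::theta_block_target_k(log(st2$theta[k]), st$nu[cells],
                                       st$s[cells], hp) -
      scdv:::theta_block_target_k(log(st$theta[k]), st$nu[cells],
                                  st$s[cells], hp)
    expect_equal(blk, jp(st2) - jp(st) + log(1.3), tolerance = 1e-10)
  }
  # s conditional shape (GIG with batch-specific theta)
  st2 <- st; st2$s[3] <- st$s[3] * 1.4
  gig_ld <- function(s, p, a, b) (p - 1) * log(s) - 0.5 * (a * s + b / s)
  p <- hp$a_s - 1 / st$theta[2]; a <- 2 * hp$b_s
  b <- 2 * st$nu[3] / st$theta[2]
  expect_equal(gig_ld(st2$s[3], p, a, b) - gig_ld(st$s[3], p, a, b),
               jp(st2) - jp(st), tolerance = 1e-10)
})

test_that("the identifiability restriction holds exactly in all draws", {
  tr <- simulation_truth(n_genes = 40, n_cells = 24, seed = 41)
  ds <- simulate_nospikes(tr, n_cells_per_batch = c(12, 12), seed = 42)
  ch <- fit_nospikes(ds, n_iter = 400, burn_in = 200, thin = 2, seed = 43)
  gm <- apply(ch$draws$mu[, ch$constrained, drop = FALSE], 1,
              function(m) mean(log(m)))
  expect_true(all(abs(gm - log(ch$mu0)) < 1e-10))
  expect_true(all(ch$reference_draws %in% which(ch$constrained)))
  # determinism
  ch2 <- fit_nospikes(ds, n_iter = 400, burn_in = 200, thin = 2, seed = 43)
  expect_identical(ch$draws, ch2$draws)
})

test_that("a single batch runs with a warning; labels permute theta", {
  tr <- simulation_truth(n_genes = 20, n_cells = 12, seed = 51)
  ds1 <- simulate_nospikes(tr, n_cells_per_batch = 12, seed = 52)
  expect_warning(fit_nospikes(ds1, n_iter = 60, burn_in = 30, thin = 1,
                              seed = 53), "single batch")
  # renaming batch labels leaves the chain invariant: only the partition
  # of cells into batches matters, and theta columns follow the cells
  ds2 <- simulate_nospikes(tr, n_cells_per_batch = c(6, 6), seed = 54)
  ch_a <- fit_nospikes(ds2, n_iter = 200, burn_in = 100, thin = 1, seed = 55)
  ds_ren <- expression_dataset(ds2$counts, gene_ids = ds2$genes$gene_id,
                               batch = c(rep("z", 6), rep("a", 6)))
  ch_b <- fit_nospikes(ds_ren, n_iter = 200, burn_in = 100, thin = 1,
                       seed = 55)
  expect_equal(ch_a$draws$theta, ch_b$draws$theta, tolerance = 1e-12)
  expect_equal(ch_b$batches, c(rep("z", 6), rep("a", 6)))
})

test_that("two seeded runs agree gene-wise (stochastic reference works)", {
  tr <- simulation_truth(n_genes = 60, n_cells = 40, seed = 61)
  ds <- simulate_nospikes(tr, n_cells_per_batch = c(20, 20), seed = 62)
  ch1 <- fit_nospikes(ds, n_iter = 1200, burn_in = 600, thin = 3, seed = 63)
  ch2 <- fit_nospikes(ds, n_iter = 1200, burn_in = 600, thin = 3, seed = 64)
  m1 <- log(apply(ch1$draws$mu, 2, median))
  m2 <- log(apply(ch2$draws$mu, 2, median))
  expect_gt(cor(m1, m2), 0.99)
  # no single gene is distorted beyond Monte Carlo noise
  expect_lt(max(abs(m1 - m2)), 0.5)
  expect_lt(median(abs(m1 - m2)), 0.1)
})

test_that("no-spikes and spikes fits agree on data containing spike-ins", {
  tr <- simulation_truth(n_genes = 120, n_cells = 50, seed = 71)
  ds <- simulate_spikes(tr, seed = 72)
  # give the cells two batch labels so the no-spikes model applies
  ds$cells$batch <- rep(c("b1", "b2"), length.out = 50)
  ch_sp <- fit_spikes(ds, n_iter = 1500, burn_in = 750, thin = 3, seed = 73)
  bio <- expression_dataset(scdv:::bio_counts(ds),
                            gene_ids = ch_sp$gene_ids,
                            batch = ds$cells$batch)
  ch_ns <- fit_nospikes(bio, n_iter = 1500, burn_in = 750, thin = 3,
                        seed = 74)
  msp <- log(apply(ch_sp$draws$mu, 2, median))
  mns <- log(apply(ch_ns$draws$mu, 2, median))
  dsp <- log(apply(ch_sp$draws$delta, 2, median))
  dns <- log(apply(ch_ns$draws$delta, 2, median))
  expect_gt(cor(msp, mns), 0.9)
  expect_gt(cor(dsp, dns), 0.9)
})
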