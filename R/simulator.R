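# Model-based simulator: draws synthetic datasets from the exact
# generative model (spikes and no-spikes variants) and runs the
# null/alternative validation protocol for the residual over-dispersion
# test (FPR, TPR, empirical FDR against the recorded truth).

#' Synthetic ground-truth parameters
#'
#' Generates a complete parameter set for the generative model. Defaults
#' emulate the features that motivate the regression prior: log means are
#' Normal(2, 1.5^2) on the natural-log scale (spanning roughly four orders
#' of magnitude of expression), log over-dispersion follows a decreasing
#' trend in log mean plus Student-t(5) residuals of scale 0.35, cell mRNA
#' content is Dirichlet-distributed around equality, s = 1, theta = 0.4,
#' and 10% of genes are spike-ins with inputs spanning four orders of
#' magnitude. All values are overridable.
#'
#' @param n_genes number of biological genes
#' @param n_cells number of cells (one batch; see [simulate_nospikes()] for
#'   multi-batch designs)
#' @param n_spikes number of spike-in genes (default 10% of `n_genes`)
#' @param mu,delta optional explicit parameter vectors
#' @param theta technical noise (scalar, or per batch for no-spikes use)
#' @param s cell scales (default all 1)
#' @param phi_conc Dirichlet concentration of the mRNA-content parameters
#' @param trend function mapping log(mu) to the trend of log(delta)
#' @param resid_scale,resid_df scale and degrees of freedom of the
#'   Student-t residuals around the trend
#' @param seed integer seed
#' @return list of class `simulation_truth`: all generative parameters plus
#'   empty perturbation bookkeeping (`perturbed`, `direction`, `log2fc`)
#' @export
simulation_truth <- function(n_genes = 500, n_cells = 50,
                             n_spikes = ceiling(n_genes / 10),
                             mu = NULL, delta = NULL, theta = 0.4, s = NULL,
                             phi_conc = 5,
                             trend = function(lmu) 0.5 - 0.4 * lmu,
                             resid_scale = 0.35, resid_df = 5, seed = 1) {
  set.seed(seed)
  if (is.null(mu)) mu <- exp(stats::rnorm(n_genes, mean = 2, sd = 1.5))
  if (is.null(delta)) {
    eps <- resid_scale * stats::rt(n_genes, df = resid_df)
    delta <- exp(trend(log(mu)) + eps)
  }
  if (is.null(s)) s <- rep(1, n_cells)
  g <- stats::rgamma(n_cells, shape = phi_conc, rate = 1)
  phi <- n_cells * g / sum(g)
  mu_spike <- 10^seq(-1, 3, length.out = max(n_spikes, 2))[seq_len(n_spikes)]
  structure(list(
    mu = unname(mu), delta = unname(delta), phi = phi, s = s, theta = theta,
    mu_spike = mu_spike, n_genes = n_genes, n_cells = n_cells,
    n_spikes = n_spikes, seed = seed,
    perturbed = integer(0), direction = integer(0), log2fc = 0),
    class = "simulation_truth")
}

#' Perturb over-dispersion parameters
#'
#' Selects `n_perturb` biological genes uniformly at random and multiplies
#' or divides (50/50) each gene's delta by `2^log2fc`, recording the
#' perturbed set and directions. `log2fc = 0` returns the truth unchanged
#' (the null model).
#'
#' @param truth a [simulation_truth()]
#' @param n_perturb number of genes to perturb
#' @param log2fc absolute log2 fold change (default 5)
#' @param seed seed for the gene/direction draws
#' @return modified `simulation_truth`
#' @export
perturb_overdispersion <- function(truth, n_perturb, log2fc = 5, seed = 1) {
  stopifnot(n_perturb <= truth$n_genes)
  if (log2fc == 0) return(truth)
  set.seed(seed)
  idx <- sort(sample.int(truth$n_genes, n_perturb))
  dir <- sample(c(-1L, 1L), n_perturb, replace = TRUE)
  truth$delta[idx] <- truth$delta[idx] * 2^(dir * log2fc)
  truth$perturbed <- idx
  truth$direction <- dir
  truth$log2fc <- log2fc
  truth
}

#' Simulate counts from the spikes generative model
#'
#' Draws nu_j ~ Gamma(1/theta, 1/(s_j theta)) and
#' rho_ij ~ Gamma(1/delta_i, 1/delta_i), then Poisson counts with mean
#' phi_j nu_j mu_i rho_ij for biological genes and nu_j mu_i for spike-ins
#' (so marginally, given the cell factors, biological counts are negative
#' binomial with variance m + delta m^2).
#'
#' @param truth a [simulation_truth()]
#' @param seed seed for the count draws
#' @return an [expression_dataset()] (single batch)
#' @export
simulate_spikes <- function(truth, seed = 1) {
  set.seed(seed)
  n <- truth$n_cells
  nu <- stats::rgamma(n, shape = 1 / truth$theta[1],
                      rate = 1 / (truth$s * truth$theta[1]))
  rho <- matrix(stats::rgamma(truth$n_genes * n,
                              shape = 1 / truth$delta, rate = 1 / truth$delta),
                truth$n_genes, n)
  bio_mean <- outer(truth$mu, truth$phi * nu) * rho
  spike_mean <- outer(truth$mu_spike, nu)
  counts <- rbind(
    matrix(stats::rpois(length(bio_mean), bio_mean), truth$n_genes, n),
    matrix(stats::rpois(length(spike_mean), spike_mean),
           truth$n_spikes, n))
  expression_dataset(
    counts,
    gene_ids = c(paste0("gene_", seq_len(truth$n_genes)),
                 paste0("spike_", seq_len(truth$n_spikes))),
    is_spike = rep(c(FALSE, TRUE), c(truth$n_genes, truth$n_spikes)),
    spike_input = c(rep(NA_real_, truth$n_genes), truth$mu_spike))
}

#' Simulate counts from the no-spikes generative model
#'
#' Multi-batch variant without spike-ins or the mRNA-content parameter:
#' counts are Poisson with mean nu_jk mu_i rho_ijk, where
#' nu_jk ~ Gamma(1/theta_k, 1/(s_jk theta_k)) with batch-specific
#' technical noise.
#'
#' @param truth a [simulation_truth()]; `truth$theta` is recycled to one
#'   value per batch
#' @param n_cells_per_batch integer vector of batch sizes
#' @param seed seed for the count draws
#' @return an [expression_dataset()] with batch labels and no spike-ins
#' @export
simulate_nospikes <- function(truth, n_cells_per_batch, seed = 1) {
  set.seed(seed)
  K <- length(n_cells_per_batch)
  theta <- rep_len(truth$theta, K)
  n <- sum(n_cells_per_batch)
  batch <- rep(paste0("batch", seq_len(K)), n_cells_per_batch)
  theta_cell <- rep(theta, n_cells_per_batch)
  s <- rep_len(truth$s, n)
  nu <- stats::rgamma(n, shape = 1 / theta_cell, rate = 1 / (s * theta_cell))
  rho <- matrix(stats::rgamma(truth$n_genes * n,
                              shape = 1 / truth$delta, rate = 1 / truth$delta),
                truth$n_genes, n)
  mean_mat <- outer(truth$mu, nu) * rho
  counts <- matrix(stats::rpois(length(mean_mat), mean_mat), truth$n_genes, n)
  expression_dataset(counts,
                     gene_ids = paste0("gene_", seq_len(truth$n_genes)),
                     batch = batch)
}

#' Confusion metrics of a differential call set against the truth
#'
#' FPR = false calls / true nulls, TPR = true calls / perturbed genes,
#' empirical FDR = false calls / all calls (0 when nothing is called).
#'
#' @param result an `sc_de_result` (typically from [test_residual()])
#' @param truth the `simulation_truth` used to generate the data
#' @return one-row tibble: `n_calls`, `tp`, `fp`, `fpr`, `tpr`, `fdr`,
#'   `efdr_achieved`
#' @export
evaluate_test <- function(result, truth) {
  gene_num <- match(result$gene_id, paste0("gene_", seq_len(truth$n_genes)))
  if (any(is.na(gene_num)))
    stop("result genes do not align with the simulation truth")
  is_alt <- gene_num %in% truth$perturbed
  tp <- sum(result$call & is_alt)
  fp <- sum(result$call & !is_alt)
  tibble::tibble(
    n_calls = tp + fp, tp = tp, fp = fp,
    fpr = if (sum(!is_alt) > 0) fp / sum(!is_alt) else 0,
    tpr = if (length(truth$perturbed) > 0) tp / length(truth$perturbed) else 0,
    fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
    efdr_achieved = attr(result, "efdr") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Null/alternative validation of the residual over-dispersion test
#'
#' For each sample size and repetition: simulate a reference group and
#' either an independent replicate from the same truth (null) or a
#' replicate from a perturbed truth (alternative), fit both groups with the
#' spikes regression model, run the residual over-dispersion test at the
#' default tolerance and EFDR target, and score the calls against the
#' truth.
#'
#' @param n_genes genes per dataset
#' @param n_perturb perturbed genes under the alternative
#' @param log2fc perturbation magnitude (|log2 fold change| of delta)
#' @param cells_per_group vector of sample sizes to sweep
#' @param reps repetitions per sample size
#' @param n_iter,burn_in,thin MCMC schedule for each fit
#' @param efdr_target EFDR target of the test
#' @param seed master seed; all per-run seeds derive from it
#' @return tidy tibble: one row per (model, sample size, rep) with the
#'   metrics of [evaluate_test()]
#' @export
run_validation <- function(n_genes = 500, n_perturb = 100, log2fc = 5,
                           cells_per_group = c(25, 50, 100), reps = 2,
                           n_iter = 4000, burn_in = 2000, thin = 2,
                           efdr_target = 0.10, seed = 1) {
  grid <- tidyr::expand_grid(model = c("null", "alternative"),
                             n_cells = cells_per_group, rep = seq_len(reps))
  purrr::pmap_dfr(grid, function(model, n_cells, rep) {
    base <- (seed + 7919L * rep + 131L * n_cells) %% 2147483000L
    truth <- simulation_truth(n_genes = n_genes, n_cells = n_cells,
                              seed = base + 1L)
    truthB <- if (model == "alternative")
      perturb_overdispersion(truth, n_perturb, log2fc, seed = base + 2L)
    else truth
    dsA <- simulate_spikes(truth, seed = base + 3L)
    dsB <- simulate_spikes(truthB, seed = base + 4L)
    chA <- fit_spikes(dsA, n_iter = n_iter, burn_in = burn_in, thin = thin,
                      seed = base + 5L)
    chB <- fit_spikes(dsB, n_iter = n_iter, burn_in = burn_in, thin = thin,
                      seed = base + 6L)
    oc <- offset_correct(chA, chB)
    res <- test_residual(oc$chainA, oc$chainB, efdr_target = efdr_target,
                         eligible = eligibility_filter(dsA, dsB))
    dplyr::bind_cols(tibble::tibble(model = model, n_cells = n_cells,
                                    rep = rep),
                     evaluate_test(res, truthB))
  })
}
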