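# Shared fixtures: tiny datasets and states built in code.

# 2 biological genes x 3 cells plus one spike-in (smallest instance on
# which every full conditional is exercised)
tiny_spikes_ds <- function(seed = 42) {
  set.seed(seed)
  counts <- matrix(c(3, 0, 5,
                     1, 2, 0,
                     4, 1, 2), 3, 3, byrow = TRUE)
  expression_dataset(counts,
                     gene_ids = c("g1", "g2", "sp1"),
                     is_spike = c(FALSE, FALSE, TRUE),
                     spike_input = c(NA, NA, 2))
}

# 3 genes x 2 batches x 2 cells, all biological
tiny_nospikes_ds <- function(seed = 7) {
  set.seed(seed)
  counts <- matrix(rpois(12, 5) + 1, 3, 4)
  expression_dataset(counts, gene_ids = paste0("gene_", 1:3),
                     batch = c("b1", "b1", "b2", "b2"))
}

# a consistent parameter state for the tiny spikes instance
tiny_spikes_state <- function(seed = 42) {
  set.seed(seed)
  list(mu = c(1.3, 0.7), delta = c(0.5, 1.2), lambda = c(0.8, 1.1),
       phi = c(1.2, 0.9, 0.9), s = c(1, 1.1, 0.8), nu = c(0.9, 1.2, 1.1),
       theta = 0.4, beta = rnorm(12) * 0.1, sigma2 = 0.7)
}

# precomputed count summaries as the samplers use them
precomp <- function(counts) {
  dimnames(counts) <- NULL
  list(counts = counts, rs = rowSums(counts), cs = colSums(counts))
}

# hand-built chain pair with given draw matrices (draws x genes)
fake_chain_pair <- function(muA, muB, deltaA = NULL, deltaB = NULL,
                            epsA = NULL, epsB = NULL) {
  mk <- function(mu, delta, eps) {
    nd <- nrow(mu); q <- ncol(mu)
    scdv:::new_sc_chain(
      draws = list(mu = mu,
                   delta = if (is.null(delta)) matrix(1, nd, q) else delta,
                   epsilon = eps,
                   nu = matrix(1, nd, 2), s = matrix(1, nd, 2),
                   phi = matrix(1, nd, 2), theta = matrix(0.4, nd, 1)),
      variant = "spikes-regression",
      gene_ids = paste0("gene_", seq_len(q)), cell_ids = c("c1", "c2"),
      batches = c("batch1", "batch1"),
      n_iter = 2 * nd, burn_in = nd, thin = 1, seed = 1,
      cfg = NULL, hp = hyper_params(), acceptance = c(mu = 0.4))
  }
  list(A = mk(muA, deltaA, epsA), B = mk(muB, deltaB, epsB))
}

# deterministic alternative/null validation pair at a given group size;
# follows the scaled-down protocol (500 genes, 100 perturbed by |log2FC|=5)
validation_pair <- function(n_cells, base_seed, null = FALSE,
                            n_genes = 500, n_perturb = 100, log2fc = 5,
                            n_iter = 4000, burn_in = 2000, thin = 2) {
  truth <- simulation_truth(n_genes = n_genes, n_cells = n_cells,
                            seed = base_seed + 1L)
  truthB <- if (null) truth else
    perturb_overdispersion(truth, n_perturb, log2fc, seed = base_seed + 2L)
  dsA <- simulate_spikes(truth, seed = base_seed + 3L)
  dsB <- simulate_spikes(truthB, seed = base_seed + 4L)
  chA <- fit_spikes(dsA, n_iter = n_iter, burn_in = burn_in, thin = thin,
                    seed = base_seed + 5L)
  chB <- fit_spikes(dsB, n_iter = n_iter, burn_in = burn_in, thin = thin,
                    seed = base_seed + 6L)
  oc <- offset_correct(chA, chB)
  res <- suppressWarnings(
    test_residual(oc$chainA, oc$chainB,
                  eligible = eligibility_filter(dsA, dsB)))
  list(truth = truth, truthB = truthB, dsA = dsA, dsB = dsB,
       chainA = chA, chainB = chB, result = res,
       metrics = evaluate_test(res, truthB))
}
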