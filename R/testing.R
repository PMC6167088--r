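# Probabilistic differential tests on posterior chains: changes in mean,
# over-dispersion, and residual over-dispersion between two groups of
# cells, with the decision threshold calibrated by the expected false
# discovery rate (EFDR). Chains are paired draw by draw, so both groups
# must store the same number of draws.

check_pair <- function(chainA, chainB) {
  if (!identical(chainA$gene_ids, chainB$gene_ids)) {
    miss <- c(setdiff(chainA$gene_ids, chainB$gene_ids),
              setdiff(chainB$gene_ids, chainA$gene_ids))
    stop("chains cover different gene sets; mismatches: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  if (n_draws(chainA) != n_draws(chainB))
    stop("chains store different numbers of draws (",
         n_draws(chainA), " vs ", n_draws(chainB), ")")
  if (n_draws(chainA) < 1) stop("chains contain zero stored draws")
  invisible(TRUE)
}

#' Correct the global offset between two groups
#'
#' Without spike-ins (and, in general, across separately fitted groups) the
#' overall scale of the mean parameters is arbitrary, so group B is put on
#' group A's scale: for each stored draw, the offset
#' Omega = sum(mu_A) / sum(mu_B) multiplies every mu_B and divides every
#' nu_B, leaving all likelihood-invariant quantities (and delta, epsilon)
#' unchanged.
#'
#' @param chainA,chainB `sc_chain` objects over the same gene set with
#'   equal stored length
#' @return list with elements `chainA`, `chainB` (corrected) and `offset`
#'   (per-draw vector)
#' @export
offset_correct <- function(chainA, chainB) {
  check_pair(chainA, chainB)
  offset <- rowSums(chainA$draws$mu) / rowSums(chainB$draws$mu)
  chainB$draws$mu <- chainB$draws$mu * offset
  chainB$draws$nu <- chainB$draws$nu / offset
  list(chainA = chainA, chainB = chainB, offset = offset)
}

#' Calibrate the posterior probability cutoff by EFDR
#'
#' For a cutoff alpha the expected false discovery rate is
#' EFDR(alpha) = sum((1 - pi_i) * [pi_i > alpha]) / sum([pi_i > alpha]).
#' The cutoff is searched on the grid 0.50, 0.5025, ..., 0.9975 and set to
#' the value whose EFDR is closest to the target from below (ties resolved
#' toward the larger cutoff). If no grid value achieves EFDR <= target with
#' at least one call, a no-calls result is returned with a warning.
#'
#' @param tail_probs per-gene tail posterior probabilities in `[0, 1]`
#'   (`NA` entries — excluded genes — are ignored)
#' @param target EFDR target in (0, 1); default 0.10
#' @return list with `alpha` (cutoff, `NA` if no admissible cutoff),
#'   `efdr` (achieved), `n_calls`
#' @export
calibrate_efdr <- function(tail_probs, target = 0.10) {
  probs <- tail_probs[!is.na(tail_probs)]
  if (!length(probs)) stop("empty probability vector")
  if (any(probs < 0 | probs > 1)) stop("tail probabilities must lie in [0, 1]")
  grid <- seq(0.5, 0.9975, by = 0.0025)
  n_calls <- vapply(grid, function(a) sum(probs > a), numeric(1))
  efdr <- vapply(grid, function(a) {
    k <- probs > a
    if (!any(k)) NA_real_ else sum(1 - probs[k]) / sum(k)
  }, numeric(1))
  ok <- !is.na(efdr) & efdr <= target & n_calls > 0
  if (!any(ok)) {
    warning("no cutoff achieves EFDR <= ", target, " with at least one call; ",
            "returning a no-calls result")
    return(list(alpha = NA_real_, efdr = NA_real_, n_calls = 0L))
  }
  cand <- which(ok)
  best <- cand[efdr[cand] == max(efdr[cand])]
  pick <- max(best)                                   # ties -> larger alpha
  list(alpha = grid[pick], efdr = efdr[pick], n_calls = as.integer(n_calls[pick]))
}

# shared engine: paired-draw tail probabilities on a per-gene difference
# matrix `diffs` (draws x genes), tolerance `tol`, sign rule when tol == 0
tail_probabilities <- function(diffs, tol) {
  if (tol > 0) {
    colMeans(abs(diffs) > tol)
  } else {
    # sign rule; exactly tied draws split evenly so self-comparisons are null
    p <- colMeans(diffs > 0) + 0.5 * colMeans(diffs == 0)
    2 * pmax(p, 1 - p) - 1
  }
}

run_prob_test <- function(point, probs, eligible, target, threshold, test,
                          gene_ids, extra = NULL) {
  probs_cal <- ifelse(eligible, probs, NA_real_)
  cal <- calibrate_efdr(probs_cal, target)
  res <- tibble::tibble(
    gene_id = gene_ids,
    estimate = point,
    tail_prob = probs,
    eligible = eligible,
    call = !is.na(cal$alpha) & eligible & probs > cal$alpha)
  if (!is.null(extra)) res <- dplyr::bind_cols(res, extra)
  structure(res, class = c("sc_de_result", class(res)),
            test = test, threshold = threshold,
            alpha = cal$alpha, efdr = cal$efdr,
            efdr_target = target, n_calls = cal$n_calls)
}

#' @export
print.sc_de_result <- function(x, ...) {
  cat("<sc_de_result> test:", attr(x, "test"),
      " tolerance:", signif(attr(x, "threshold"), 3),
      " EFDR target:", attr(x, "efdr_target"), "\n")
  cat("  cutoff alpha:", signif(attr(x, "alpha"), 4),
      " achieved EFDR:", signif(attr(x, "efdr"), 3),
      " calls:", attr(x, "n_calls"), "\n")
  NextMethod()
}

#' Glance at a differential test result
#' @param x an `sc_de_result`
#' @param ... unused
#' @return one-row tibble with the test name, tolerance threshold,
#'   calibrated cutoff, achieved EFDR and call count
#' @export
glance.sc_de_result <- function(x, ...) {
  tibble::tibble(test = attr(x, "test"), threshold = attr(x, "threshold"),
                 alpha = attr(x, "alpha"), efdr = attr(x, "efdr"),
                 efdr_target = attr(x, "efdr_target"),
                 n_calls = attr(x, "n_calls"),
                 n_eligible = sum(x$eligible))
}

#' Differential mean expression test
#'
#' Tail posterior probability that |log2(mu_A / mu_B)| exceeds `tau0`,
#' estimated as the fraction of paired stored draws beyond the tolerance;
#' with `tau0 = 0` the sign rule 2 max(pi, 1 - pi) - 1 on
#' P(mu_A > mu_B | data) is used instead. The probability cutoff is
#' calibrated by [calibrate_efdr()].
#'
#' @param chainA,chainB offset-corrected chains (see [offset_correct()])
#' @param tau0 minimum absolute log2 fold change; default log2(1.5)
#' @param efdr_target EFDR target; default 0.10
#' @param eligible optional logical mask of testable genes (from
#'   [eligibility_filter()]); ineligible genes keep their probability but
#'   are excluded from calibration and never called
#' @return an `sc_de_result` tibble: `gene_id`, `estimate` (posterior
#'   median log2 fold change), `tail_prob`, `eligible`, `call`
#' @export
test_mean <- function(chainA, chainB, tau0 = log2(1.5), efdr_target = 0.10,
                      eligible = NULL) {
  check_pair(chainA, chainB)
  l2fc <- log2(chainA$draws$mu) - log2(chainB$draws$mu)
  if (is.null(eligible)) eligible <- rep(TRUE, length(chainA$gene_ids))
  run_prob_test(point = apply(l2fc, 2, stats::median),
                probs = tail_probabilities(l2fc, tau0),
                eligible = eligible, target = efdr_target,
                threshold = tau0, test = "mean", gene_ids = chainA$gene_ids)
}

#' Differential over-dispersion test
#'
#' Same machinery as [test_mean()] applied to log2(delta_A / delta_B).
#' Because over-dispersion changes are confounded by mean changes, the
#' result is annotated with the mean-test call when `mean_result` is given;
#' `restrict_to_non_de = TRUE` additionally removes genes with a mean call
#' from the eligible set (the classical workflow of testing
#' over-dispersion only where the mean is unchanged).
#'
#' @inheritParams test_mean
#' @param omega0 minimum absolute log2 fold change; default log2(1.5)
#' @param mean_result optional `sc_de_result` from [test_mean()]
#' @param restrict_to_non_de drop mean-called genes from eligibility
#' @return an `sc_de_result` (extra column `mean_call` when annotated)
#' @export
test_overdispersion <- function(chainA, chainB, omega0 = log2(1.5),
                                efdr_target = 0.10, mean_result = NULL,
                                restrict_to_non_de = FALSE, eligible = NULL) {
  check_pair(chainA, chainB)
  l2fc <- log2(chainA$draws$delta) - log2(chainB$draws$delta)
  if (is.null(eligible)) eligible <- rep(TRUE, length(chainA$gene_ids))
  extra <- NULL
  if (!is.null(mean_result)) {
    mc <- mean_result$call[match(chainA$gene_ids, mean_result$gene_id)]
    extra <- tibble::tibble(mean_call = mc)
    if (restrict_to_non_de) eligible <- eligible & !mc
  }
  run_prob_test(point = apply(l2fc, 2, stats::median),
                probs = tail_probabilities(l2fc, omega0),
                eligible = eligible, target = efdr_target,
                threshold = omega0, test = "overdispersion",
                gene_ids = chainA$gene_ids, extra = extra)
}

#' Differential residual over-dispersion test
#'
#' Tests |epsilon_A - epsilon_B| > psi0 across paired draws — the
#' variability comparison that is not confounded by mean expression, since
#' epsilon measures the departure of log over-dispersion from the global
#' mean/over-dispersion trend. With `psi0 = 0` the tail probability is 1 by
#' construction, so the sign rule 2 max(pi, 1 - pi) - 1 is used.
#'
#' @inheritParams test_mean
#' @param psi0 minimum |epsilon_A - epsilon_B| (natural-log scale); the
#'   default ln(1.5) ~ 0.41 corresponds to a 50% change in over-dispersion
#' @return an `sc_de_result`; `estimate` is the posterior median of
#'   epsilon_A - epsilon_B
#' @export
test_residual <- function(chainA, chainB, psi0 = log(1.5), efdr_target = 0.10,
                          eligible = NULL) {
  check_pair(chainA, chainB)
  if (is.null(chainA$draws$epsilon) || is.null(chainB$draws$epsilon))
    stop("residual over-dispersion test requires regression-variant chains ",
         "(epsilon draws are absent)")
  d <- chainA$draws$epsilon - chainB$draws$epsilon
  if (is.null(eligible)) eligible <- rep(TRUE, length(chainA$gene_ids))
  run_prob_test(point = apply(d, 2, stats::median),
                probs = tail_probabilities(d, psi0),
                eligible = eligible, target = efdr_target,
                threshold = psi0, test = "residual",
                gene_ids = chainA$gene_ids)
}

#' Decompose the over-dispersion fold change
#'
#' Per draw, log2(delta_A / delta_B) splits exactly into a mean
#' contribution log2(e) (f_A(mu_A) - f_B(mu_B)) — the part explained by the
#' two trends at the two means — and a residual change
#' log2(e) (epsilon_A - epsilon_B). Trends are recomputed from the stored
#' beta draws and each chain's frozen kernel configuration.
#'
#' @param chainA,chainB regression-variant chains over the same genes
#' @return tibble: `gene_id`, `mean_contribution`, `residual_change`,
#'   `log2fc_delta` (posterior medians; the identity holds draw-wise)
#' @export
decompose_log2fc <- function(chainA, chainB) {
  check_pair(chainA, chainB)
  if (is.null(chainA$cfg) || is.null(chainB$cfg))
    stop("decomposition requires regression-variant chains")
  fA <- trend_draws(chainA)
  fB <- trend_draws(chainB)
  l2e <- log2(exp(1))
  mc <- l2e * (fA - fB)
  rc <- l2e * (chainA$draws$epsilon - chainB$draws$epsilon)
  tibble::tibble(gene_id = chainA$gene_ids,
                 mean_contribution = apply(mc, 2, stats::median),
                 residual_change = apply(rc, 2, stats::median),
                 log2fc_delta = apply(
                   log2(chainA$draws$delta) - log2(chainB$draws$delta),
                   2, stats::median))
}

# per-draw trend values f(mu) recomputed from stored beta and mu
trend_draws <- function(chain) {
  t(vapply(seq_len(n_draws(chain)), function(d)
    predict_trend(log(chain$draws$mu[d, ]), chain$draws$beta[d, ], chain$cfg),
    numeric(length(chain$gene_ids))))
}

#' Eligibility for differential variability testing
#'
#' A gene is testable iff it shows a nonzero count in at least
#' `min_cells` cells in BOTH groups.
#'
#' @param dsA,dsB the two groups' `expression_dataset`s (shared gene set)
#' @param min_cells default 2
#' @return logical vector over the shared biological genes
#' @export
eligibility_filter <- function(dsA, dsB, min_cells = 2) {
  gA <- dsA$genes$gene_id[!dsA$genes$is_spike]
  gB <- dsB$genes$gene_id[!dsB$genes$is_spike]
  if (!identical(sort(gA), sort(gB)))
    stop("datasets cover different biological gene sets")
  cA <- bio_counts(dsA)
  cB <- bio_counts(dsB)[match(gA, gB), , drop = FALSE]
  unname(rowSums(cA > 0) >= min_cells & rowSums(cB > 0) >= min_cells)
}

#' Four-way classification of expression changes
#'
#' Genes significant in both the mean and the residual over-dispersion
#' tests are labelled by the direction of each change
#' (`up+higherVar`, `up+lowerVar`, `down+higherVar`, `down+lowerVar`);
#' genes significant in one test only are `mean-only` / `residual-only`;
#' ineligible genes are `excluded`; the rest are `none`.
#'
#' @param mean_result,residual_result `sc_de_result`s on the same genes
#' @return tibble: `gene_id`, `category`
#' @export
classify_four_way <- function(mean_result, residual_result) {
  stopifnot(identical(mean_result$gene_id, residual_result$gene_id))
  both <- mean_result$call & residual_result$call
  cat_both <- paste0(ifelse(mean_result$estimate > 0, "up", "down"),
                     ifelse(residual_result$estimate > 0,
                            "+higherVar", "+lowerVar"))
  category <- dplyr::case_when(
    both ~ cat_both,
    mean_result$call ~ "mean-only",
    residual_result$call ~ "residual-only",
    !mean_result$eligible & !residual_result$eligible ~ "excluded",
    TRUE ~ "none")
  tibble::tibble(gene_id = mean_result$gene_id, category = category)
}

#' Denoised expression counts
#'
#' Rescales the raw biological counts by the posterior medians of the
#' cell-specific factors — phi_j nu_j in the spikes model, nu_jk in the
#' no-spikes model — yielding expression values comparable across cells.
#'
#' @param ds the dataset the chain was fitted on
#' @param chain the fitted `sc_chain`
#' @return numeric matrix, biological genes x cells
#' @export
denoised_counts <- function(ds, chain) {
  counts <- bio_counts(ds)
  if (!identical(rownames(counts), chain$gene_ids))
    stop("chain was not fitted on this dataset (gene ids differ)")
  fac <- if (startsWith(chain$variant, "spikes")) {
    apply(chain$draws$phi * chain$draws$nu, 2, stats::median)
  } else {
    apply(chain$draws$nu, 2, stats::median)
  }
  sweep(counts, 2, fac, "/")
}

#' Full two-group differential analysis
#'
#' Convenience pipeline: offset correction, eligibility filtering (when the
#' datasets are supplied), the three probabilistic tests at their default
#' tolerances, and the four-way classification.
#'
#' @param chainA,chainB fitted chains for the two groups
#' @param dsA,dsB optional datasets, used for the detected-in-2-cells
#'   eligibility rule
#' @param tau0,omega0,psi0,efdr_target tolerances and EFDR target
#' @return list of class `sc_de`: `mean`, `overdispersion`, `residual`
#'   (each an `sc_de_result`), `classification`, `offset`
#' @export
de_test <- function(chainA, chainB, dsA = NULL, dsB = NULL,
                    tau0 = log2(1.5), omega0 = log2(1.5), psi0 = log(1.5),
                    efdr_target = 0.10) {
  oc <- offset_correct(chainA, chainB)
  eligible <- if (!is.null(dsA) && !is.null(dsB))
    eligibility_filter(dsA, dsB) else NULL
  m <- test_mean(oc$chainA, oc$chainB, tau0, efdr_target, eligible = eligible)
  o <- test_overdispersion(oc$chainA, oc$chainB, omega0, efdr_target,
                           mean_result = m, eligible = eligible)
  r <- if (!is.null(oc$chainA$draws$epsilon) &&
           !is.null(oc$chainB$draws$epsilon))
    test_residual(oc$chainA, oc$chainB, psi0, efdr_target, eligible = eligible)
  else NULL
  cls <- if (!is.null(r)) classify_four_way(m, r) else NULL
  structure(list(mean = m, overdispersion = o, residual = r,
                 classification = cls, offset = oc$offset),
            class = "sc_de")
}

#' Write differential test results to TSV
#'
#' One row per gene: the three point estimates, tail probabilities, calls
#' and the category, plus a header comment recording cutoffs, achieved
#' EFDRs and the package version.
#'
#' @param x an `sc_de` from [de_test()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_de_results <- function(x, path) {
  tab <- tibble::tibble(
    gene_id = x$mean$gene_id,
    log2fc_mean = x$mean$estimate, prob_mean = x$mean$tail_prob,
    call_mean = x$mean$call,
    log2fc_disp = x$overdispersion$estimate,
    prob_disp = x$overdispersion$tail_prob,
    call_disp = x$overdispersion$call)
  if (!is.null(x$residual)) {
    tab$d_epsilon <- x$residual$estimate
    tab$prob_residual <- x$residual$tail_prob
    tab$call_residual <- x$residual$call
    tab$category <- x$classification$category
  }
  hdr <- sprintf(
    "# scdv %s | alpha(mean)=%s efdr(mean)=%s | alpha(resid)=%s efdr(resid)=%s",
    utils::packageVersion("scdv"),
    signif(attr(x$mean, "alpha"), 4), signif(attr(x$mean, "efdr"), 4),
    if (!is.null(x$residual)) signif(attr(x$residual, "alpha"), 4) else NA,
    if (!is.null(x$residual)) signif(attr(x$residual, "efdr"), 4) else NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
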