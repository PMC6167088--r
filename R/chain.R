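# Posterior chain container and its tidy/serialization surface.

new_sc_chain <- function(draws, variant, gene_ids, cell_ids, batches,
                         n_iter, burn_in, thin, seed, cfg, hp, acceptance,
                         mu0 = NULL, constrained = NULL, reference_draws = NULL) {
  structure(list(
    draws = draws, variant = variant, gene_ids = gene_ids,
    cell_ids = cell_ids, batches = batches,
    n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
    cfg = cfg, hp = hp, acceptance = acceptance,
    mu0 = mu0, constrained = constrained, reference_draws = reference_draws),
    class = "sc_chain")
}

#' @export
print.sc_chain <- function(x, ...) {
  cat("<sc_chain> variant:", x$variant, "\n")
  cat("  genes:", length(x$gene_ids), " cells:", length(x$cell_ids),
      " stored draws:", nrow(x$draws$mu), "\n")
  cat("  schedule: n_iter", x$n_iter, "burn_in", x$burn_in, "thin", x$thin,
      "seed", x$seed, "\n")
  cat("  acceptance:", paste(names(x$acceptance),
                             sprintf("%.2f", x$acceptance), collapse = ", "), "\n")
  invisible(x)
}

#' Number of stored draws
#' @param chain an `sc_chain`
#' @return integer
#' @export
n_draws <- function(chain) nrow(chain$draws$mu)

#' Extract the draw matrix of one parameter
#' @param chain an `sc_chain`
#' @param param one of `"mu"`, `"delta"`, `"epsilon"`, `"lambda"`, `"phi"`,
#'   `"s"`, `"nu"`, `"theta"`, `"beta"`, `"sigma2"`
#' @return matrix (stored draws in rows) or vector for scalar parameters
#' @export
chain_draws <- function(chain, param) {
  if (!param %in% names(chain$draws) || is.null(chain$draws[[param]]))
    stop("parameter '", param, "' not stored in this chain (variant ",
         chain$variant, ")")
  chain$draws[[param]]
}

# highest posterior density interval from draws (shortest-window method)
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  w <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(w)
  c(x[i], x[i + m])
}

#' Tidy per-gene posterior summaries
#'
#' One row per gene and parameter (mu, delta, and epsilon for regression
#' chains) with the posterior median and a 95% highest-posterior-density
#' interval.
#'
#' @param x an `sc_chain`
#' @param ... unused
#' @return a tibble with columns `gene_id`, `parameter`, `median`,
#'   `hpd_lower`, `hpd_upper`
#' @export
tidy.sc_chain <- function(x, ...) {
  params <- c("mu", "delta", if (!is.null(x$draws$epsilon)) "epsilon")
  purrr::map_dfr(params, function(p) {
    d <- x$draws[[p]]
    hpd <- apply(d, 2, hpd_interval)
    tibble::tibble(gene_id = x$gene_ids, parameter = p,
                   median = apply(d, 2, stats::median),
                   hpd_lower = hpd[1, ], hpd_upper = hpd[2, ])
  })
}

#' One-row chain overview
#' @param x an `sc_chain`
#' @param ... unused
#' @return a tibble with run metadata and block acceptance rates
#' @export
glance.sc_chain <- function(x, ...) {
  tibble::tibble(variant = x$variant, n_genes = length(x$gene_ids),
                 n_cells = length(x$cell_ids), n_iter = x$n_iter,
                 burn_in = x$burn_in, thin = x$thin, seed = x$seed,
                 n_draws = n_draws(x),
                 accept_mu = unname(x$acceptance["mu"]),
                 accept_delta = unname(x$acceptance["delta"]))
}

#' @export
summary.sc_chain <- function(object, ...) tidy(object)

#' Serialize a chain to a directory container
#'
#' Writes one TSV per stored parameter array plus an `attributes.json` file
#' carrying run metadata (schedule, seed, variant, package version,
#' hyper-parameters, frozen kernel configuration, and for no-spikes chains
#' the anchor mu0, constraint mask and per-draw reference gene). Everything
#' is plain text; [read_chain()] restores the object losslessly up to
#' numeric formatting (17 significant digits are written).
#'
#' @param chain an `sc_chain`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_chain <- function(chain, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in names(chain$draws)) {
    if (is.null(chain$draws[[p]])) next
    m <- chain$draws[[p]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                       file.path(dir, paste0("draws_", p, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  meta <- list(
    variant = chain$variant, gene_ids = chain$gene_ids,
    cell_ids = chain$cell_ids, batches = chain$batches,
    n_iter = chain$n_iter, burn_in = chain$burn_in, thin = chain$thin,
    seed = chain$seed, acceptance = as.list(chain$acceptance),
    package_version = as.character(utils::packageVersion("scdv")),
    hp = chain$hp[!vapply(chain$hp, is.null, TRUE)],
    cfg = if (!is.null(chain$cfg))
      chain$cfg[c("L", "c", "eta", "locations", "scales", "range")],
    mu0 = chain$mu0, constrained = chain$constrained,
    reference_draws = chain$reference_draws)
  jsonlite::write_json(meta, file.path(dir, "attributes.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a chain container written by [write_chain()]
#' @param dir directory path
#' @return an `sc_chain`
#' @export
read_chain <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "attributes.json"),
                              simplifyVector = TRUE)
  draws <- list()
  for (f in list.files(dir, pattern = "^draws_.*\\.tsv$")) {
    p <- sub("^draws_(.*)\\.tsv$", "\\1", f)
    m <- as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
    dimnames(m) <- NULL
    draws[[p]] <- if (p == "sigma2") drop(m) else m
  }
  hp <- do.call(hyper_params, meta$hp[setdiff(names(meta$hp),
                                              c("m_beta", "V_beta"))])
  if (!is.null(meta$hp$m_beta)) hp$m_beta <- meta$hp$m_beta
  if (!is.null(meta$hp$V_beta)) hp$V_beta <- as.matrix(meta$hp$V_beta)
  cfg <- NULL
  if (!is.null(meta$cfg)) {
    cfg <- regression_config(L = meta$cfg$L, c = meta$cfg$c, eta = meta$cfg$eta,
                             locations = meta$cfg$locations,
                             scales = meta$cfg$scales)
    cfg$range <- meta$cfg$range
  }
  new_sc_chain(draws = draws, variant = meta$variant,
               gene_ids = meta$gene_ids, cell_ids = meta$cell_ids,
               batches = meta$batches, n_iter = meta$n_iter,
               burn_in = meta$burn_in, thin = meta$thin, seed = meta$seed,
               cfg = cfg, hp = hp, acceptance = unlist(meta$acceptance),
               mu0 = meta$mu0, constrained = meta$constrained,
               reference_draws = meta$reference_draws)
}
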