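# High-level workflows tying the modules together: fit / test / simulate /
# denoise with on-disk inputs and outputs.

#' Fit the model appropriate for a dataset
#'
#' Dispatches to [fit_spikes()] or [fit_nospikes()] after validating the
#' variant-specific requirements (spike-ins with known inputs, or at least
#' two batches), optionally writing the chain container and a per-gene
#' summary table.
#'
#' @param ds an [expression_dataset()]
#' @param model `"spikes"` or `"nospikes"`
#' @param out_dir optional output directory; when given, the chain is
#'   serialized to `<out_dir>/chain/` and per-gene posterior summaries
#'   (median and 95% HPD for mu, delta, epsilon) to
#'   `<out_dir>/summary.tsv`
#' @param ... passed on to the sampler (`hp`, `regression`, `cfg`,
#'   `n_iter`, `burn_in`, `thin`, `seed`)
#' @return the fitted `sc_chain`
#' @export
fit_expression_model <- function(ds, model = c("spikes", "nospikes"),
                                 out_dir = NULL, ...) {
  model <- match.arg(model)
  chain <- if (model == "spikes") {
    validate_dataset(ds, "spikes")
    fit_spikes(ds, ...)
  } else {
    fit_nospikes(ds, ...)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_chain(chain, file.path(out_dir, "chain"))
    utils::write.table(tidy(chain), file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  chain
}
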