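#' Assemble and validate a single-cell expression dataset
#'
#' Bundles a genes-by-cells matrix of raw counts with the gene and cell
#' annotations the model needs: which genes are technical spike-ins (and
#' their known input quantities), and which experimental batch each cell
#' belongs to. Internally genes are re-ordered so biological genes precede
#' spike-ins; the original order is preserved in the gene table and restored
#' in all user-facing outputs.
#'
#' @param counts integer matrix, genes in rows and cells in columns. Row
#'   names (gene ids) and column names (cell ids) are used if present.
#' @param gene_ids character vector of gene identifiers, one per row.
#' @param is_spike logical vector flagging spike-in genes.
#' @param batch factor/character vector of batch labels, one per cell. A
#'   single shared batch is assumed when omitted.
#' @param spike_input positive numeric vector of input molecule quantities,
#'   one per spike-in gene (`NA` for biological genes), required when any
#'   gene is flagged as a spike-in.
#' @param cell_ids character vector of cell identifiers.
#' @return An object of class `expression_dataset`: a list with elements
#'   `counts` (integer matrix, biological genes first), `genes` (tibble:
#'   `gene_id`, `is_spike`, `spike_input`, `orig_order`), `cells` (tibble:
#'   `cell_id`, `batch`).
#' @export
expression_dataset <- function(counts, gene_ids = rownames(counts),
                               is_spike = NULL, batch = NULL,
                               spike_input = NULL,
                               cell_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  q <- nrow(counts)
  n <- ncol(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(q))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  if (is.null(is_spike)) is_spike <- rep(FALSE, q)
  if (is.null(batch)) batch <- rep("batch1", n)
  if (length(gene_ids) != q)
    stop("`gene_ids` length (", length(gene_ids), ") != number of rows (", q, ")")
  if (length(cell_ids) != n || length(batch) != n)
    stop("`cell_ids`/`batch` length must equal the number of columns (", n, ")")
  if (length(is_spike) != q)
    stop("`is_spike` length must equal the number of rows")
  check_count_matrix(counts)
  storage.mode(counts) <- "double"  # exact integers, double storage for arithmetic
  is_spike <- as.logical(is_spike)

  if (is.null(spike_input)) spike_input <- rep(NA_real_, q)
  if (length(spike_input) == sum(is_spike) && sum(is_spike) != q) {
    full <- rep(NA_real_, q)
    full[is_spike] <- spike_input
    spike_input <- full
  }
  if (length(spike_input) != q)
    stop("`spike_input` must have one entry per gene or per spike-in gene")
  if (any(is_spike & (is.na(spike_input) | spike_input <= 0)))
    stop("every spike-in gene needs a positive `spike_input`")

  # biological genes first (internal convention); original order retained
  ord <- order(is_spike)
  genes <- tibble::tibble(
    gene_id = as.character(gene_ids)[ord],
    is_spike = is_spike[ord],
    spike_input = spike_input[ord],
    orig_order = ord
  )
  counts <- counts[ord, , drop = FALSE]
  rownames(counts) <- genes$gene_id
  colnames(counts) <- as.character(cell_ids)
  cells <- tibble::tibble(cell_id = as.character(cell_ids),
                          batch = as.character(batch))
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "expression_dataset")
}

check_count_matrix <- function(counts) {
  if (any(!is.finite(counts)))
    stop("counts contain non-finite values")
  if (any(counts < 0))
    stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers; found fractional values (e.g. ",
         counts[counts != round(counts)][1], ")")
  invisible(TRUE)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells\n", sep = "")
  cat("  biological: ", sum(!x$genes$is_spike),
      ", spike-ins: ", sum(x$genes$is_spike),
      ", batches: ", length(unique(x$cells$batch)), "\n", sep = "")
  invisible(x)
}

#' Number of biological genes / cells helpers
#' @param ds an `expression_dataset`
#' @return integer count
#' @keywords internal
n_bio <- function(ds) sum(!ds$genes$is_spike)

bio_counts <- function(ds) ds$counts[!ds$genes$is_spike, , drop = FALSE]
spike_counts <- function(ds) ds$counts[ds$genes$is_spike, , drop = FALSE]

#' Validate a dataset for a given model variant
#'
#' Checks the structural invariants a sampler relies on: spike-in mode needs
#' at least one spike-in gene with a known input quantity; the no-spikes
#' (horizontal integration) mode needs at least two batches, since technical
#' noise is then identified through replication across batches.
#'
#' @param ds an `expression_dataset`
#' @param model `"spikes"` or `"nospikes"`
#' @return `ds`, invisibly; errors describe the violated requirement.
#' @export
validate_dataset <- function(ds, model = c("spikes", "nospikes")) {
  model <- match.arg(model)
  stopifnot(inherits(ds, "expression_dataset"))
  check_count_matrix(ds$counts)
  if (model == "spikes") {
    if (!any(ds$genes$is_spike))
      stop("spikes model requires at least one spike-in gene")
    si <- ds$genes$spike_input[ds$genes$is_spike]
    if (any(is.na(si) | si <= 0))
      stop("spikes model requires a positive spike_input for every spike-in gene")
  } else {
    if (length(unique(ds$cells$batch)) < 2)
      stop("no-spikes model requires >= 2 batches (horizontal replication)")
    if (any(ds$genes$is_spike))
      stop("no-spikes model expects biological genes only; drop spike-in rows first")
  }
  if (n_bio(ds) < 1) stop("dataset contains no biological genes")
  invisible(ds)
}

#' Read a count matrix with sidecar annotations
#'
#' Reads either a MatrixMarket coordinate file (`format = "mtx"`) or a dense
#' tab-separated file (`format = "tsv"`, header row of cell ids, first
#' column of gene ids). Gene and cell annotations are read from sidecar TSV
#' files: the gene table needs columns `gene_id`, `is_spike`, `spike_input`;
#' the cell table needs `cell_id`, `batch`. For MTX input the row order of
#' the gene table defines the matrix rows (likewise cells/columns).
#'
#' @param path path to the counts file.
#' @param format `"mtx"` or `"tsv"`.
#' @param gene_file,cell_file sidecar annotation paths. Defaults:
#'   `<path>.genes.tsv` and `<path>.cells.tsv`. For dense TSV input the
#'   sidecars are optional (all-biological, single batch assumed).
#' @param genes_in_rows set to `FALSE` if the matrix on disk stores cells in
#'   rows; no orientation auto-detection is attempted.
#' @return an [expression_dataset()]
#' @export
read_counts <- function(path, format = c("mtx", "tsv"),
                        gene_file = paste0(path, ".genes.tsv"),
                        cell_file = paste0(path, ".cells.tsv"),
                        genes_in_rows = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    if (!genes_in_rows) m <- t(m)
    if (!file.exists(gene_file) || !file.exists(cell_file))
      stop("MTX input needs sidecar tables: ", gene_file, ", ", cell_file)
    gt <- utils::read.delim(gene_file, stringsAsFactors = FALSE)
    ct <- utils::read.delim(cell_file, stringsAsFactors = FALSE)
    if (nrow(gt) != nrow(m)) stop("gene table rows != matrix rows")
    if (nrow(ct) != ncol(m)) stop("cell table rows != matrix columns")
    check_count_matrix(m)
    expression_dataset(m, gene_ids = gt$gene_id,
                       is_spike = as.logical(gt$is_spike),
                       spike_input = suppressWarnings(as.numeric(gt$spike_input)),
                       batch = ct$batch, cell_ids = ct$cell_id)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in count TSV: ", path)
    if (!genes_in_rows) {
      m <- t(m)
      rn <- colnames(tab)[-1]
      colnames(m) <- ids
      rownames(m) <- rn
      ids <- rn
    } else {
      rownames(m) <- ids
    }
    check_count_matrix(m)
    gt <- if (file.exists(gene_file))
      utils::read.delim(gene_file, stringsAsFactors = FALSE) else NULL
    ct <- if (file.exists(cell_file))
      utils::read.delim(cell_file, stringsAsFactors = FALSE) else NULL
    expression_dataset(
      m, gene_ids = ids,
      is_spike = if (!is.null(gt)) as.logical(gt$is_spike[match(ids, gt$gene_id)]) else NULL,
      spike_input = if (!is.null(gt)) suppressWarnings(as.numeric(gt$spike_input[match(ids, gt$gene_id)])) else NULL,
      batch = if (!is.null(ct)) ct$batch[match(colnames(m), ct$cell_id)] else NULL,
      cell_ids = colnames(m))
  }
}

#' Write a dataset to disk
#'
#' Inverse of [read_counts()]; writes the counts (MTX or dense TSV, in the
#' original gene order) plus the two sidecar annotation tables.
#'
#' @inheritParams read_counts
#' @param ds an `expression_dataset`
#' @return `path`, invisibly
#' @export
write_counts <- function(ds, path, format = c("mtx", "tsv"),
                         gene_file = paste0(path, ".genes.tsv"),
                         cell_file = paste0(path, ".cells.tsv")) {
  format <- match.arg(format)
  inv <- order(ds$genes$orig_order)       # back to original ordering
  m <- ds$counts[inv, , drop = FALSE]
  gt <- ds$genes[inv, c("gene_id", "is_spike", "spike_input")]
  ct <- ds$cells[, c("cell_id", "batch")]
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  } else {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(gt, gene_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ct, cell_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter lowly expressed genes
#'
#' Biological genes are kept when their average count across all cells is at
#' least `min_mean_count` AND they are detected (non-zero) in at least
#' `min_cells_detected` cells. Spike-in genes follow a separate rule: only
#' spike-ins with zero total counts are dropped (undetected spike-ins carry
#' no information about technical noise).
#'
#' @param ds an `expression_dataset`
#' @param min_mean_count non-negative; default 1 (the usual quality filter).
#' @param min_cells_detected non-negative integer; default 2 (genes seen in
#'   fewer cells cannot support a variability statement).
#' @return the filtered `expression_dataset`, with attribute `"removed"`:
#'   a tibble reporting each removed gene and the reason.
#' @export
filter_genes <- function(ds, min_mean_count = 1, min_cells_detected = 2) {
  stopifnot(min_mean_count >= 0, min_cells_detected >= 0)
  mean_ct <- rowMeans(ds$counts)
  ncells <- rowSums(ds$counts > 0)
  tot <- rowSums(ds$counts)
  bio <- !ds$genes$is_spike
  keep <- ifelse(bio,
                 mean_ct >= min_mean_count & ncells >= min_cells_detected,
                 tot > 0)
  if (!any(keep & bio))
    stop("all biological genes removed by the filter")
  removed <- tibble::tibble(
    gene_id = ds$genes$gene_id[!keep],
    is_spike = ds$genes$is_spike[!keep],
    reason = ifelse(ds$genes$is_spike[!keep], "spike-in with zero total count",
                    ifelse(mean_ct[!keep] < min_mean_count,
                           "mean count below threshold",
                           "detected in too few cells")))
  out <- expression_dataset(
    ds$counts[keep, , drop = FALSE],
    gene_ids = ds$genes$gene_id[keep],
    is_spike = ds$genes$is_spike[keep],
    spike_input = ds$genes$spike_input[keep],
    batch = ds$cells$batch, cell_ids = ds$cells$cell_id)
  attr(out, "removed") <- removed
  out
}
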