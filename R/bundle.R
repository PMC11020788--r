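#' Filter genes by zero-count proportion
#'
#' Drops genes whose fraction of zero counts across cells exceeds
#' `max_zero_prop` (default 0.99, i.e. genes with more than 99% zeros are
#' removed). Gene order is preserved.
#'
#' @param counts genes x cells matrix of nonnegative integer counts (dense or
#'   `Matrix` sparse).
#' @param max_zero_prop maximum tolerated proportion of zero counts, in (0, 1].
#' @return integer vector of retained gene (row) indices.
#' @export
filter_genes <- function(counts, max_zero_prop = 0.99) {
  if (is.null(dim(counts)) || nrow(counts) == 0L || ncol(counts) == 0L)
    stop("'counts' must be a non-empty genes x cells matrix")
  if (!is.numeric(max_zero_prop) || max_zero_prop <= 0 || max_zero_prop > 1)
    stop("'max_zero_prop' must lie in (0, 1]")
  zero_prop <- 1 - (Matrix::rowSums(counts != 0) / ncol(counts))
  keep <- which(zero_prop <= max_zero_prop)
  if (length(keep) == 0L)
    stop("all genes exceed the zero-proportion threshold ", max_zero_prop)
  keep
}

#' Log-normalize a count matrix
#'
#' Per-cell total-count scaling to `scale_factor` followed by log(1 + x):
#' `expr[g, i] = log(1 + scale_factor * counts[g, i] / sum(counts[, i]))`.
#'
#' @param counts genes x cells matrix of nonnegative counts.
#' @param scale_factor library size each cell is scaled to (default 10,000).
#' @return matrix of log-normalized expression, same shape and dimnames.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("'scale_factor' must be positive")
  if (min(counts) < 0) stop("'counts' must be nonnegative")
  cs <- Matrix::colSums(counts)
  if (any(cs == 0)) {
    bad <- which(cs == 0)
    stop("cells with zero total counts: ",
         paste(utils::head(colnames(counts)[bad] %||% bad, 10), collapse = ", "))
  }
  if (methods::is(counts, "sparseMatrix")) {
    expr <- counts %*% Matrix::Diagonal(x = scale_factor / cs)
    expr@x <- log1p(expr@x)
    dimnames(expr) <- dimnames(counts)
    expr
  } else {
    log1p(sweep(as.matrix(counts), 2, scale_factor / cs, `*`))
  }
}

#' Assemble a time-course expression bundle
#'
#' Packages (optionally raw) expression together with per-cell time and sample
#' labels into the unit every model fit consumes. When raw `counts` are given
#' they are filtered ([filter_genes()]) and log-normalized ([log_normalize()]);
#' an already-normalized matrix can be supplied through `expr` instead, in
#' which case no renormalization ever happens downstream.
#'
#' Time labels are mapped to consecutive integers 1..T: numeric labels are
#' ordered ascending, factors keep their level order, characters the order of
#' first appearance. The mapping is stored in the returned object
#' (`$time_map`). Samples must be nested within time points and at least three
#' time points are required (fewer cannot distinguish a peak from growth).
#'
#' @param counts genes x cells raw count matrix (or NULL if `expr` is given).
#' @param time per-cell time point / stage label.
#' @param sample_id per-cell individual or replicate label.
#' @param expr optional pre-normalized genes x cells expression matrix.
#' @param covariates optional per-cell numeric covariate matrix or data.frame.
#' @param scale_factor passed to [log_normalize()].
#' @param max_zero_prop passed to [filter_genes()]; set to NULL to skip
#'   filtering.
#' @return an object of class `"expr_bundle"`: list with elements `expr`,
#'   `counts`, `time` (integer 1..T), `time_map`, `sample_id` (factor),
#'   `covariates`, `gene_names`, `cell_names`.
#' @export
expression_bundle <- function(counts = NULL, time, sample_id, expr = NULL,
                              covariates = NULL, scale_factor = 1e4,
                              max_zero_prop = 0.99) {
  if (is.null(counts) && is.null(expr))
    stop("supply 'counts' or 'expr'")
  n_cells <- ncol(expr %||% counts)
  if (length(time) != n_cells || length(sample_id) != n_cells)
    stop("'time' and 'sample_id' must have one entry per cell")

  if (is.null(expr)) {
    if (!is.null(max_zero_prop)) {
      keep <- filter_genes(counts, max_zero_prop)
      counts <- counts[keep, , drop = FALSE]
    }
    expr <- log_normalize(counts, scale_factor)
  }

  # time -> 1..T
  if (is.numeric(time)) levels_t <- sort(unique(time))
  else if (is.factor(time)) levels_t <- levels(droplevels(time))
  else levels_t <- unique(as.character(time))
  t_idx <- match(if (is.factor(time)) as.character(time) else time,
                 if (is.numeric(time)) levels_t else as.character(levels_t))
  T_n <- length(levels_t)
  if (T_n < 3L) stop("at least 3 time points are required (found ", T_n, ")")

  sample_id <- factor(as.character(sample_id), levels = unique(as.character(sample_id)))
  tab <- tapply(t_idx, sample_id, function(z) length(unique(z)))
  if (any(tab > 1L))
    stop("each sample must map to exactly one time point; offending samples: ",
         paste(names(tab)[tab > 1L], collapse = ", "))

  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n_cells)
      stop("'covariates' must have one row per cell")
    storage.mode(covariates) <- "double"
  }

  structure(list(
    expr = expr,
    counts = counts,
    time = as.integer(t_idx),
    time_map = data.frame(label = levels_t, index = seq_len(T_n)),
    sample_id = sample_id,
    covariates = covariates,
    gene_names = rownames(expr) %||% paste0("gene", seq_len(nrow(expr))),
    cell_names = colnames(expr) %||% paste0("cell", seq_len(ncol(expr)))
  ), class = "expr_bundle")
}

#' @export
print.expr_bundle <- function(x, ...) {
  cat("Time-course expression bundle\n")
  cat("  genes:", nrow(x$expr), " cells:", ncol(x$expr), "\n")
  cat("  time points:", nrow(x$time_map),
      " samples:", nlevels(x$sample_id), "\n")
  cat("  cells per time point:",
      paste(tabulate(x$time, nbins = nrow(x$time_map)), collapse = ", "), "\n")
  if (!is.null(x$covariates))
    cat("  covariates:", ncol(x$covariates), "\n")
  invisible(x)
}

# subset a bundle to a set of cells, keeping all labels aligned
.bundle_cells <- function(bundle, cells) {
  bundle$expr <- bundle$expr[, cells, drop = FALSE]
  if (!is.null(bundle$counts))
    bundle$counts <- bundle$counts[, cells, drop = FALSE]
  bundle$time <- bundle$time[cells]
  bundle$sample_id <- droplevels(bundle$sample_id[cells])
  if (!is.null(bundle$covariates))
    bundle$covariates <- bundle$covariates[cells, , drop = FALSE]
  bundle$cell_names <- bundle$cell_names[cells]
  bundle
}

#' Down-sample cells within each stage
#'
#' Randomly retains at most `max_cells_per_stage` cells per time point
#' (uniformly, without replacement); stages already below the cap pass through
#' unchanged. Reproducible given `seed`.
#'
#' @param bundle an [expression_bundle()].
#' @param max_cells_per_stage cap on cells per time point (>= 1).
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return the down-sampled bundle.
#' @export
downsample_stage <- function(bundle, max_cells_per_stage, seed = NULL) {
  stopifnot(inherits(bundle, "expr_bundle"))
  if (max_cells_per_stage < 1) stop("'max_cells_per_stage' must be >= 1")
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_along(bundle$time), bundle$time), function(ix) {
      if (length(ix) <= max_cells_per_stage) ix
      else sort(sample(ix, max_cells_per_stage))
    }), use.names = FALSE)
  })
  .bundle_cells(bundle, sort(keep))
}

#' Permute time labels at the sample level
#'
#' Shuffles which time point each sample is assigned to, keeping every cell
#' with its sample. Cells within a sample stay together, preserving the
#' within-sample dependence the mixed model assumes; the multiset of
#' sample-level time labels is preserved.
#'
#' @param bundle an [expression_bundle()].
#' @param seed integer seed for reproducibility.
#' @return a bundle with permuted time labels.
#' @export
permute_times <- function(bundle, seed = NULL) {
  stopifnot(inherits(bundle, "expr_bundle"))
  samples <- levels(bundle$sample_id)
  cur <- vapply(samples, function(s)
    bundle$time[match(s, as.character(bundle$sample_id))], integer(1))
  new <- with_seed(seed, sample(cur))
  names(new) <- samples
  bundle$time <- as.integer(new[as.character(bundle$sample_id)])
  bundle
}

#' Read a MatrixMarket count matrix with row/column name files
#'
#' @param mtx path to the .mtx file (genes x cells).
#' @param genes path to a one-column (or TSV; first column used) gene name file.
#' @param barcodes path to the cell barcode file.
#' @return a sparse genes x cells count matrix with dimnames.
#' @export
read_counts_mtx <- function(mtx, genes, barcodes) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  g <- utils::read.table(genes, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  b <- utils::read.table(barcodes, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  if (length(g) != nrow(m) || length(b) != ncol(m))
    stop("dimension mismatch between matrix and gene/barcode files")
  dimnames(m) <- list(g, b)
  m
}

#' Read a dense count matrix (genes as rows)
#'
#' @param path CSV/TSV file; first column holds gene names.
#' @param sep field separator ("," or "\t"); guessed from the extension when NULL.
#' @return dense genes x cells matrix.
#' @export
read_counts_dense <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Read per-cell metadata
#'
#' Requires columns `cell`, `time`, `sample`; any further columns are treated
#' as cell-level covariates.
#'
#' @param path CSV/TSV metadata file.
#' @param sep field separator; guessed from the extension when NULL.
#' @return data.frame with one row per cell.
#' @export
read_cell_metadata <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  md <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell", "time", "sample")
  if (!all(need %in% names(md)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  md
}

#' Build a bundle from matrix + metadata files
#'
#' Convenience reader: matches metadata rows to matrix columns by the `cell`
#' column, then calls [expression_bundle()].
#'
#' @param counts count matrix or path handled by [read_counts_dense()].
#' @param metadata data.frame from [read_cell_metadata()] or a file path.
#' @param covariate_cols names of metadata columns to carry as covariates.
#' @param ... passed on to [expression_bundle()].
#' @return an `expr_bundle`.
#' @export
bundle_from_files <- function(counts, metadata, covariate_cols = NULL, ...) {
  if (is.character(counts)) counts <- read_counts_dense(counts)
  if (is.character(metadata)) metadata <- read_cell_metadata(metadata)
  ix <- match(colnames(counts), metadata$cell)
  if (anyNA(ix)) stop("metadata is missing entries for some matrix columns")
  md <- metadata[ix, , drop = FALSE]
  cov <- if (!is.null(covariate_cols)) md[, covariate_cols, drop = FALSE]
  expression_bundle(counts = counts, time = md$time, sample_id = md$sample,
                    covariates = cov, ...)
}
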