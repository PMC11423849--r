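## Expression-matrix container, TSV I/O, low-expression filtering,
## replicate averaging and transcriptome correlation.

#' Construct an expression matrix with sample metadata
#'
#' The central container of the pipeline: a genes-by-samples FPKM matrix
#' together with per-sample metadata (cell type, stage, replicate) and the
#' ordered stage series each cell type is allowed to use. Columns are
#' reordered to follow the metadata row order.
#'
#' @param values Numeric matrix of non-negative, finite FPKM values with
#'   gene symbols as row names and sample ids as column names.
#' @param meta Data frame with columns `sample_id`, `cell_type`, `stage`,
#'   `replicate`; one row per sample column of `values`.
#' @param stage_series Named list of ordered stage labels per cell type;
#'   see [default_stage_series()].
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix, columns in metadata order), `meta`, and `stage_series`.
#' @export
expression_matrix <- function(values, meta, stage_series = default_stage_series()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene row names and sample column names")
  dup <- duplicated(rownames(values))
  if (any(dup))
    stop("duplicate gene symbol(s): ", paste(unique(rownames(values)[dup]), collapse = ", "))
  bad <- !is.finite(values) | values < 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite or negative FPKM at gene '%s', sample '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  need <- c("sample_id", "cell_type", "stage", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  meta <- as.data.frame(meta)[, need]
  meta$sample_id <- as.character(meta$sample_id)
  meta$cell_type <- as.character(meta$cell_type)
  meta$stage <- as.character(meta$stage)
  meta$replicate <- as.integer(meta$replicate)
  if (any(is.na(meta$replicate)) || any(meta$replicate < 1))
    stop("replicate ids must be positive integers")

  absent <- setdiff(colnames(values), meta$sample_id)
  if (length(absent))
    stop("sample column(s) missing from metadata: ", paste(absent, collapse = ", "))
  orphan <- setdiff(meta$sample_id, colnames(values))
  if (length(orphan))
    stop("metadata sample(s) absent from matrix: ", paste(orphan, collapse = ", "))

  key <- paste(meta$cell_type, meta$stage, meta$replicate)
  if (anyDuplicated(key))
    stop("duplicate (cell_type, stage, replicate) triple: ", key[duplicated(key)][1])
  for (ct in unique(meta$cell_type)) {
    series <- stage_series[[ct]]
    if (is.null(series))
      stop("cell type '", ct, "' has no configured stage series")
    off <- setdiff(meta$stage[meta$cell_type == ct], series)
    if (length(off))
      stop("stage label(s) not in the '", ct, "' series: ", paste(off, collapse = ", "))
  }

  structure(list(values = values[, meta$sample_id, drop = FALSE],
                 meta = meta, stage_series = stage_series),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n", nrow(x$values), ncol(x$values)))
  tab <- table(x$meta$cell_type, x$meta$stage)
  cat("samples per (cell type, stage):\n")
  print(tab)
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its metadata from TSV files
#'
#' The matrix TSV must have a first column `gene` and one column per
#' sample; the metadata TSV must have columns `sample_id`, `cell_type`,
#' `stage`, `replicate` covering every sample column.
#'
#' @inheritParams expression_matrix
#' @param matrix_path,metadata_path Paths to the two TSV files.
#' @return An `expr_matrix`.
#' @export
read_expression_table <- function(matrix_path, metadata_path,
                                  stage_series = default_stage_series()) {
  raw <- read_tsv_file(matrix_path)
  if (names(raw)[1] != "gene")
    stop("expression TSV must have 'gene' as its first column")
  meta <- read_tsv_file(metadata_path)
  genes <- as.character(raw$gene)
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value at row %d, column '%s'", bad, names(vals)[j]))
    }
    if (any(v < 0, na.rm = TRUE))
      stop(sprintf("negative value at row %d, column '%s'",
                   which(v < 0)[1], names(vals)[j]))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  expression_matrix(m, meta, stage_series)
}

#' Write an expression matrix and metadata to TSV files
#'
#' @param x An `expr_matrix`.
#' @param matrix_path,metadata_path Output paths.
#' @export
write_expression_table <- function(x, matrix_path, metadata_path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  write_tsv_file(df, matrix_path)
  write_tsv_file(x$meta, metadata_path)
  invisible(c(matrix_path, metadata_path))
}

#' Drop genes below an FPKM floor in every sample
#'
#' Removes genes whose FPKM is below `min_fpkm` in all samples; a gene with
#' any single value at or above the floor is retained. Applying the filter
#' twice is a no-op.
#'
#' @param x An `expr_matrix`.
#' @param min_fpkm Retention floor (default 1 FPKM).
#' @return Filtered `expr_matrix` with the same samples.
#' @export
filter_low_expression <- function(x, min_fpkm = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  keep <- apply(x$values, 1, max) >= min_fpkm
  x$values <- x$values[keep, , drop = FALSE]
  x
}

#' Average replicates into per-stage expression profiles
#'
#' Collapses the replicate dimension for one cell type: per gene and stage,
#' the arithmetic mean FPKM over replicates, with stages ordered by the
#' configured series.
#'
#' @param x An `expr_matrix`.
#' @param cell_type Cell type whose samples to average.
#' @return An object of class `stage_profiles`: list with `cell_type`,
#'   `stages`, and `profiles` (genes x stages matrix of mean FPKM).
#' @export
average_replicates <- function(x, cell_type) {
  stopifnot(inherits(x, "expr_matrix"))
  series <- x$stage_series[[cell_type]]
  if (is.null(series)) stop("no stage series configured for '", cell_type, "'")
  sel <- x$meta$cell_type == cell_type
  have <- unique(x$meta$stage[sel])
  missing <- setdiff(series, have)
  if (length(missing))
    stop("cell type '", cell_type, "' has no samples at stage(s): ",
         paste(missing, collapse = ", "))
  prof <- sapply(series, function(s) {
    cols <- x$meta$sample_id[sel & x$meta$stage == s]
    rowMeans(x$values[, cols, drop = FALSE])
  })
  stage_profiles(prof, cell_type, series)
}

#' Construct a stage-profile set
#'
#' @param profiles Genes x stages numeric matrix of replicate-mean FPKM.
#' @param cell_type Cell-type label.
#' @param stages Ordered stage labels, one per column.
#' @return A `stage_profiles` object.
#' @export
stage_profiles <- function(profiles, cell_type, stages = colnames(profiles)) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != length(stages))
    stop("profile width (", ncol(profiles), ") != number of stages (", length(stages), ")")
  colnames(profiles) <- stages
  structure(list(cell_type = cell_type, stages = stages, profiles = profiles),
            class = "stage_profiles")
}

#' @export
print.stage_profiles <- function(x, ...) {
  cat(sprintf("stage_profiles [%s]: %d genes over %d stages (%s)\n",
              x$cell_type, nrow(x$profiles), length(x$stages),
              paste(x$stages, collapse = " ")))
  invisible(x)
}

#' Pearson correlation between two transcriptome vectors
#'
#' Inner-joins the two gene-named vectors on gene symbol, then computes the
#' Pearson correlation of `log2(FPKM + 1)` values (or raw values with
#' `log_transform = FALSE`). The join size is attached as attribute
#' `n_genes` so shrinking overlaps are visible.
#'
#' @param a,b Named numeric vectors (names are gene symbols), e.g. one
#'   sample column or one stage column of a profile set.
#' @param log_transform Correlate on `log2(x + 1)` (default) or raw values.
#' @return Correlation in `[-1, 1]` with attribute `n_genes`.
#' @export
pairwise_correlation <- function(a, b, log_transform = TRUE) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("both vectors must be named by gene symbol")
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3)
    stop("fewer than 3 shared genes (", length(shared), ") between the vectors")
  va <- as.numeric(a[shared]); vb <- as.numeric(b[shared])
  if (log_transform) { va <- log2p1(va); vb <- log2p1(vb) }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("correlation undefined: zero variance in one of the vectors")
  structure(stats::cor(va, vb), n_genes = length(shared))
}
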