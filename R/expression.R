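#' Expression matrix container
#'
#' Bundles a log2-scale expression matrix (genes in rows, samples in columns)
#' with optional per-sample condition labels (+1 stress / -1 control) and
#' per-sample time points in hours.
#'
#' @param values Numeric matrix, genes x samples, with unique rownames
#'   (gene IDs) and colnames (sample IDs).
#' @param labels Optional numeric vector of +1/-1 condition labels, one per
#'   sample (recycled names are matched to sample IDs when named).
#' @param time_h Optional non-negative numeric vector of time points in
#'   hours, one per sample.
#' @return An object of class `expression_matrix` with elements `values`,
#'   `labels` and `time_h`.
#' @export
expression_matrix <- function(values, labels = NULL, time_h = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene IDs as rownames and sample IDs as colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  if (ncol(values) < 2L)
    stop("need at least 2 samples")
  if (anyNA(values))
    stop("`values` contains missing values; drop or impute before construction")
  if (!is.null(labels)) {
    labels <- align_sample_field(labels, colnames(values), "labels")
    if (!all(labels %in% c(-1, 1)))
      stop("`labels` must be +1 or -1")
  }
  if (!is.null(time_h)) {
    time_h <- align_sample_field(time_h, colnames(values), "time_h")
    if (any(time_h < 0)) stop("`time_h` must be non-negative")
  }
  structure(list(values = values, labels = labels, time_h = time_h),
            class = "expression_matrix")
}

align_sample_field <- function(x, sample_ids, what) {
  if (length(x) != length(sample_ids))
    stop("`", what, "` must have one entry per sample")
  if (!is.null(names(x))) {
    if (!setequal(names(x), sample_ids))
      stop("`", what, "` names do not match sample IDs")
    x <- x[sample_ids]
  } else {
    names(x) <- sample_ids
  }
  x
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  if (!is.null(x$labels))
    cat("  labels: ", sum(x$labels == 1), " stress (+1), ",
        sum(x$labels == -1), " control (-1)\n", sep = "")
  if (!is.null(x$time_h))
    cat("  time points (h):",
        paste(sort(unique(x$time_h)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by sample
#'
#' @param expr An [expression_matrix()].
#' @param samples Sample indices, IDs or a logical vector.
#' @return An `expression_matrix` restricted to the chosen samples.
#' @export
subset_samples <- function(expr, samples) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values[, samples, drop = FALSE]
  expression_matrix(v,
                    labels = if (!is.null(expr$labels)) expr$labels[colnames(v)],
                    time_h = if (!is.null(expr$time_h)) expr$time_h[colnames(v)])
}

#' Read an expression matrix from tab-delimited text
#'
#' The expression file has a `gene_id` first column and one column per
#' sample; the optional metadata file has columns `sample_id`, `label`
#' (+1/-1) and optionally `time_h`. Rows containing any missing value are
#' dropped with a message stating how many.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Optional path to the sample metadata TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, metadata_path = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("expression file needs gene IDs plus >= 1 sample")
  gene_ids <- raw[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene IDs in ", path, ": ", paste(dup, collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is.na(cells) & cells != "" &
                 toupper(cells) != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at gene row %d, sample column %d",
                 cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L]))
  dimnames(num) <- list(gene_ids, colnames(cells))
  drop_rows <- apply(num, 1L, anyNA)
  if (any(drop_rows)) {
    message(sum(drop_rows), " gene row(s) with missing values dropped")
    num <- num[!drop_rows, , drop = FALSE]
  }
  labels <- NULL
  time_h <- NULL
  if (!is.null(metadata_path)) {
    md <- utils::read.delim(metadata_path, check.names = FALSE)
    if (!all(c("sample_id", "label") %in% names(md)))
      stop("metadata must have columns sample_id and label")
    unknown <- setdiff(md$sample_id, colnames(num))
    if (length(unknown))
      stop("metadata sample IDs not in expression header: ",
           paste(unknown, collapse = ", "))
    missing_md <- setdiff(colnames(num), md$sample_id)
    if (length(missing_md))
      stop("samples missing from metadata: ",
           paste(missing_md, collapse = ", "))
    labels <- stats::setNames(md$label, md$sample_id)[colnames(num)]
    if ("time_h" %in% names(md))
      time_h <- stats::setNames(md$time_h, md$sample_id)[colnames(num)]
  }
  expression_matrix(num, labels = labels, time_h = time_h)
}

#' Write an expression matrix (and optionally its metadata) as TSV
#'
#' @param expr An [expression_matrix()].
#' @param path Output path for the expression TSV.
#' @param metadata_path Optional output path for the sample metadata TSV;
#'   written only when the object carries labels or time points.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, metadata_path = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path) &&
      (!is.null(expr$labels) || !is.null(expr$time_h))) {
    md <- data.frame(sample_id = colnames(expr$values))
    if (!is.null(expr$labels)) md$label <- unname(expr$labels)
    if (!is.null(expr$time_h)) md$time_h <- unname(expr$time_h)
    utils::write.table(md, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Quality-filter samples by mean and standard deviation
#'
#' Retains exactly the samples whose across-gene mean expression is at least
#' `mean_min` and whose standard deviation (denominator G-1) is at most
#' `sd_max`; both comparisons are inclusive. The defaults are the filter
#' used for RMA-processed log2 array data.
#'
#' @param expr An [expression_matrix()].
#' @param mean_min Minimum per-sample mean (log2 units).
#' @param sd_max Maximum per-sample standard deviation.
#' @return The filtered `expression_matrix`.
#' @export
filter_samples <- function(expr, mean_min = 7.1, sd_max = 2.5) {
  stopifnot(inherits(expr, "expression_matrix"))
  mu <- colMeans(expr$values)
  sd_ <- apply(expr$values, 2L, stats::sd)
  keep <- mu >= mean_min & sd_ <= sd_max
  if (!any(keep))
    stop("all samples removed by the mean/sd filter")
  subset_samples(expr, keep)
}
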