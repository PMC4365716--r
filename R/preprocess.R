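#' Floor and log2-transform intensities
#'
#' Raw bead-summary intensities can be zero or negative after background
#' correction, so every value is floored before taking log2: each value `v`
#' becomes `log2(max(v, floor))`.
#'
#' @param x An `expr_matrix` on the linear scale.
#' @param floor Positive linear-scale floor (default 1, i.e. log2 values are
#'   non-negative).
#' @return The transformed `expr_matrix` with `scale = "log2"`.
#' @export
log2_transform <- function(x, floor = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "linear") {
    stop("matrix is already on the log2 scale", call. = FALSE)
  }
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    stop("floor must be a single positive number", call. = FALSE)
  }
  x$values <- log2(pmax(x$values, floor))
  x$scale <- "log2"
  x
}

#' Quantile-normalize arrays to a common distribution
#'
#' Forces the intensity distribution of every sample to be identical: the
#' reference distribution is formed by averaging each quantile (each sorted
#' position) across all samples, and every column's k-th smallest value is
#' replaced by the k-th reference value. Tied values within a column receive
#' the mean of the reference entries over the tied rank span, which makes the
#' operation deterministic and equivariant under row permutation.
#'
#' @param x An `expr_matrix` on the log2 scale with at least 2 samples. A
#'   single-sample matrix is returned unchanged with a warning.
#' @return A list with `matrix` (the normalized `expr_matrix`) and `report`
#'   (class `"norm_report"`): the non-decreasing reference distribution and,
#'   as a diagnostic, the median shift applied to each sample.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "log2") {
    stop("quantile normalization operates on the log2 scale; ",
         "call log2_transform() first", call. = FALSE)
  }
  v <- x$values
  if (ncol(v) < 2L) {
    warning("single-sample matrix: quantile normalization is a no-op")
    report <- structure(
      list(reference_distribution = sort(v[, 1L]),
           per_sample_shift = stats::setNames(0, colnames(v))),
      class = "norm_report"
    )
    return(list(matrix = x, report = report))
  }
  sorted <- apply(v, 2L, sort, method = "radix")
  ref <- unname(rowMeans(sorted))
  out <- v
  for (j in seq_len(ncol(v))) {
    o <- order(v[, j], method = "radix")
    # mean of reference entries over each span of tied input values
    out[o, j] <- stats::ave(ref, match(v[o, j], v[o, j]), FUN = mean)
  }
  shift <- apply(out - v, 2L, stats::median)
  x$values <- out
  report <- structure(
    list(reference_distribution = ref, per_sample_shift = shift),
    class = "norm_report"
  )
  list(matrix = x, report = report)
}

#' @export
print.norm_report <- function(x, ...) {
  cat(sprintf("quantile normalization: %d quantiles\n",
              length(x$reference_distribution)))
  cat("median per-sample shifts:\n")
  print(round(x$per_sample_shift, 4))
  invisible(x)
}

#' Combine expression matrices from the same platform
#'
#' Column-binds two or more matrices measured on an identical probe universe,
#' aligning rows by probe identifier (not by row position). Downstream
#' normalization is intended to run once on the combined matrix so that all
#' arrays share one reference distribution.
#'
#' @param matrices List of `expr_matrix` objects on the same scale.
#' @return One combined `expr_matrix`; probe order and gene symbols are taken
#'   from the first matrix.
#' @export
combine_datasets <- function(matrices) {
  if (inherits(matrices, "expr_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1), "expr_matrix")))
  if (length(matrices) == 1L) return(matrices[[1L]])
  scales <- unique(vapply(matrices, function(m) m$scale, character(1)))
  if (length(scales) != 1L) {
    stop("matrices are on different scales: ", paste(scales, collapse = ", "),
         call. = FALSE)
  }
  first <- matrices[[1L]]
  probes <- probe_ids(first)
  for (i in seq_along(matrices)[-1L]) {
    other <- probe_ids(matrices[[i]])
    if (!setequal(probes, other)) {
      stop(sprintf(
        "probe universes differ: %d probes missing from matrix %d, %d extra",
        length(setdiff(probes, other)), i, length(setdiff(other, probes))),
        call. = FALSE)
    }
  }
  all_samples <- unlist(lapply(matrices, sample_ids))
  dup <- all_samples[duplicated(all_samples)]
  if (length(dup)) {
    stop("duplicate sample identifier(s) across matrices: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  values <- do.call(cbind, lapply(matrices, function(m) {
    m$values[probes, , drop = FALSE]
  }))
  expression_matrix(values, gene_symbols = first$gene_symbols,
                    scale = first$scale)
}
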