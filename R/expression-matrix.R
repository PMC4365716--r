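#' Construct an expression matrix
#'
#' Container for a probes-by-samples intensity matrix together with per-probe
#' gene-symbol annotation and a scale flag. All downstream analysis operates on
#' the `log2` scale; raw bead-summary exports are typically on the `linear`
#' scale and are converted with [log2_transform()].
#'
#' @param values Numeric matrix, probes in rows and samples in columns. Row
#'   names are taken as probe identifiers, column names as sample identifiers;
#'   both are required and must be unique.
#' @param gene_symbols Optional character vector of gene symbols, one per
#'   probe. Symbols may repeat (several probes can target one gene). Missing
#'   or empty entries fall back to the probe identifier, which never affects
#'   the ranking arithmetic.
#' @param scale Either `"linear"` (raw intensities) or `"log2"`.
#'
#' @return An object of class `"expr_matrix"`: a list with elements `values`,
#'   `gene_symbols` (named by probe), and `scale`.
#' @export
#' @examples
#' m <- matrix(2^(1:6), 3, 2, dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' x <- expression_matrix(m, gene_symbols = c("GeneA", "GeneB", "GeneA"))
#' x
expression_matrix <- function(values, gene_symbols = NULL,
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric", call. = FALSE)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix is empty", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    stop("probe identifiers (row names) are required", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    stop("sample identifiers (column names) are required", call. = FALSE)
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("duplicate probe identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression values contain missing entries", call. = FALSE)
  }
  if (is.null(gene_symbols)) {
    gene_symbols <- rownames(values)
  } else {
    gene_symbols <- as.character(gene_symbols)
    if (length(gene_symbols) != nrow(values)) {
      stop("gene_symbols must have one entry per probe", call. = FALSE)
    }
    blank <- is.na(gene_symbols) | !nzchar(gene_symbols)
    gene_symbols[blank] <- rownames(values)[blank]
  }
  names(gene_symbols) <- rownames(values)
  structure(
    list(values = values, gene_symbols = gene_symbols, scale = scale),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("samples:", paste(utils::head(colnames(x$values), 8), collapse = ", "),
      if (ncol(x$values) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Probe and sample identifiers
#'
#' @param x An `expr_matrix`.
#' @return Character vector of identifiers.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)
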