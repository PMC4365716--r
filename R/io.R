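#' Read a tab-delimited expression matrix
#'
#' Supports two dialects. `"plain_tsv"` expects a header row followed by one
#' row per probe: probe identifier, gene symbol, then one intensity column per
#' sample. `"genomestudio"` accepts bead-array sample-probe-profile style
#' exports in which each sample may carry an extra detection p-value column;
#' any column whose name contains "detection" (case-insensitive) is parsed and
#' ignored, and a trailing ".AVG_Signal" suffix is stripped from sample names.
#'
#' @param path Path to a tab-delimited text file.
#' @param dialect `"plain_tsv"` or `"genomestudio"`.
#' @param scale Scale of the stored intensities; raw exports are `"linear"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = c("plain_tsv", "genomestudio"),
                                   scale = c("linear", "log2")) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 3L) {
    stop("empty or malformed expression matrix: ", path, call. = FALSE)
  }
  probe <- raw[[1L]]
  symbol <- raw[[2L]]
  dup <- probe[duplicated(probe)]
  if (length(dup)) {
    stop("duplicate probe identifier(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  value_cols <- names(raw)[-(1:2)]
  if (dialect == "genomestudio") {
    value_cols <- value_cols[!grepl("detection", value_cols, ignore.case = TRUE)]
    if (!length(value_cols)) {
      stop("no intensity columns left after dropping detection columns",
           call. = FALSE)
    }
  }
  values <- matrix(NA_real_, nrow(raw), length(value_cols))
  for (j in seq_along(value_cols)) {
    col <- raw[[value_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      stop(sprintf("non-numeric intensity '%s' at row %d, column '%s' in %s",
                   col[bad[1]], bad[1], value_cols[j], path), call. = FALSE)
    }
    values[, j] <- num
  }
  sample_names <- sub("\\.AVG_Signal$", "", value_cols)
  dimnames(values) <- list(probe, sample_names)
  expression_matrix(values, gene_symbols = symbol, scale = scale)
}

#' Write an expression matrix as tab-delimited text
#'
#' Companion writer for [read_expression_matrix()] (plain_tsv dialect). Values
#' are rendered with enough digits that a write/read round trip reproduces
#' every double exactly.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  header <- c("probe_id", "gene_symbol", sample_ids(x))
  body <- cbind(probe_ids(x), unname(x$gene_symbols),
                apply(x$values, 2, function(v) sprintf("%.17g", v)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects a tab-delimited file with header `sample`, `group`, `role`. The
#' role must be constant within a group and one of `"target"` or
#' `"reference"`.
#'
#' @param path Path to the sheet.
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("sample", "group", "role")
  if (!all(need %in% names(raw))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  roles <- tapply(raw$role, raw$group, unique)
  multi <- names(roles)[lengths(roles) > 1L]
  if (length(multi)) {
    stop("conflicting roles declared for group(s): ",
         paste(multi, collapse = ", "), call. = FALSE)
  }
  sample_sheet(raw$sample, raw$group,
               roles = stats::setNames(unlist(roles), names(roles)))
}

#' Write a sample sheet
#'
#' @param sheet A `sample_sheet`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(inherits(sheet, "sample_sheet"))
  df <- data.frame(
    sample = names(sheet$sample_to_group),
    group = unname(sheet$sample_to_group),
    role = unname(sheet$group_roles[sheet$sample_to_group]),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed significant-digit rendering keeps regression fixtures byte-stable
format_sig <- function(x, digits = 7L) {
  out <- formatC(x, digits = digits, format = "g", flag = "#")
  out <- sub("\\.$", "", sub("0+$", "", out))
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

#' Write the ranked results table
#'
#' Serializes the per-probe results of [lineage_specificity()] as a
#' tab-delimited table mirroring a searchable supplemental-spreadsheet layout:
#' one row per probe with per-group means and SDs, per-category fold change,
#' q-value and rank, the reference-vs-reference contrast, the consensus group
#' label, consensus score, and consensus rank. Rows are ordered by consensus
#' rank; numbers carry seven significant digits.
#'
#' @param result A `lineage_result` from [lineage_specificity()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ranked_table <- function(result, path) {
  stopifnot(inherits(result, "lineage_result"))
  tab <- result$table[order(result$table$consensus_rank), , drop = FALSE]
  out <- tab
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], format_sig)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
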