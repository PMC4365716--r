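#' Construct a sample sheet
#'
#' Maps each sample to a biological group and each group to a role. Groups
#' with role `"target"` are the lineage categories being scored (e.g. otic
#' vesicle, hair cells, supporting cells); groups with role `"reference"`
#' supply the per-probe maximum-expressing denominator for fold changes.
#'
#' @param sample Character vector of sample identifiers.
#' @param group Character vector (same length) assigning each sample to a
#'   group.
#' @param roles Named character vector mapping every group name to `"target"`
#'   or `"reference"`.
#' @param target_order Optional character vector fixing the order of the
#'   target categories (defaults to order of first appearance in `group`).
#'
#' @return An object of class `"sample_sheet"`: list with `sample_to_group`
#'   (named character), `group_roles` (named character), `target_order`, and
#'   `reference_order`.
#' @export
#' @examples
#' sample_sheet(
#'   sample = c("ov1", "ov2", "ref1", "ref2"),
#'   group = c("OV", "OV", "embryo", "embryo"),
#'   roles = c(OV = "target", embryo = "reference")
#' )
sample_sheet <- function(sample, group, roles, target_order = NULL) {
  sample <- as.character(sample)
  group <- as.character(group)
  if (length(sample) != length(group)) {
    stop("sample and group must have the same length", call. = FALSE)
  }
  if (anyDuplicated(sample)) {
    stop("duplicate sample identifier(s) in sample sheet: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "),
         call. = FALSE)
  }
  roles <- vapply(roles, as.character, character(1))
  bad <- setdiff(roles, c("target", "reference"))
  if (length(bad)) {
    stop("unknown group role(s): ", paste(unique(bad), collapse = ", "),
         "; must be 'target' or 'reference'", call. = FALSE)
  }
  groups_seen <- unique(group)
  missing_role <- setdiff(groups_seen, names(roles))
  if (length(missing_role)) {
    stop("no role declared for group(s): ",
         paste(missing_role, collapse = ", "), call. = FALSE)
  }
  roles <- roles[intersect(names(roles), groups_seen)]
  targets <- names(roles)[roles == "target"]
  refs <- names(roles)[roles == "reference"]
  if (length(targets) < 1L) stop("at least one target group is required", call. = FALSE)
  if (length(refs) < 1L) stop("at least one reference group is required", call. = FALSE)
  if (is.null(target_order)) {
    target_order <- groups_seen[groups_seen %in% targets]
  } else {
    target_order <- as.character(target_order)
    if (!setequal(target_order, targets)) {
      stop("target_order must list exactly the target groups", call. = FALSE)
    }
  }
  reference_order <- groups_seen[groups_seen %in% refs]
  structure(
    list(
      sample_to_group = stats::setNames(group, sample),
      group_roles = roles,
      target_order = target_order,
      reference_order = reference_order
    ),
    class = "sample_sheet"
  )
}

#' @export
print.sample_sheet <- function(x, ...) {
  tab <- table(x$sample_to_group)
  cat(sprintf("sample sheet: %d samples, %d groups\n",
              length(x$sample_to_group), length(x$group_roles)))
  cat("  targets:   ",
      paste(sprintf("%s (n=%d)", x$target_order, tab[x$target_order]),
            collapse = ", "), "\n")
  cat("  references:",
      paste(sprintf("%s (n=%d)", x$reference_order, tab[x$reference_order]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Check that a matrix and a sample sheet describe the same samples
#'
#' Every sample in the matrix must appear exactly once in the sheet. Samples
#' present in the sheet but absent from the matrix are tolerated (the sheet
#' may describe a superset design).
#'
#' @param x An `expr_matrix`.
#' @param sheet A `sample_sheet`.
#' @return Invisibly, `TRUE`.
#' @export
validate_design <- function(x, sheet) {
  stopifnot(inherits(x, "expr_matrix"), inherits(sheet, "sample_sheet"))
  missing <- setdiff(sample_ids(x), names(sheet$sample_to_group))
  if (length(missing)) {
    stop("sample(s) in matrix but not in sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Samples belonging to one group
#'
#' @param x An `expr_matrix`.
#' @param sheet A `sample_sheet`.
#' @param group Group name.
#' @return Character vector of sample ids present in the matrix.
#' @keywords internal
group_samples <- function(x, sheet, group) {
  s <- names(sheet$sample_to_group)[sheet$sample_to_group == group]
  intersect(sample_ids(x), s)
}
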