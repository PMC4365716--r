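#' Rank probes by descending fold change
#'
#' Assigns strict integer ranks 1..N (1 = largest fold change). Ties are
#' broken deterministically by ascending q-value and then lexicographic probe
#' identifier, so the result is always a permutation of 1..N.
#'
#' @param folds Per-probe fold changes.
#' @param q Optional per-probe q-values used as first tiebreak.
#' @param probe_id Optional probe identifiers (default: names of `folds`, else
#'   position) used as final tiebreak.
#' @return Integer vector of ranks aligned with the input.
#' @export
rank_by_fold_change <- function(folds, q = NULL, probe_id = NULL) {
  n <- length(folds)
  if (is.null(probe_id)) {
    probe_id <- if (!is.null(names(folds))) names(folds) else
      formatC(seq_len(n), width = nchar(n), flag = "0")
  }
  keys <- list(-folds)
  if (!is.null(q)) {
    if (length(q) != n) stop("q must align with folds", call. = FALSE)
    keys <- c(keys, list(q))
  }
  keys <- c(keys, list(as.character(probe_id)))
  ord <- do.call(order, keys)
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  ranks
}

#' Assign threshold-based consensus group labels
#'
#' A probe is a member of a target category when its fold change against the
#' maximum-expressing reference strictly exceeds the threshold. The label is
#' the slash-joined subset of categories (e.g. `"OV/HC/SC"`), or `"-"` for the
#' empty set.
#'
#' @param folds Numeric matrix or data frame of fold changes, probes in rows
#'   and one column per target category (column names are the category names).
#' @param threshold Strict fold-change threshold (default 4).
#' @param empty Rendering of the empty set (default `"-"`).
#' @return Character vector of labels with a `"membership"` attribute (the
#'   logical probes x categories matrix).
#' @export
#' @examples
#' f <- rbind(c(14.62, 233.46, 209.11), c(11.06, 1.07, 2.18))
#' colnames(f) <- c("OV", "HC", "SC")
#' assign_consensus_groups(f) # "OV/HC/SC", "OV"
assign_consensus_groups <- function(folds, threshold = 4, empty = "-") {
  folds <- as.matrix(folds)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  categories <- colnames(folds)
  if (is.null(categories)) {
    stop("fold matrix must carry category column names", call. = FALSE)
  }
  member <- folds > threshold
  labels <- apply(member, 1L, function(m) {
    if (any(m)) paste(categories[m], collapse = "/") else empty
  })
  attr(labels, "membership") <- member
  labels
}

#' Consensus score: sum of category ranks
#'
#' The rank-sum across target categories; smaller scores mean more
#' lineage-specific. With C categories the minimum achievable score is C,
#' attained only by a probe ranked first in every category.
#'
#' @param ranks Integer matrix (or data frame), probes x categories, each
#'   column a permutation-style rank vector with minimum 1.
#' @return Integer vector of scores.
#' @export
#' @examples
#' consensus_score(cbind(2, 3, 4)) # 9
consensus_score <- function(ranks) {
  ranks <- as.matrix(ranks)
  if (any(ranks < 1)) stop("ranks must be >= 1", call. = FALSE)
  as.integer(round(rowSums(ranks)))
}

#' Rank probes by consensus score
#'
#' Ascending score order, rank 1 = most lineage-specific. Ties are broken by
#' the best (smallest) single-category rank, then by probe identifier.
#'
#' @param scores Integer consensus scores.
#' @param best_rank Optional per-probe best single-category rank (tiebreak).
#' @param probe_id Optional probe identifiers (final tiebreak).
#' @return Integer vector of consensus ranks, a permutation of 1..N.
#' @export
consensus_rank <- function(scores, best_rank = NULL, probe_id = NULL) {
  n <- length(scores)
  if (is.null(probe_id)) {
    probe_id <- if (!is.null(names(scores))) names(scores) else
      formatC(seq_len(n), width = nchar(n), flag = "0")
  }
  keys <- list(scores)
  if (!is.null(best_rank)) {
    if (length(best_rank) != n) {
      stop("best_rank must align with scores", call. = FALSE)
    }
    keys <- c(keys, list(best_rank))
  }
  keys <- c(keys, list(as.character(probe_id)))
  ord <- do.call(order, keys)
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  ranks
}

#' Count probes passing volcano-plot cutoffs
#'
#' Number of probes with fold change strictly above `fc_cut` and q-value
#' strictly below `q_cut` (the upper-right region of a volcano plot).
#'
#' @param folds Per-probe fold changes.
#' @param q_values Aligned per-probe q-values.
#' @param fc_cut Fold-change cutoff (default 4).
#' @param q_cut q-value cutoff (default 0.001).
#' @return Integer count.
#' @export
volcano_counts <- function(folds, q_values, fc_cut = 4, q_cut = 0.001) {
  if (length(folds) != length(q_values)) {
    stop("folds and q_values must have the same length", call. = FALSE)
  }
  sum(folds > fc_cut & q_values < q_cut)
}

#' Overlap of a consensus set with the top k probes of a category
#'
#' How many of the probes above the consensus threshold in one category fall
#' within the top `k` probes of another category's ranking, and what fraction
#' of the consensus set that represents (also rendered as a one-decimal
#' percentage, the convention used for reporting).
#'
#' @param category_rank Integer ranks of all probes in the reference category.
#' @param in_consensus Logical vector: probe belongs to the consensus set.
#' @param k Size of the top list (must not exceed the number of probes).
#' @return List with `count`, `set_size`, `fraction` (`NA` for an empty set),
#'   and `percent` (fraction as a percentage rounded to one decimal).
#' @export
#' @examples
#' # 119 of 684 consensus probes inside the top 500
#' r <- seq_len(1000); cs <- r %in% c(1:119, 501:1065)[1:684]
top_k_overlap <- function(category_rank, in_consensus, k) {
  if (length(category_rank) != length(in_consensus)) {
    stop("category_rank and in_consensus must align", call. = FALSE)
  }
  if (k > length(category_rank)) {
    stop("k exceeds the number of probes", call. = FALSE)
  }
  set_size <- sum(in_consensus)
  count <- sum(in_consensus & category_rank <= k)
  fraction <- if (set_size > 0L) count / set_size else NA_real_
  list(count = count, set_size = set_size, fraction = fraction,
       percent = if (is.na(fraction)) NA_real_ else round(100 * fraction, 1))
}
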