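#' Lineage-specificity analysis pipeline
#'
#' Runs the full comparative analysis on a probes-by-samples matrix:
#'
#' 1. floor + log2 transform (if the matrix is on the linear scale), then one
#'    joint quantile normalization across all arrays;
#' 2. per-group means/SDs;
#' 3. for every target category, the fold change against the per-probe
#'    maximum-expressing reference group, a moderated t-test against that
#'    chosen reference (empirical-Bayes variance prior fitted per contrast
#'    family from the pooled two-group variances), Benjamini-Hochberg
#'    q-values over the contrast family, and descending fold-change ranks;
#' 4. a reference-vs-reference contrast (first two reference groups) as a
#'    detector of expression outside the target lineage;
#' 5. consensus group labels at the fold threshold, the rank-sum consensus
#'    score, and the consensus rank.
#'
#' @param x An `expr_matrix` (linear or log2 scale).
#' @param sheet A `sample_sheet` covering all samples of `x`.
#' @param floor Linear-scale floor applied before log2 (default 1).
#' @param normalize `"quantile"` (default) or `"none"`.
#' @param consensus_threshold Strict fold-change threshold for consensus group
#'   membership (default 4).
#' @param ref_q_cutoff Significance cutoff for the reference-vs-reference
#'   direction call (default 0.05).
#' @return Object of class `"lineage_result"`: list with
#'   * `table`: one row per probe (probe id, gene symbol, per-group mean/SD,
#'     per-category fold change / q-value / rank plus chosen reference,
#'     reference-contrast columns, consensus group/score/rank);
#'   * `group_summary`, `contrasts` (per category: the fold/test tables and
#'     fitted `variance_prior`), `reference_contrast`, `norm_report`,
#'     `target_order`, and `params`.
#' @export
#' @examples
#' sim <- generate_dataset(simulation_config(n_probes = 300), seed = 1)
#' res <- lineage_specificity(sim$matrix, sim$sheet)
#' head(res$table[, c("probe_id", "consensus_group", "consensus_score")])
lineage_specificity <- function(x, sheet, floor = 1,
                                normalize = c("quantile", "none"),
                                consensus_threshold = 4,
                                ref_q_cutoff = 0.05) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(x, "expr_matrix"), inherits(sheet, "sample_sheet"))
  validate_design(x, sheet)

  if (x$scale == "linear") x <- log2_transform(x, floor = floor)
  norm_report <- NULL
  if (normalize == "quantile") {
    qn <- quantile_normalize(x)
    x <- qn$matrix
    norm_report <- qn$report
  }

  gs <- group_summary(x, sheet)
  targets <- sheet$target_order
  refs <- sheet$reference_order

  contrasts <- list()
  fold_mat <- matrix(NA_real_, length(gs$probe_ids), length(targets),
                     dimnames = list(gs$probe_ids, targets))
  rank_mat <- fold_mat
  for (tg in targets) {
    mrfc <- max_reference_fold_change(gs, tg, refs)
    n1 <- gs$n[tg]
    n2 <- gs$n[mrfc$chosen_reference]
    dg <- n1 + n2 - 2
    ridx <- cbind(seq_len(nrow(gs$mean)),
                  match(mrfc$chosen_reference, colnames(gs$mean)))
    sg2 <- ((n1 - 1) * gs$sd[, tg]^2 + (n2 - 1) * gs$sd[ridx]^2) / dg
    prior <- fit_variance_prior(sg2, dg)
    tt <- moderated_t_test(gs, tg, mrfc$chosen_reference, prior)
    q <- bh_adjust(tt$p_value)
    rk <- rank_by_fold_change(mrfc$fold_change, q = q, probe_id = gs$probe_ids)
    contrasts[[tg]] <- list(
      fold_change = mrfc$fold_change,
      chosen_reference = mrfc$chosen_reference,
      t_stat = tt$t_stat, p_value = tt$p_value, q_value = q,
      rank = rk, prior = prior
    )
    fold_mat[, tg] <- mrfc$fold_change
    rank_mat[, tg] <- rk
  }

  ref_con <- if (length(refs) >= 2L) {
    reference_contrast(gs, refs[1], refs[2], q_cutoff = ref_q_cutoff)
  } else NULL

  labels <- assign_consensus_groups(fold_mat, threshold = consensus_threshold)
  score <- consensus_score(rank_mat)
  best <- apply(rank_mat, 1L, min)
  crank <- consensus_rank(score, best_rank = best, probe_id = gs$probe_ids)

  tab <- data.frame(probe_id = gs$probe_ids,
                    gene_symbol = unname(gs$gene_symbols),
                    stringsAsFactors = FALSE)
  for (g in colnames(gs$mean)) {
    tab[[paste0("mean_", g)]] <- gs$mean[, g]
    tab[[paste0("sd_", g)]] <- gs$sd[, g]
  }
  for (tg in targets) {
    con <- contrasts[[tg]]
    tab[[paste0("fold_", tg)]] <- con$fold_change
    tab[[paste0("ref_", tg)]] <- con$chosen_reference
    tab[[paste0("q_", tg)]] <- con$q_value
    tab[[paste0("rank_", tg)]] <- con$rank
  }
  if (!is.null(ref_con)) {
    tab$ref_fold_abs <- ref_con$fold_change_abs
    tab$ref_direction <- ref_con$direction
    tab$ref_q <- ref_con$q_value
  }
  tab$consensus_group <- as.character(labels)
  tab$consensus_score <- score
  tab$consensus_rank <- crank

  structure(
    list(table = tab, group_summary = gs, contrasts = contrasts,
         reference_contrast = ref_con, norm_report = norm_report,
         target_order = targets,
         params = list(floor = floor, normalize = normalize,
                       consensus_threshold = consensus_threshold,
                       ref_q_cutoff = ref_q_cutoff)),
    class = "lineage_result"
  )
}

#' @export
print.lineage_result <- function(x, ...) {
  cat(sprintf("lineage-specificity result: %d probes, categories: %s\n",
              nrow(x$table), paste(x$target_order, collapse = ", ")))
  thr <- x$params$consensus_threshold
  memb <- x$table$consensus_group != "-"
  cat(sprintf("probes above the %g-fold consensus threshold in >=1 category: %d\n",
              thr, sum(memb)))
  top <- x$table[order(x$table$consensus_rank), ][1:min(5, nrow(x$table)), ]
  cat("top probes by consensus rank:\n")
  print(top[, c("probe_id", "gene_symbol", "consensus_group",
                "consensus_score", "consensus_rank")], row.names = FALSE)
  invisible(x)
}
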