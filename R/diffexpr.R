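#' Per-group means and standard deviations
#'
#' Computes, for every probe and group, the mean log2 intensity, the sample
#' standard deviation (denominator n - 1), and the replicate count. Every
#' group must have at least two replicates so that a within-group variance is
#' defined.
#'
#' @param x An `expr_matrix` on the log2 scale.
#' @param sheet A `sample_sheet` covering all samples in `x`.
#' @return An object of class `"group_summary"`: list with `mean` and `sd`
#'   (probes x groups matrices), `n` (named replicate counts), `probe_ids`,
#'   and `gene_symbols`.
#' @export
group_summary <- function(x, sheet) {
  stopifnot(inherits(x, "expr_matrix"), inherits(sheet, "sample_sheet"))
  if (x$scale != "log2") {
    stop("group_summary expects log2-scale intensities", call. = FALSE)
  }
  validate_design(x, sheet)
  groups <- c(sheet$target_order, sheet$reference_order)
  means <- sds <- matrix(
    NA_real_, nrow(x$values), length(groups),
    dimnames = list(probe_ids(x), groups)
  )
  n <- stats::setNames(integer(length(groups)), groups)
  for (g in groups) {
    cols <- group_samples(x, sheet, g)
    if (length(cols) < 2L) {
      stop(sprintf("group '%s' has %d sample(s); at least 2 are required",
                   g, length(cols)), call. = FALSE)
    }
    sub <- x$values[, cols, drop = FALSE]
    m <- rowMeans(sub)
    means[, g] <- m
    sds[, g] <- sqrt(rowSums((sub - m)^2) / (length(cols) - 1L))
    n[g] <- length(cols)
  }
  structure(
    list(mean = means, sd = sds, n = n,
         probe_ids = probe_ids(x), gene_symbols = x$gene_symbols),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group summary: %d probes, groups: %s\n", length(x$probe_ids),
              paste(sprintf("%s (n=%d)", names(x$n), x$n), collapse = ", ")))
  invisible(x)
}

#' Linear-scale fold change from log2 means
#'
#' `fold_change(a, b)` returns `2^(a - b)`, the expression ratio implied by two
#' log2-scale mean intensities. Values below 1 represent depletion.
#'
#' @param a,b Log2-scale intensities (vectors recycle).
#' @return Positive numeric vector.
#' @export
#' @examples
#' fold_change(5, 3) # 4
fold_change <- function(a, b) 2^(a - b)

#' Fold change against the maximum-expressing reference group
#'
#' For every probe, picks the reference group with the highest mean intensity
#' and computes the target's fold change against it. Using the per-probe
#' maximum reference is the most conservative specificity estimate: the
#' resulting fold change never exceeds the fold change against any individual
#' reference group. Ties between reference means are resolved by the fixed
#' order of `references`.
#'
#' @param summary A `group_summary`.
#' @param target Target group name.
#' @param references Character vector of reference group names (>= 1).
#' @return `data.frame` with `probe_id`, `fold_change`, `chosen_reference`.
#' @export
max_reference_fold_change <- function(summary, target, references) {
  stopifnot(inherits(summary, "group_summary"), length(references) >= 1L)
  if (!target %in% colnames(summary$mean)) {
    stop("unknown target group: ", target, call. = FALSE)
  }
  missing <- setdiff(references, colnames(summary$mean))
  if (length(missing)) {
    stop("unknown reference group(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  refs <- summary$mean[, references, drop = FALSE]
  j <- max.col(refs, ties.method = "first")
  max_ref <- refs[cbind(seq_len(nrow(refs)), j)]
  data.frame(
    probe_id = summary$probe_ids,
    fold_change = fold_change(summary$mean[, target], max_ref),
    chosen_reference = references[j],
    stringsAsFactors = FALSE
  )
}

#' Empirical-Bayes prior for per-probe variances
#'
#' Fits a scaled inverse chi-square prior (`d0` degrees of freedom, prior
#' variance `s0_sq`) to a set of per-probe sample variances by moment-matching
#' the mean and variance of `log(s^2)` against the digamma/trigamma
#' expressions implied by `s^2 ~ s0^2 * chi^2_dg / dg` under the prior. If the
#' dispersion of `log(s^2)` does not exceed the sampling-only expectation, the
#' prior degrees of freedom are infinite and `s0_sq` is the bias-corrected
#' geometric mean of the variances. Estimates above `d0_cap` are reported as
#' infinite.
#'
#' @param s_sq Per-probe sample variances (log2-intensity scale, squared).
#' @param d_g Residual degrees of freedom of each variance (scalar or vector).
#' @param d0_cap Cap above which `d0` is declared infinite (default `1e6`).
#' @return Object of class `"variance_prior"`: list with `d0`, `s0_sq`, and
#'   `n_used` (number of positive finite variances used).
#' @export
fit_variance_prior <- function(s_sq, d_g, d0_cap = 1e6) {
  if (!is.numeric(s_sq) || !length(s_sq)) {
    stop("s_sq must be a numeric vector", call. = FALSE)
  }
  dg <- rep_len(as.numeric(d_g), length(s_sq))
  if (any(dg < 1)) stop("d_g must be >= 1", call. = FALSE)
  ok <- is.finite(s_sq) & s_sq > 0
  if (!any(ok)) {
    stop("all variances are zero or missing: degenerate data", call. = FALSE)
  }
  if (sum(ok) < 50L) {
    warning("fewer than 50 positive variances; prior estimate is unstable")
  }
  z <- log(s_sq[ok])
  dg <- dg[ok]
  e <- z - digamma(dg / 2) + log(dg / 2)
  n <- length(e)
  emean <- mean(e)
  evar <- if (n > 1L) sum((e - emean)^2) / (n - 1L) - mean(trigamma(dg / 2))
          else -Inf
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (!is.finite(d0) || d0 > d0_cap) d0 <- Inf
  } else {
    d0 <- Inf
  }
  s0_sq <- if (is.finite(d0)) {
    exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    exp(emean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = n),
            class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("variance prior: d0 = %s, s0^2 = %.6g (n = %d probes)\n",
              format(x$d0), x$s0_sq, x$n_used))
  invisible(x)
}

# Newton solver for trigamma(y) = x, monotone decreasing on (0, Inf).
# Relative tolerance 1e-8.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Moderated two-sample t-test
#'
#' Empirical-Bayes moderated t-statistic for a target group against a
#' reference group (possibly chosen per probe). The pooled two-sample variance
#' `s_g^2` on `dg = n1 + n2 - 2` degrees of freedom is shrunk toward the prior:
#' `s_tilde^2 = (d0 * s0^2 + dg * s_g^2) / (d0 + dg)`, and
#' `t = (mean1 - mean2) / (s_tilde * sqrt(1/n1 + 1/n2))` is referred to a t
#' distribution on `d0 + dg` degrees of freedom (standard normal when
#' `d0 = Inf`; the ordinary pooled t-test when `d0 = 0`). Shrinkage is what
#' keeps inference stable for groups with as few as two replicates.
#'
#' @param summary A `group_summary`.
#' @param target Target group name.
#' @param reference Reference group name; either a single name or one per
#'   probe (e.g. the `chosen_reference` from [max_reference_fold_change()]).
#' @param prior A `variance_prior` (or list with `d0` and `s0_sq`).
#' @return `data.frame` with `probe_id`, `t_stat`, `p_value`, `df_total`, and
#'   `pooled_var`.
#' @export
moderated_t_test <- function(summary, target, reference, prior) {
  stopifnot(inherits(summary, "group_summary"))
  if (is.null(prior$d0) || is.null(prior$s0_sq)) {
    stop("prior must provide d0 and s0_sq", call. = FALSE)
  }
  groups <- colnames(summary$mean)
  if (!target %in% groups) stop("unknown target group: ", target, call. = FALSE)
  reference <- rep_len(as.character(reference), length(summary$probe_ids))
  bad <- setdiff(unique(reference), groups)
  if (length(bad)) {
    stop("unknown reference group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n1 <- summary$n[target]
  n2 <- summary$n[reference]
  if (n1 < 2L || any(n2 < 2L)) {
    stop("both compared groups need at least 2 replicates", call. = FALSE)
  }
  ridx <- cbind(seq_along(reference), match(reference, groups))
  m1 <- summary$mean[, target]
  m2 <- summary$mean[ridx]
  v1 <- summary$sd[, target]^2
  v2 <- summary$sd[ridx]^2
  dg <- n1 + n2 - 2
  sg2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  d0 <- prior$d0
  s0 <- prior$s0_sq
  if (is.finite(d0)) {
    st2 <- (d0 * s0 + dg * sg2) / (d0 + dg)
    df <- d0 + dg
  } else {
    st2 <- rep_len(s0, length(sg2))
    df <- Inf
  }
  t_stat <- (m1 - m2) / sqrt(st2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  data.frame(
    probe_id = summary$probe_ids,
    t_stat = t_stat,
    p_value = p,
    df_total = df,
    pooled_var = sg2,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i}
#' (p_(j) * m / j)`, capped at 1 and mapped back to input order. Wraps
#' `stats::p.adjust(method = "BH")` after validating the input.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Contrast between two reference groups
#'
#' Used as a detector of expression outside the target lineage: if a probe's
#' gene were not substantially expressed in non-target tissue, the two
#' reference groups should not differ. Reports the absolute fold change
#' `2^|A - B|`, the direction (which reference group is up-regulated, or
#' `"NS"` when the q-value exceeds the significance cutoff), and the q-value
#' from a moderated t-test between the two groups.
#'
#' @param summary A `group_summary`.
#' @param ref_a,ref_b The two reference group names.
#' @param q_cutoff Significance cutoff for calling a direction (default 0.05).
#' @param prior Optional `variance_prior`; fitted from the pooled two-group
#'   variances when `NULL`.
#' @return `data.frame` with `probe_id`, `fold_change_abs`, `direction`,
#'   `q_value` (and `p_value`).
#' @export
reference_contrast <- function(summary, ref_a, ref_b, q_cutoff = 0.05,
                               prior = NULL) {
  stopifnot(inherits(summary, "group_summary"))
  n <- summary$n[c(ref_a, ref_b)]
  if (any(is.na(n)) || any(n < 2L)) {
    stop("both reference groups need at least 2 replicates", call. = FALSE)
  }
  if (is.null(prior)) {
    dg <- sum(n) - 2L
    sg2 <- ((n[1] - 1) * summary$sd[, ref_a]^2 +
              (n[2] - 1) * summary$sd[, ref_b]^2) / dg
    prior <- fit_variance_prior(sg2, dg)
  }
  tt <- moderated_t_test(summary, ref_a, ref_b, prior)
  q <- bh_adjust(tt$p_value)
  delta <- summary$mean[, ref_a] - summary$mean[, ref_b]
  direction <- ifelse(q > q_cutoff, "NS", ifelse(delta >= 0, ref_a, ref_b))
  data.frame(
    probe_id = summary$probe_ids,
    fold_change_abs = 2^abs(delta),
    direction = direction,
    p_value = tt$p_value,
    q_value = q,
    stringsAsFactors = FALSE
  )
}
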