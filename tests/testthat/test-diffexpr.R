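test_that("group summaries use sample SD and require replicates", {
  vals <- rbind(c(3, 3, 3, 1, 2, 3),
                c(5, 6, 7, 2, 2, 2))
  colnames(vals) <- c(paste0("a", 1:3), paste0("b", 1:3))
  rownames(vals) <- c("p1", "p2")
  x <- expression_matrix(vals, scale = "log2")
  sheet <- sample_sheet(colnames(vals), rep(c("A", "B"), each = 3),
                        c(A = "target", B = "reference"))
  gs <- group_summary(x, sheet)
  expect_equal(gs$mean["p1", ], c(A = 3, B = 2))
  expect_equal(gs$sd["p1", ], c(A = 0, B = 1))
  expect_equal(gs$mean["p2", "A"], 6)
  expect_equal(gs$n, c(A = 3L, B = 3L))

  lone <- sample_sheet(colnames(vals), c("A", "A", "A", "B", "B", "C"),
                       c(A = "target", B = "reference", C = "reference"))
  expect_error(group_summary(x, lone), "'C' has 1 sample")
})

test_that("group means recover planted means within sampling error", {
  sim <- generate_dataset(
    simulation_config(n_probes = 2000L, array_shift_sd = 0,
                      array_scale_sd = 0, array_warp_max = 0),
    seed = 31
  )
  gs <- group_summary(log2_transform(sim$matrix), sim$sheet)
  ok <- 0
  for (g in names(gs$n)) {
    se <- sqrt(sim$truth$true_var / gs$n[g])
    ok <- ok + sum(abs(gs$mean[, g] - sim$truth[[paste0("mean_", g)]]) < 3 * se)
  }
  expect_gt(ok / (2000 * length(gs$n)), 0.99)
})

test_that("fold_change is 2^(a-b) with exact reciprocity", {
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(5, 3), 4)
  # printed worked example: mean and fold published for the top probe
  a <- 10.97366167
  b <- a - log2(15.316797)
  expect_equal(fold_change(a, b), 15.316797, tolerance = 1e-9)
  set.seed(3)
  aa <- rnorm(50); bb <- rnorm(50)
  expect_equal(fold_change(aa, bb) * fold_change(bb, aa), rep(1, 50))
})

test_that("max-reference fold change picks the highest reference and is conservative", {
  vals <- rbind(p1 = c(10, 10, 7, 7, 8, 8),
                p2 = c(6, 6, 8, 8, 5, 5),   # ref A > target > ref B
                p3 = c(9, 9, 7, 7, 7, 7))   # tied references
  colnames(vals) <- paste0("s", 1:6)
  x <- expression_matrix(vals, scale = "log2")
  sheet <- sample_sheet(colnames(vals), rep(c("T", "R1", "R2"), each = 2),
                        c(T = "target", R1 = "reference", R2 = "reference"))
  gs <- group_summary(x, sheet)
  mrfc <- max_reference_fold_change(gs, "T", c("R1", "R2"))
  expect_equal(mrfc$fold_change[1], 4)
  expect_identical(mrfc$chosen_reference[1], "R2")
  expect_lt(mrfc$fold_change[2], 1)          # depletion representable
  expect_identical(mrfc$chosen_reference[3], "R1")  # tie -> fixed order

  # conservativeness: never exceeds the fold vs any single reference
  sim <- generate_dataset(simulation_config(n_probes = 500L), seed = 8)
  gs2 <- group_summary(quantile_normalize(log2_transform(sim$matrix))$matrix,
                       sim$sheet)
  refs <- sim$sheet$reference_order
  fmax <- max_reference_fold_change(gs2, "OV", refs)$fold_change
  for (r in refs) {
    single <- fold_change(gs2$mean[, "OV"], gs2$mean[, r])
    expect_true(all(fmax <= single + 1e-12))
  }
})

test_that("variance prior: infinite-d0 branch, two-value case, Monte-Carlo recovery", {
  # no excess dispersion -> infinite prior df, geometric-mean-based scale
  pr <- suppressWarnings(fit_variance_prior(rep(0.04, 30), d_g = 4))
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, exp(mean(log(0.04)) - digamma(2) + log(2)))

  # two widely separated repeated variances (dispersion beyond the
  # chi-square sampling expectation): finite d0, s0^2 between them
  s2 <- rep(c(0.01, 0.5), each = 100)
  pr2 <- fit_variance_prior(s2, d_g = 4)
  expect_true(is.finite(pr2$d0) && pr2$d0 > 0)
  expect_gt(pr2$s0_sq, 0.01)
  expect_lt(pr2$s0_sq, 0.5)

  # recovery of a known scaled-inverse-chi-square prior
  set.seed(101)
  true_var <- 4 * 0.04 / rchisq(5000, df = 4)
  s2_obs <- true_var * rchisq(5000, df = 4) / 4
  pr3 <- fit_variance_prior(s2_obs, d_g = 4)
  expect_lt(abs(pr3$d0 - 4) / 4, 0.30)
  expect_lt(abs(pr3$s0_sq - 0.04) / 0.04, 0.15)

  expect_error(fit_variance_prior(rep(0, 100), 4), "degenerate")
})

test_that("variance prior fit matches the independent reference implementation", {
  skip_if_not_installed("limma")
  set.seed(55)
  s2 <- (4 * 0.05 / rchisq(3000, 4)) * rchisq(3000, 6) / 6
  pr <- fit_variance_prior(s2, d_g = 6)
  fd <- limma::fitFDist(s2, df1 = 6)
  expect_equal(pr$d0, fd$df2, tolerance = 1e-6)
  expect_equal(pr$s0_sq, fd$scale, tolerance = 1e-6)
})

test_that("moderated t: hand formula, d0 = 0 limit, equal means", {
  vals <- rbind(p1 = c(3, 2, 1, 1, 0, -1),    # means 2 vs 0, pooled s^2 = 1
                p2 = c(4, 5, 6, 4, 5, 6))     # equal means
  colnames(vals) <- paste0("s", 1:6)
  x <- expression_matrix(vals, scale = "log2")
  sheet <- sample_sheet(colnames(vals), rep(c("A", "B"), each = 3),
                        c(A = "target", B = "reference"))
  gs <- group_summary(x, sheet)

  tt <- moderated_t_test(gs, "A", "B", list(d0 = 4, s0_sq = 1))
  # oracle: direct evaluation of the posterior-variance formula
  st2 <- (4 * 1 + 4 * 1) / (4 + 4)
  t_exp <- 2 / sqrt(st2 * (2 / 3))
  expect_equal(tt$t_stat[1], t_exp)
  expect_equal(tt$df_total[1], 8)
  expect_equal(tt$p_value[1], 2 * pt(-t_exp, df = 8))
  expect_equal(tt$t_stat[2], 0)
  expect_equal(tt$p_value[2], 1)

  # d0 = 0: ordinary pooled two-sample t-test
  t0 <- moderated_t_test(gs, "A", "B", list(d0 = 0, s0_sq = 1))
  classic <- t.test(vals[1, 1:3], vals[1, 4:6], var.equal = TRUE)
  expect_equal(t0$t_stat[1], unname(classic$statistic), tolerance = 1e-12)
  expect_equal(t0$p_value[1], classic$p.value, tolerance = 1e-12)
})

test_that("moderated t matches the independent empirical-Bayes reference", {
  skip_if_not_installed("limma")
  set.seed(9)
  n <- 1000
  sdv <- sqrt(4 * 0.04 / rchisq(n, 4))
  vals <- matrix(rnorm(n * 6, 0, sdv), n) + 8
  dimnames(vals) <- list(sprintf("p%04d", 1:n), paste0("s", 1:6))
  fit <- limma::eBayes(limma::lmFit(vals, cbind(1, rep(c(0, 1), each = 3))))
  x <- expression_matrix(vals, scale = "log2")
  sheet <- sample_sheet(paste0("s", 1:6), rep(c("B", "A"), each = 3),
                        c(A = "target", B = "reference"))
  gs <- group_summary(x, sheet)
  sg2 <- (2 * gs$sd[, "A"]^2 + 2 * gs$sd[, "B"]^2) / 4
  pr <- fit_variance_prior(sg2, 4)
  tt <- moderated_t_test(gs, "A", "B", pr)
  expect_equal(tt$t_stat, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(tt$p_value, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("BH adjustment: frozen example, properties, input validation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  set.seed(77)
  for (i in 1:20) {
    p <- runif(sample(1:20, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    expect_false(is.unsorted(q[order(p)]))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("reference contrast flags direction only when significant", {
  set.seed(19)
  n <- 400
  sdv <- 0.15
  base <- runif(n, 6, 12)
  mean_a <- base
  mean_b <- base
  planted <- 1:20
  mean_b[planted] <- mean_b[planted] + log2(2.4)  # embryo-specific genes
  vals <- cbind(matrix(rep(mean_a, 3), n) + rnorm(3 * n, 0, sdv),
                matrix(rep(mean_b, 3), n) + rnorm(3 * n, 0, sdv))
  dimnames(vals) <- list(sprintf("p%04d", 1:n),
                         c(paste0("peri", 1:3), paste0("emb", 1:3)))
  x <- expression_matrix(vals, scale = "log2")
  # minimal design: the two non-target reference tissues under comparison
  sheet <- sample_sheet(colnames(vals), rep(c("periotic", "embryo"), each = 3),
                        c(periotic = "target", embryo = "reference"))
  gs <- group_summary(x, sheet)
  rc <- reference_contrast(gs, "periotic", "embryo")

  # planted 2.4-fold embryo-specific genes are called for embryo
  expect_gte(mean(rc$direction[planted] == "embryo" & rc$q_value[planted] < 0.05),
             0.90)
  # identical means are overwhelmingly NS
  expect_gt(mean(rc$direction[-planted] == "NS"), 0.9)
  expect_equal(rc$fold_change_abs[planted[1]],
               2^abs(gs$mean[planted[1], "periotic"] - gs$mean[planted[1], "embryo"]))
  expect_true(all(rc$fold_change_abs >= 1))
})

test_that("moderated t with infinite prior df equals the normal-limit closed form", {
  sim <- two_group_matrix(mean_a = c(8, 9, 10), mean_b = c(8, 8.5, 11))
  gs <- group_summary(sim$matrix, sim$sheet)
  s0 <- 0.09
  tt <- moderated_t_test(gs, "A", "B", list(d0 = Inf, s0_sq = s0))
  delta <- gs$mean[, "A"] - gs$mean[, "B"]
  t_closed <- delta / (sqrt(s0) * sqrt(2 / 3))
  expect_equal(tt$t_stat, unname(t_closed), tolerance = 1e-10)
  expect_equal(tt$p_value, unname(2 * pnorm(-abs(t_closed))), tolerance = 1e-10)
})

test_that("null simulation keeps type-I error at nominal level", {
  set.seed(42)
  n <- 10000
  sdv <- sqrt(4 * 0.04 / rchisq(n, 4))
  vals <- matrix(rnorm(n * 6, 0, sdv), n) + 8
  dimnames(vals) <- list(sprintf("p%05d", 1:n), paste0("s", 1:6))
  x <- expression_matrix(vals, scale = "log2")
  sheet <- sample_sheet(paste0("s", 1:6), rep(c("A", "B"), each = 3),
                        c(A = "target", B = "reference"))
  tt <- moderated_t_test(group_summary(x, sheet), "A", "B",
                         list(d0 = 4, s0_sq = 0.04))
  for (alpha in c(0.05, 0.01)) {
    rate <- mean(tt$p_value < alpha)
    expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / n))
  }
})
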