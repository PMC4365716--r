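# shared helpers: tiny designs built in code, plus the packaged ranking tables

toy_matrix <- function(values, scale = "log2", symbols = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  expression_matrix(values, gene_symbols = symbols, scale = scale)
}

# two groups x `n_rep` replicates with given per-group log2 means
two_group_matrix <- function(mean_a, mean_b, n_rep = 3, noise_sd = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(mean_a)
  vals <- cbind(
    matrix(rep(mean_a, n_rep), n) + matrix(rnorm(n * n_rep, 0, noise_sd), n),
    matrix(rep(mean_b, n_rep), n) + matrix(rnorm(n * n_rep, 0, noise_sd), n)
  )
  rownames(vals) <- sprintf("p%04d", seq_len(n))
  colnames(vals) <- c(paste0("a", seq_len(n_rep)), paste0("b", seq_len(n_rep)))
  list(
    matrix = expression_matrix(vals, scale = "log2"),
    sheet = sample_sheet(colnames(vals), rep(c("A", "B"), each = n_rep),
                         roles = c(A = "target", B = "reference"))
  )
}

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "lineageRank")
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# published top-30 rankings (otic vesicle / hair cell / supporting cell study)
ov_top30 <- function() read_fixture("ov_top30.tsv")
otic_by_ov_rank <- function() read_fixture("otic_top30_by_ov_rank.tsv")
otic_by_consensus <- function() read_fixture("otic_top30_by_consensus.tsv")

# brute-force Benjamini-Hochberg step-up oracle: q_(i) = min_{j>=i} p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q
}
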