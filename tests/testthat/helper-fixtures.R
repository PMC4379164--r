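# Shared fixture builders (everything generated in code, no stored data).

tiny_design <- function(n_pairs = 2, extra = NULL) {
  d <- data.frame(
    sample_id = as.vector(rbind(sprintf("P%d_case", seq_len(n_pairs)),
                                sprintf("P%d_ctrl", seq_len(n_pairs)))),
    group = rep(c("case", "control"), n_pairs),
    pair_id = rep(sprintf("P%d", seq_len(n_pairs)), each = 2),
    set = "A_train",
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) d <- rbind(d, extra)
  as_sample_design(d)
}

write_tiny_expression <- function(values, path) {
  df <- data.frame(probe = rownames(values), values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent oracle for the variance-prior moment fit: same moment
# equations, solved by uniroot rather than Newton iteration
oracle_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (evar <= 0) return(list(d0 = Inf, s0sq = exp(mean(e))))
  g <- function(x) trigamma(x) - evar
  half_d0 <- uniroot(g, c(1e-6, 1e8), tol = 1e-12)$root
  list(d0 = 2 * half_d0,
       s0sq = exp(mean(e) + digamma(half_d0) - log(half_d0)))
}

# heteroskedastic paired-difference matrix: per-feature variances drawn from
# a scaled inverse chi-square so the moment fit has a finite d0 truth
hetero_pair_diffs <- function(n_features, n_pairs, d0 = 4, s0sq = 0.25,
                              mu = 0, seed = 1) {
  set.seed(seed)
  sigma2 <- d0 * s0sq / rchisq(n_features, df = d0)
  D <- matrix(rnorm(n_features * n_pairs, mu, sqrt(sigma2)), n_features)
  rownames(D) <- sprintf("F%04d", seq_len(n_features))
  D
}

# expression-matrix-plus-design wrapper around a difference fixture: builds
# case = ctrl + diff so paired_moderated_t sees exactly those differences
matrix_from_diffs <- function(D, seed = 1) {
  set.seed(seed)
  n <- ncol(D)
  base <- matrix(rnorm(nrow(D) * n, 8, 1), nrow(D))
  vals <- matrix(0, nrow(D), 2 * n)
  vals[, seq(1, 2 * n, 2)] <- base + D   # cases
  vals[, seq(2, 2 * n, 2)] <- base       # controls
  rownames(vals) <- rownames(D)
  colnames(vals) <- as.vector(rbind(sprintf("P%d_case", 1:n),
                                    sprintf("P%d_ctrl", 1:n)))
  list(m = vals, design = tiny_design(n))
}

round_half_up_vec <- function(x) sign(x) * floor(abs(x) + 0.5)
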