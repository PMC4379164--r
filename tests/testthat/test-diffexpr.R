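# explicit rank-expansion oracle for quantile normalization (independent of
# the implementation path): sort each column, average across columns per
# quantile slot, map back through ranks, averaging slots on ties
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    r <- rank(col, ties.method = "min")
    cnt <- table(r)
    vapply(seq_along(col), function(i) {
      slots <- r[i]:(r[i] + cnt[[as.character(r[i])]] - 1L)
      mean(ref[slots])
    }, numeric(1))
  })
}

test_that("quantile normalization matches the hand-computed example", {
  m <- cbind(c(1, 2, 3), c(4, 6, 8))
  out <- quantile_normalize(m)
  # sorted-column means: (2.5, 4, 5.5); both columns are already ascending
  expect_equal(out, cbind(c(2.5, 4, 5.5), c(2.5, 4, 5.5)))
})

test_that("quantile normalization equalizes columns, keeps ranks, averages ties", {
  set.seed(1)
  m <- matrix(rnorm(200), 40, 5)
  out <- quantile_normalize(m)
  sorted <- apply(out, 2, sort)
  for (j in 2:5) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  for (j in 1:5) expect_identical(rank(out[, j]), rank(m[, j]))

  tie <- cbind(c(1, 1, 2), c(5, 7, 9))
  expect_equal(quantile_normalize(tie), qn_oracle(tie))
  set.seed(2)
  tied_big <- matrix(sample(1:5, 60, replace = TRUE), 20, 3)
  expect_equal(quantile_normalize(tied_big), qn_oracle(tied_big))

  # identical columns and single columns are unchanged
  same <- cbind(c(3, 1, 2), c(3, 1, 2))
  expect_equal(quantile_normalize(same), same)
  one <- matrix(c(5, 1, 7), 3, 1)
  expect_identical(quantile_normalize(one), one)
})

test_that("quantile normalization matches limma on tie-free matrices", {
  skip_if_not_installed("limma")
  set.seed(3)
  m <- matrix(rnorm(150), 30, 5)
  expect_equal(quantile_normalize(m), limma::normalizeQuantiles(m),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("preprocess offsets, logs, normalizes and flips the state flag", {
  vals <- matrix(c(0, 1, 3, 7, 15, 31), 3,
                 dimnames = list(c("p1", "p2", "p3"), c("P1_case", "P1_ctrl")))
  m <- expression_matrix(vals, "raw")
  out <- preprocess(m)
  expect_identical(expr_state(out), "log2_normalized")
  expect_equal(unclass(out), qn_oracle(log2(vals + 1)), ignore_attr = TRUE)

  const <- expression_matrix(matrix(5, 3, 2, dimnames = dimnames(vals)), "raw")
  expect_true(all(unclass(preprocess(const)) == log2(6)))

  expect_error(preprocess(out), "already preprocessed")
  expect_error(expression_matrix(matrix(-1, 2, 2,
                                        dimnames = list(c("a", "b"),
                                                        c("x", "y"))), "raw"),
               "non-negative")
})

test_that("d0 = 0 reduces the moderated t to the ordinary paired t", {
  D <- hetero_pair_diffs(200, 6, seed = 3)
  fx <- matrix_from_diffs(D)
  res <- paired_moderated_t(fx$m, fx$design, d0 = 0)
  ord <- t(apply(D, 1, function(d) {
    tt <- t.test(d)
    c(tt$statistic, tt$p.value)
  }))
  expect_equal(res$t_mod, unname(ord[, 1]), tolerance = 1e-10)
  expect_equal(res$p, unname(ord[, 2]), tolerance = 1e-10)
})

test_that("d0 = Inf gives the fully shrunk statistic", {
  D <- hetero_pair_diffs(100, 5, seed = 4)
  fx <- matrix_from_diffs(D)
  res <- paired_moderated_t(fx$m, fx$design, d0 = Inf, s0sq = 0.3)
  expect_equal(res$t_mod, unname(rowMeans(D)) / sqrt(0.3 / 5),
               tolerance = 1e-12)
})

test_that("the full moderated t matches an independent moment-fit oracle", {
  D <- hetero_pair_diffs(1000, 4, d0 = 5, s0sq = 0.4, seed = 5)
  fx <- matrix_from_diffs(D)
  res <- paired_moderated_t(fx$m, fx$design)

  n <- 4
  s2 <- apply(D, 1, var)
  prior <- oracle_variance_prior(s2, n - 1)
  expect_equal(res$d0[1], prior$d0, tolerance = 1e-8)
  expect_equal(res$s0sq[1], prior$s0sq, tolerance = 1e-8)
  st2 <- (prior$d0 * prior$s0sq + (n - 1) * s2) / (prior$d0 + n - 1)
  t_oracle <- rowMeans(D) / sqrt(st2 / n)
  p_oracle <- 2 * pt(-abs(t_oracle), prior$d0 + n - 1)
  expect_equal(res$t_mod, unname(t_oracle), tolerance = 1e-8)
  expect_equal(res$p, unname(p_oracle), tolerance = 1e-8)
})

test_that("the moderated t agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  D <- hetero_pair_diffs(500, 8, d0 = 6, s0sq = 0.5, seed = 6)
  fx <- matrix_from_diffs(D)
  res <- paired_moderated_t(fx$m, fx$design)
  fit <- limma::eBayes(limma::lmFit(D, matrix(1, ncol(D), 1)))
  expect_equal(res$d0[1], fit$df.prior, tolerance = 1e-6)
  expect_equal(res$s0sq[1], fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, 1]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, 1]), tolerance = 1e-6)
})

test_that("moderation shrinks every t between ordinary and fully shrunk", {
  D <- hetero_pair_diffs(300, 6, seed = 8)
  fx <- matrix_from_diffs(D)
  full <- paired_moderated_t(fx$m, fx$design)
  plain <- paired_moderated_t(fx$m, fx$design, d0 = 0)
  lim <- paired_moderated_t(fx$m, fx$design, d0 = Inf,
                            s0sq = full$s0sq[1])
  lo <- pmin(abs(plain$t_mod), abs(lim$t_mod))
  hi <- pmax(abs(plain$t_mod), abs(lim$t_mod))
  expect_true(all(abs(full$t_mod) >= lo - 1e-12))
  expect_true(all(abs(full$t_mod) <= hi + 1e-12))
})

test_that("select_de applies strict gates and counts unique genes", {
  res <- data.frame(
    feature_id = c("pr1", "pr2", "pr3", "pr4"),
    p = c(0.04, 0.04, 0.06, 0.01),
    FC = c(1.6, 1.4, 2.0, -1.8),
    stringsAsFactors = FALSE
  )
  sel <- select_de(res, probe_to_gene = c(pr1 = "geneA", pr2 = "geneB",
                                          pr3 = "geneC", pr4 = "geneA"))
  expect_identical(sel$n_probes_selected, 2L)
  expect_identical(sel$n_unique_genes, 1L)
  expect_setequal(sel$selected, c("pr1", "pr4"))

  none <- select_de(data.frame(feature_id = "x", p = 0.5, FC = 1.1))
  expect_identical(none$n_probes_selected, 0L)
  expect_identical(none$n_unique_genes, 0L)

  # boundary values are excluded (strict inequalities)
  edge <- select_de(data.frame(feature_id = c("a", "b"),
                               p = c(0.05, 0.049), FC = c(2, 1.5)))
  expect_identical(edge$n_probes_selected, 0L)
})

test_that("fold changes are signed symmetrically around 1", {
  D <- hetero_pair_diffs(50, 6, mu = 0.4, seed = 9)
  fx <- matrix_from_diffs(D)
  res <- paired_moderated_t(fx$m, fx$design)
  expect_true(all(abs(res$FC) >= 1))
  expect_equal(abs(res$FC), 2^abs(res$logFC))
  # swapping case and control negates logFC and FC
  sw <- fx$design
  sw$group <- ifelse(sw$group == "case", "control", "case")
  res_sw <- paired_moderated_t(fx$m, as_sample_design(as.data.frame(sw)))
  expect_equal(res_sw$logFC, -res$logFC)
  expect_equal(abs(res_sw$FC), abs(res$FC))
})

test_that("null data keep the nominal type-I error rate", {
  sim <- simulate_expression(14, 2000, n_de = 0, seed = 12)
  res <- paired_moderated_t(preprocess(sim$expr), sim$design)
  frac <- mean(res$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("selection count grows with planted effect size", {
  counts <- vapply(c(0.3, 0.6, 1.0), function(b) {
    sim <- simulate_expression(14, 800, n_de = 80,
                               effect_log2 = function(n) rep(b, n),
                               seed = 21)
    res <- paired_moderated_t(preprocess(sim$expr), sim$design)
    select_de(res)$n_probes_selected
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("degenerate inputs error", {
  D <- matrix(0, 5, 4, dimnames = list(letters[1:5], NULL))
  fx <- matrix_from_diffs(D)
  vals <- fx$m * 0 + 5  # constant matrix: zero variance everywhere
  expect_error(paired_moderated_t(vals, fx$design), "zero variance")
  expect_error(paired_moderated_t(fx$m[, 1:2, drop = FALSE],
                                  tiny_design(1)), "at least 2")
})
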