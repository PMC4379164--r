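test_that("ratios are -Ct differences that cancel per-sample shifts", {
  ct <- matrix(c(20, 22, 24,
                 21, 22, 26), nrow = 3,
               dimnames = list(c("g1", "norm", "g3"), c("s1", "s2")))
  r <- make_ratios(ct, "norm")
  # Ct_gene = 20, Ct_norm = 22: gene is 4-fold more abundant, r = +2
  expect_equal(r["g1/norm", "s1"], 2)
  expect_equal(r["g3/norm", "s1"], -2)
  # the self-ratio is excluded
  expect_false("norm/norm" %in% rownames(r))
  expect_identical(nrow(r), 2L)
  # adding a constant to every Ct of one sample changes nothing
  ct2 <- ct; ct2[, "s2"] <- ct2[, "s2"] + 3.7
  expect_equal(make_ratios(ct2, "norm"), make_ratios(ct, "norm"))

  expect_error(make_ratios(ct, "absent"), "missing from panel")

  # samples missing the normalizer are excluded and flagged
  ct3 <- ct; ct3["norm", "s2"] <- NA
  r3 <- make_ratios(ct3, "norm")
  expect_identical(colnames(r3), "s1")
  expect_identical(attr(r3, "excluded_samples"), "s2")
})

test_that("ranking gates on 1.2-fold and orders by moderated-t p", {
  set.seed(5)
  n <- 14
  lab <- rep(c("case", "control"), each = n)
  mk <- function(delta, sd = 1) c(rnorm(n, delta, sd), rnorm(n, 0, sd))
  feats <- rbind(f1 = mk(2.0), f2 = mk(0.5), f3 = mk(0.0))
  rk <- rank_ratios(feats, lab)
  expect_identical(rk[1], "f1")
  st <- attr(rk, "stats")
  # anything under the log2(1.2) ~ 0.263 gate is discarded
  gated <- st$feature_id[abs(st$logFC) < log2(1.2)]
  expect_true(!any(gated %in% rk))

  # a feature with group difference log2(1.1) is below the gate
  f <- matrix(c(rep(log2(1.1), n) + rnorm(n, 0, 1e-6), rnorm(n, 0, 1e-6)),
              nrow = 1, dimnames = list("weak", NULL))
  expect_length(rank_ratios(f, lab), 0)

  # scale invariance of the ranking
  rk10 <- rank_ratios(feats * 10, lab, fc_min_ratio = 1)
  rk1 <- rank_ratios(feats, lab, fc_min_ratio = 1)
  expect_identical(c(rk10), c(rk1))
})

test_that("three-feature toy ranking matches an independent recomputation", {
  set.seed(8)
  n <- 10
  lab <- rep(c("case", "control"), each = n)
  feats <- rbind(f1 = c(rnorm(n, 2), rnorm(n)),
                 f2 = c(rnorm(n, 0.5), rnorm(n)),
                 f3 = c(rnorm(n, 0), rnorm(n)))
  st <- attr(rank_ratios(feats, lab, fc_min_ratio = 1), "stats")
  # oracle: pooled-variance two-sample t moderated with the oracle prior
  s2 <- apply(feats, 1, function(x)
    ((n - 1) * var(x[1:n]) + (n - 1) * var(x[-(1:n)])) / (2 * n - 2))
  pr <- oracle_variance_prior(s2, 2 * n - 2)
  st2 <- (pr$d0 * pr$s0sq + (2 * n - 2) * s2) / (pr$d0 + 2 * n - 2)
  diff <- apply(feats, 1, function(x) mean(x[1:n]) - mean(x[-(1:n)]))
  t_or <- diff / sqrt(st2 * (2 / n))
  expect_equal(st$t_mod, unname(t_or), tolerance = 1e-8)
})

test_that("two-class LDA matches closed-form algebra and names collinear pairs", {
  # 1-D symmetric classes with equal priors: boundary at 0
  x <- matrix(c(-1.2, -1, -0.8, 0.8, 1, 1.2), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c("control", "case"), each = 3)
  fit <- fit_lda(x, y)
  expect_equal(predict(fit, matrix(0, 1, 1)), 0, tolerance = 1e-12)
  expect_gt(predict(fit, matrix(1, 1, 1)), 0)

  # 2-D toy: discriminant direction equals solve(Sigma, mu1 - mu0)
  set.seed(3)
  x2 <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  x2[1:10, ] <- x2[1:10, ] + matrix(c(1, 2), 10, 2, byrow = TRUE)
  y2 <- rep(c("case", "control"), each = 10)
  fit2 <- fit_lda(x2, y2)
  mu1 <- colMeans(x2[1:10, ]); mu0 <- colMeans(x2[11:20, ])
  S <- ((9 * cov(x2[1:10, ])) + (9 * cov(x2[11:20, ]))) / 18
  expect_equal(unname(fit2$w), unname(solve(S, mu1 - mu0)), tolerance = 1e-10)

  # duplicated feature column errors, naming the pair
  x3 <- cbind(x2, a2 = x2[, "a"])
  expect_error(fit_lda(x3, y2), "collinear")
})

test_that("LDA scores agree with the MASS cross-check up to ordering", {
  skip_if_not_installed("MASS")
  set.seed(4)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  x[1:15, ] <- x[1:15, ] + 1
  y <- rep(c("case", "control"), each = 15)
  ours <- predict(fit_lda(x, y), x)
  mfit <- MASS::lda(x, grouping = factor(y, levels = c("control", "case")))
  post <- predict(mfit, x)$posterior[, "case"]
  # same ranking of samples and same sign of the log-posterior-odds
  expect_equal(order(ours), order(qlogis(post)))
  expect_equal(unname(sign(ours)), unname(sign(qlogis(post))))
})

test_that("cross-validated criterion behaves at its limits", {
  set.seed(6)
  n <- 14
  lab <- rep(c("case", "control"), each = n)
  pid <- c(sprintf("P%02d", 1:n), sprintf("P%02d", 1:n))
  # a perfectly separating planted ratio
  feats <- rbind(hit = c(rnorm(n, 10, 0.1), rnorm(n, 0, 0.1)),
                 null1 = rnorm(2 * n), null2 = rnorm(2 * n))
  cfg <- cv_config(seed = 1)
  expect_equal(cv_criterion(feats, lab, 1, cfg, pid), 1.0)
  # determinism under the config seed
  expect_identical(cv_criterion(feats, lab, 2, cfg, pid),
                   cv_criterion(feats, lab, 2, cfg, pid))
})

test_that("the criterion is honest on pure noise and inflated when leaky", {
  set.seed(7)
  crit_h <- crit_l <- numeric(12)
  cfg <- cv_config(seed = 99)
  for (i in 1:12) {
    feats <- matrix(rnorm(60 * 28), 60, 28,
                    dimnames = list(sprintf("r%02d", 1:60), NULL))
    lab <- rep(c("case", "control"), 14)
    crit_h[i] <- cv_criterion(feats, lab, 2, cfg)
    crit_l[i] <- cv_criterion(feats, lab, 2, cfg, leaky = TRUE)
  }
  # honest variant sits near the analytic null level mean(0.2, 0.15, 0.1)
  expect_lt(abs(mean(crit_h) - 0.15), 0.08)
  # the leaky variant (ranking sees the held-out data) is clearly inflated
  expect_gt(mean(crit_l), mean(crit_h) + 0.1)
})

test_that("a two-gene panel yields the only possible ratio model", {
  set.seed(9)
  n <- 10
  ct <- rbind(A = c(rnorm(n, 20, 0.2), rnorm(n, 22, 0.2)),
              B = rnorm(2 * n, 25, 0.2))
  colnames(ct) <- sprintf("S%02d", 1:(2 * n))
  design <- as_sample_design(data.frame(
    sample_id = colnames(ct),
    group = rep(c("case", "control"), each = n),
    stringsAsFactors = FALSE))
  m <- ratio_lda(ct, design, cv_config(k_grid = 1:2, seed = 2))
  expect_identical(m$k, 1L)
  expect_true(m$normalizer %in% c("A", "B"))
  expect_length(m$ratios, 1)
  expect_identical(sort(strsplit(m$ratios, "/")[[1]]), c("A", "B"))
})

test_that("model selection is deterministic and prediction handles failures", {
  ps <- simulate_ct_panel(n_pairs_train = 8, n_per_group_test = 6,
                          n_genes = 12, seed = 14)
  cfg <- cv_config(k_grid = 1:4, seed = 3)
  m1 <- ratio_lda(ps$ct, ps$design, cfg)
  m2 <- ratio_lda(ps$ct, ps$design, cfg)
  expect_identical(m1$normalizer, m2$normalizer)
  expect_identical(m1$ratios, m2$ratios)
  expect_identical(m1$criterion, m2$criterion)
  expect_identical(m1$threshold, m2$threshold)

  te <- ps$design$sample_id[ps$design$set == "B_test"]
  ct_te <- ps$ct[, te]
  # a test sample missing the normalizer Ct is excluded, not scored
  ct_te[m1$normalizer, 1] <- NA
  pred <- predict(m1, ct_te)
  expect_true(pred$excluded[1])
  expect_true(is.na(pred$score[1]))
  expect_false(any(pred$excluded[-1]))

  # a sample at the training case centroid is called a case
  centroid <- colMeans(m1$train_features[m1$train_labels == "case", ,
                                         drop = FALSE])
  ct_c <- matrix(25, nrow(ps$ct), 1,
                 dimnames = list(rownames(ps$ct), "CENT"))
  num <- sub("/.*$", "", m1$ratios)
  ct_c[num, 1] <- 25 - centroid   # Ct_norm - Ct_gene = ratio
  pred_c <- predict(m1, ct_c)
  expect_identical(pred_c$class, "case")
})

test_that("training threshold attains the target specificity", {
  ps <- simulate_ct_panel(seed = 21)
  m <- ratio_lda(ps$ct, ps$design, cv_config(k_grid = 1:3, seed = 4))
  tr_ctrl <- m$train_scores[m$train_labels == "control"]
  expect_gte(mean(tr_ctrl < m$threshold), 0.85)
  # smallest such cut: the next lower candidate fails the target
  cand <- sort(unique(m$train_scores))
  lower <- cand[cand < m$threshold]
  if (length(lower))
    expect_lt(mean(tr_ctrl < max(lower)), 0.85)
})

test_that("QDA matches its closed-form 1-D boundary and SVM runs", {
  # two classes with different variances: boundary where the class
  # log-densities (plus log-priors) cross
  set.seed(10)
  x <- matrix(c(rnorm(50, 0, 1), rnorm(50, 3, 2)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c("control", "case"), each = 50)
  fit <- ctratio:::fit_qda(x, y)
  s1 <- sd(x[y == "case", ]); m1 <- mean(x[y == "case", ])
  s0 <- sd(x[y == "control", ]); m0 <- mean(x[y == "control", ])
  sc_fun <- function(v) dnorm(v, m1, s1, log = TRUE) -
    dnorm(v, m0, s0, log = TRUE)
  root <- uniroot(sc_fun, c(m0, m1))$root
  expect_equal(fit$score(matrix(root, 1, 1)), 0, tolerance = 1e-6,
               ignore_attr = TRUE)

  # comparator surface returns all three criteria
  feats <- rbind(hit = c(rnorm(14, 2, 0.5), rnorm(14, 0, 0.5)),
                 n1 = rnorm(28), n2 = rnorm(28))
  lab <- rep(c("case", "control"), each = 14)
  crit <- fit_comparators(feats, lab, 1, cv_config(n_repeats = 2, seed = 5))
  expect_named(crit, c("lda", "qda", "svm"))
  expect_true(all(crit >= 0 & crit <= 1))
  expect_gt(crit["lda"], 0.5)
})

test_that("models round-trip through versioned JSON", {
  ps <- simulate_ct_panel(n_pairs_train = 8, n_per_group_test = 5,
                          n_genes = 10, seed = 31)
  m <- ratio_lda(ps$ct, ps$design, cv_config(k_grid = 1:3, seed = 6))
  f <- tempfile(fileext = ".json")
  write_ratio_lda(m, f)
  m2 <- read_ratio_lda(f)
  te <- ps$design$sample_id[ps$design$set == "B_test"]
  expect_equal(predict(m, ps$ct[, te]), predict(m2, ps$ct[, te]))
  expect_identical(m2$normalizer, m$normalizer)
  expect_equal(m2$threshold, m$threshold)
})

test_that("print, summary, coef and plot methods work", {
  ps <- simulate_ct_panel(n_pairs_train = 8, n_per_group_test = 5,
                          n_genes = 10, seed = 41)
  m <- ratio_lda(ps$ct, ps$design, cv_config(k_grid = 1:3, seed = 7))
  expect_output(print(m), "normalizer gene")
  expect_output(print(summary(m)), "candidates")
  expect_named(coef(m), m$ratios)
  f <- tempfile(fileext = ".pdf")
  pdf(f); plot(m); dev.off()
  expect_true(file.exists(f))
})
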