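# Ratio-feature LDA classifier built by exhaustive normalizer-gene search
# with repeated cross-validation that nests the feature ranking, maximizing
# the average sensitivity at fixed specificities (80/85/90%).

#' Cross-validation configuration for the ratio classifier
#'
#' @param n_repeats repeats of the k-fold procedure (default 5).
#' @param n_folds folds (default 3).
#' @param specificity_cutoffs specificities at which sensitivity is read
#'   from the pooled out-of-fold ROC (default 0.80, 0.85, 0.90).
#' @param fc_min_ratio minimum fold change of a ratio between groups: ratios
#'   whose absolute mean group difference (log2 scale) is below
#'   \code{log2(fc_min_ratio)} are discarded before ranking (default 1.2).
#' @param k_grid candidate numbers of top-ranked ratios (default 1..10).
#' @param seed integer seed controlling fold assignment.
#' @return list of class \code{"cv_config"}.
#' @export
cv_config <- function(n_repeats = 5, n_folds = 3,
                      specificity_cutoffs = c(0.80, 0.85, 0.90),
                      fc_min_ratio = 1.2, k_grid = 1:10, seed = 1) {
  stopifnot(n_repeats >= 1, n_folds >= 2,
            all(specificity_cutoffs > 0 & specificity_cutoffs < 1),
            all(k_grid >= 1), fc_min_ratio >= 1)
  structure(list(n_repeats = n_repeats, n_folds = n_folds,
                 specificity_cutoffs = specificity_cutoffs,
                 fc_min_ratio = fc_min_ratio,
                 k_grid = as.integer(k_grid), seed = seed),
            class = "cv_config")
}

#' Log2 expression ratios against a normalizer gene
#'
#' The log2 ratio of gene i to the normalizer j is the difference of their
#' -Ct values, \code{r = (-Ct_i) - (-Ct_j) = Ct_j - Ct_i}. Any per-sample
#' additive Ct shift (loading effect) cancels exactly. Samples whose
#' normalizer Ct is missing are excluded and recorded in the
#' \code{"excluded_samples"} attribute.
#'
#' @param ct gene-by-sample Ct matrix (NA = missing).
#' @param normalizer gene id used as denominator.
#' @return (n_genes - 1) x n_samples matrix of ratios, rows named
#'   \code{"gene/normalizer"}.
#' @export
make_ratios <- function(ct, normalizer) {
  if (!normalizer %in% rownames(ct))
    stop("normalizer '", normalizer, "' missing from panel")
  norm_ct <- ct[normalizer, ]
  keep <- !is.na(norm_ct)
  others <- setdiff(rownames(ct), normalizer)
  r <- sweep(-ct[others, keep, drop = FALSE], 2L, -norm_ct[keep], "-")
  rownames(r) <- paste0(others, "/", normalizer)
  attr(r, "excluded_samples") <- colnames(ct)[!keep]
  attr(r, "normalizer") <- normalizer
  r
}

#' Rank ratio features by moderated-t p-value with a fold-change gate
#'
#' Each feature is tested with the two-group (unpaired) moderated t; features
#' whose absolute mean group difference is below \code{log2(fc_min_ratio)}
#' are discarded, and the rest sorted by ascending p-value.
#'
#' @param features feature-by-sample matrix (log2 scale; NA allowed).
#' @param labels per-sample \code{"case"}/\code{"control"}.
#' @param fc_min_ratio fold-change gate (default 1.2).
#' @return character vector of surviving feature ids in rank order, with the
#'   full statistics table as attribute \code{"stats"}.
#' @export
rank_ratios <- function(features, labels, fc_min_ratio = 1.2) {
  res <- twogroup_moderated_t(features, labels)
  gate <- log2(fc_min_ratio)
  keep <- !is.na(res$p) & abs(res$logFC) >= gate
  kept <- res[keep, , drop = FALSE]
  ord <- order(kept$p, kept$feature_id)
  structure(kept$feature_id[ord], stats = res)
}

# ---- two-class Gaussian discriminants -------------------------------------

#' Two-class linear discriminant analysis
#'
#' Pooled-covariance Gaussian discriminant with empirical priors. The score
#' of a sample is the linear discriminant value toward the case class,
#' \code{w'x - w'(mu_case + mu_control)/2 + log(pi_case/pi_control)} with
#' \code{w = Sigma^{-1}(mu_case - mu_control)}; positive scores favour
#' "case" and the score is monotone in the posterior case probability.
#'
#' @param x samples-by-features numeric matrix.
#' @param y per-sample labels \code{"case"}/\code{"control"}.
#' @return list of class \code{"lda_fit"}: \code{w}, \code{const},
#'   \code{means}, \code{sigma}, \code{priors}.
#' @export
fit_lda <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (!all(c("case", "control") %in% y)) stop("both classes must be present")
  if (anyNA(x)) stop("missing values in LDA features")
  if (nrow(x) <= ncol(x) + 2)
    stop("too few samples (", nrow(x), ") for ", ncol(x), " features")
  x1 <- x[y == "case", , drop = FALSE]
  x0 <- x[y == "control", , drop = FALSE]
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  S <- (crossprod(sweep(x1, 2L, mu1)) + crossprod(sweep(x0, 2L, mu0))) /
    (nrow(x) - 2)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < sqrt(.Machine$double.eps * max(diag(S), 1))) {
    cc <- suppressWarnings(stats::cor(x))
    diag(cc) <- 0
    idx <- which(abs(cc) > 1 - 1e-10, arr.ind = TRUE)
    pair <- if (nrow(idx)) paste(colnames(x)[idx[1, ]], collapse = " and ")
    else "unknown columns"
    stop("singular pooled covariance; collinear features: ", pair)
  }
  w <- backsolve(ch, backsolve(ch, mu1 - mu0, transpose = TRUE))
  priors <- c(case = mean(y == "case"), control = mean(y == "control"))
  const <- sum(w * (mu1 + mu0)) / 2 - log(priors["case"] / priors["control"])
  structure(list(w = w, const = unname(const),
                 means = rbind(case = mu1, control = mu0),
                 sigma = S, priors = priors, features = colnames(x)),
            class = "lda_fit")
}

#' @export
predict.lda_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$w) - object$const
}

#' @export
coef.lda_fit <- function(object, ...) object$w

fit_qda <- function(x, y) {
  x <- as.matrix(x); y <- as.character(y)
  x1 <- x[y == "case", , drop = FALSE]
  x0 <- x[y == "control", , drop = FALSE]
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  S1 <- stats::cov(x1); S0 <- stats::cov(x0)
  ch1 <- tryCatch(chol(S1), error = function(e) NULL)
  ch0 <- tryCatch(chol(S0), error = function(e) NULL)
  if (is.null(ch1) || is.null(ch0)) {
    warning("per-class covariance singular; QDA skipped")
    return(NULL)
  }
  priors <- c(case = mean(y == "case"), control = mean(y == "control"))
  logdet1 <- 2 * sum(log(diag(ch1)))
  logdet0 <- 2 * sum(log(diag(ch0)))
  score <- function(newx) {
    newx <- as.matrix(newx)
    d1 <- newx - matrix(mu1, nrow(newx), ncol(newx), byrow = TRUE)
    d0 <- newx - matrix(mu0, nrow(newx), ncol(newx), byrow = TRUE)
    q1 <- rowSums(backsolve(ch1, t(d1), transpose = TRUE)^2)
    q0 <- rowSums(backsolve(ch0, t(d0), transpose = TRUE)^2)
    -0.5 * (q1 - q0) - 0.5 * (logdet1 - logdet0) +
      log(priors["case"] / priors["control"])
  }
  list(score = score)
}

fit_svm <- function(x, y) {
  yf <- factor(as.character(y), levels = c("control", "case"))
  fit <- e1071::svm(as.matrix(x), yf, kernel = "radial", scale = TRUE)
  list(score = function(newx) {
    dv <- attr(stats::predict(fit, as.matrix(newx), decision.values = TRUE),
               "decision.values")
    v <- drop(dv[, 1L])
    # orient toward "case": positive decision values belong to the first
    # class named in the column label
    if (grepl("^control", colnames(dv)[1L])) v <- -v
    v
  })
}

classifier_fitter <- function(classifier) {
  switch(classifier,
         lda = function(x, y) {
           fit <- fit_lda(x, y)
           list(score = function(newx) predict(fit, newx))
         },
         qda = fit_qda,
         svm = fit_svm,
         stop("unknown classifier: ", classifier))
}

# ---- fold assignment -------------------------------------------------------

# Stratified fold assignment at the matched-pair level: a complete pair is a
# single unit (never straddles folds); unpaired samples are dealt round-robin
# within class. Returns integer fold id per sample (order of `labels`).
assign_folds <- function(labels, pair_id, n_folds) {
  n <- length(labels)
  fold <- integer(n)
  if (is.null(pair_id)) pair_id <- rep(NA_character_, n)
  paired_ids <- unique(stats::na.omit(pair_id))
  complete <- paired_ids[vapply(paired_ids, function(p) {
    sum(pair_id == p & labels == "case", na.rm = TRUE) == 1L &&
      sum(pair_id == p & labels == "control", na.rm = TRUE) == 1L
  }, logical(1))]
  if (length(complete)) {
    shuffled <- sample(complete)
    pf <- rep_len(seq_len(n_folds), length(shuffled))
    for (i in seq_along(shuffled))
      fold[!is.na(pair_id) & pair_id == shuffled[i]] <- pf[i]
  }
  loose <- which(fold == 0L)
  for (cl in c("case", "control")) {
    idx <- loose[labels[loose] == cl]
    if (length(idx))
      fold[sample(idx, length(idx))] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# ---- the cross-validated criterion ----------------------------------------

# Criterion for a grid of k values at once (the per-fold ranking is shared).
# Returns named numeric vector, one criterion per k.
cv_criterion_grid <- function(features, labels, k_grid, cfg,
                              pair_id = NULL, classifier = "lda",
                              leaky = FALSE) {
  labels <- as.character(labels)
  n <- length(labels)
  fitter <- classifier_fitter(classifier)
  ranked_all <- if (leaky)
    rank_ratios(features, labels, cfg$fc_min_ratio) else NULL
  crit <- matrix(NA_real_, cfg$n_repeats, length(k_grid))
  with_seed(cfg$seed, {
    for (r in seq_len(cfg$n_repeats)) {
      fold <- assign_folds(labels, pair_id, cfg$n_folds)
      scores <- matrix(NA_real_, n, length(k_grid))
      for (f in seq_len(cfg$n_folds)) {
        tr <- fold != f
        ranked <- if (leaky) ranked_all
        else rank_ratios(features[, tr, drop = FALSE], labels[tr],
                         cfg$fc_min_ratio)
        for (j in seq_along(k_grid)) {
          top <- utils::head(ranked, k_grid[j])
          if (length(top) == 0L) { scores[!tr, j] <- 0; next }
          xtr <- t(features[top, tr, drop = FALSE])
          xte <- t(features[top, !tr, drop = FALSE])
          cc <- stats::complete.cases(xtr)
          sc <- tryCatch({
            fit <- fitter(xtr[cc, , drop = FALSE], labels[tr][cc])
            if (is.null(fit)) rep(0, sum(!tr)) else {
              v <- rep(0, sum(!tr))
              ok <- stats::complete.cases(xte)
              if (any(ok)) v[ok] <- fit$score(xte[ok, , drop = FALSE])
              v
            }
          }, error = function(e) rep(0, sum(!tr)))
          scores[!tr, j] <- sc
        }
      }
      crit[r, ] <- vapply(seq_along(k_grid), function(j)
        mean(sensitivity_at_specificity(scores[, j], labels,
                                        cfg$specificity_cutoffs)),
        numeric(1))
    }
  })
  stats::setNames(colMeans(crit), paste0("k", k_grid))
}

#' Cross-validated sensitivity criterion
#'
#' Repeated stratified k-fold cross-validation in which the ratio ranking is
#' performed inside each training fold (no leakage), the top \code{k}
#' ratios feed the classifier, held-out samples are scored, out-of-fold
#' scores are pooled per repeat, and the sensitivity is read from the pooled
#' empirical ROC at each specificity cutoff (largest sensitivity among
#' operating points with specificity at or above the cutoff). The criterion
#' is the mean over cutoffs and repeats.
#'
#' @param features feature-by-sample matrix.
#' @param labels per-sample \code{"case"}/\code{"control"}.
#' @param k number of top-ranked features.
#' @param cfg a \code{\link{cv_config}}.
#' @param pair_id optional matched-pair ids (pairs never straddle folds).
#' @param classifier \code{"lda"} (default), \code{"qda"} or \code{"svm"}.
#' @param leaky if TRUE the ranking is done once on all data (train and
#'   held-out) — a deliberately biased variant kept for regression-testing
#'   the leakage guard; never use for real model selection.
#' @return the criterion (average sensitivity), a single number in [0, 1].
#' @export
cv_criterion <- function(features, labels, k, cfg = cv_config(),
                         pair_id = NULL, classifier = "lda", leaky = FALSE) {
  unname(cv_criterion_grid(features, labels, k, cfg, pair_id, classifier,
                           leaky))
}

#' Cross-validated criterion for QDA and SVM comparators
#'
#' Evaluates the same criterion as \code{\link{cv_criterion}} with a
#' quadratic discriminant (per-class covariances) and a radial-basis support
#' vector machine in place of the linear discriminant.
#'
#' @inheritParams cv_criterion
#' @return named numeric vector with elements \code{lda}, \code{qda},
#'   \code{svm}.
#' @export
fit_comparators <- function(features, labels, k, cfg = cv_config(),
                            pair_id = NULL) {
  vapply(c(lda = "lda", qda = "qda", svm = "svm"), function(cl)
    cv_criterion(features, labels, k, cfg, pair_id, classifier = cl),
    numeric(1))
}

# Smallest score cut achieving the target specificity on control scores.
choose_threshold <- function(scores, labels, target = 0.85) {
  ctrl <- scores[labels == "control"]
  cand <- sort(unique(c(scores, max(scores) + 1)))
  spec <- vapply(cand, function(th) mean(ctrl < th), numeric(1))
  cand[which(spec >= target)[1L]]
}

# ---- the fitted model ------------------------------------------------------

#' Fit a ratio-feature LDA classifier by normalizer search
#'
#' The central estimator: every panel gene is considered in turn as the
#' normalizer; log2 ratios of each remaining gene to the normalizer are
#' formed (differences of -Ct values, cancelling per-sample loading); the
#' number of top-ranked ratios k is optimized by the nested cross-validated
#' sensitivity criterion (\code{\link{cv_criterion}}); the normalizer and k
#' with the highest criterion are retained (ties broken by smaller k, then
#' lexicographic gene id); ranking and LDA fitting are then redone on all
#' training data, and the decision threshold is set to the smallest score
#' cut achieving the target specificity on the training controls.
#'
#' @param ct gene-by-sample Ct matrix (NA = missing). If \code{design} has a
#'   \code{set} column, only \code{"A_train"} samples are used.
#' @param design a \code{sample_design}.
#' @param cfg a \code{\link{cv_config}}.
#' @param threshold_specificity training specificity targeted by the
#'   decision threshold (default 0.85).
#' @return object of class \code{"ratio_lda"}: elements \code{normalizer},
#'   \code{ratios} (ordered), \code{k}, \code{lda} (an \code{lda_fit}),
#'   \code{threshold}, \code{criterion}, \code{search} (criterion per
#'   normalizer), \code{train_scores}, \code{cfg}.
#' @seealso \code{\link{predict.ratio_lda}}, \code{\link{fit_comparators}}
#' @export
ratio_lda <- function(ct, design, cfg = cv_config(),
                      threshold_specificity = 0.85) {
  design <- as_sample_design(as.data.frame(design))
  if (!is.null(design$set) && any(design$set == "A_train", na.rm = TRUE))
    design <- design[design$set == "A_train", , drop = FALSE]
  design <- design[design$sample_id %in% colnames(ct), , drop = FALSE]
  ct <- ct[, design$sample_id, drop = FALSE]
  if (nrow(ct) < 2) stop("need at least 2 genes")
  labels <- design$group
  pair_id <- design$pair_id
  genes <- rownames(ct)

  search <- data.frame(normalizer = genes, k = NA_integer_,
                       criterion = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    ratios <- make_ratios(ct, g)
    keep <- colnames(ct) %in% colnames(ratios)
    if (sum(labels[keep] == "case") < cfg$n_folds ||
        sum(labels[keep] == "control") < cfg$n_folds) next
    crit <- cv_criterion_grid(ratios, labels[keep], cfg$k_grid, cfg,
                              pair_id[keep])
    j <- which.max(crit)  # first maximum = smallest k on ties
    search$k[i] <- cfg$k_grid[j]
    search$criterion[i] <- crit[j]
  }
  if (all(is.na(search$criterion)))
    stop("no normalizer yields a usable model")
  ord <- order(-search$criterion, search$k, search$normalizer)
  best <- search[ord[1L], ]

  ratios <- make_ratios(ct, best$normalizer)
  keep <- colnames(ct) %in% colnames(ratios)
  ranked <- rank_ratios(ratios, labels[keep], cfg$fc_min_ratio)
  if (length(ranked) == 0L)
    stop("no ratio survives the fold-change gate on the full training data")
  top <- utils::head(ranked, best$k)
  x <- t(ratios[top, , drop = FALSE])
  cc <- stats::complete.cases(x)
  fit <- fit_lda(x[cc, , drop = FALSE], labels[keep][cc])
  xcc <- x[cc, , drop = FALSE]
  rownames(xcc) <- colnames(ratios)[cc]
  train_scores <- predict(fit, xcc)
  theta <- choose_threshold(train_scores, labels[keep][cc],
                            threshold_specificity)
  structure(list(normalizer = best$normalizer,
                 ratios = top,
                 k = length(top),
                 lda = fit,
                 threshold = theta,
                 threshold_specificity = threshold_specificity,
                 criterion = best$criterion,
                 search = search,
                 train_features = xcc,
                 train_scores = stats::setNames(train_scores, rownames(xcc)),
                 train_labels = stats::setNames(labels[keep][cc],
                                                rownames(xcc)),
                 cfg = cfg,
                 call = match.call()),
            class = "ratio_lda")
}

#' Predict outcome scores for new samples
#'
#' A sample missing the Ct of any model gene (the normalizer or a selected
#' numerator) is excluded and flagged, mirroring the discard of samples with
#' PCR failures; others receive the LDA score and the class called by
#' \code{score >= threshold}.
#'
#' @param object a \code{ratio_lda} model.
#' @param ct gene-by-sample Ct matrix for the new samples.
#' @param ... unused.
#' @return data.frame with columns \code{sample_id}, \code{score},
#'   \code{class} (\code{"case"}/\code{"control"}), \code{excluded}.
#' @export
predict.ratio_lda <- function(object, ct, ...) {
  need_num <- sub("/.*$", "", object$ratios)
  need <- unique(c(object$normalizer, need_num))
  missing_genes <- setdiff(need, rownames(ct))
  if (length(missing_genes))
    stop("model gene(s) absent from panel: ",
         paste(missing_genes, collapse = ", "))
  r <- sweep(-ct[need_num, , drop = FALSE], 2L, -ct[object$normalizer, ], "-")
  rownames(r) <- paste0(need_num, "/", object$normalizer)
  x <- t(r[object$ratios, , drop = FALSE])
  ok <- stats::complete.cases(x)
  score <- rep(NA_real_, ncol(ct))
  score[ok] <- predict(object$lda, x[ok, , drop = FALSE])
  data.frame(sample_id = colnames(ct),
             score = score,
             class = ifelse(ok,
                            ifelse(score >= object$threshold,
                                   "case", "control"),
                            NA_character_),
             excluded = !ok,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.ratio_lda <- function(x, ...) {
  cat("Ratio-feature LDA classifier\n")
  cat(sprintf("  normalizer gene: %s\n", x$normalizer))
  cat(sprintf("  ratios (k = %d): %s\n", x$k, paste(x$ratios, collapse = ", ")))
  cat(sprintf("  CV criterion (avg sensitivity at %s%% specificity): %.3f\n",
              paste(round(100 * x$cfg$specificity_cutoffs), collapse = "/"),
              x$criterion))
  cat(sprintf("  decision threshold: %.4f (training specificity >= %.0f%%)\n",
              x$threshold, 100 * x$threshold_specificity))
  invisible(x)
}

#' @export
summary.ratio_lda <- function(object, ...) {
  sr <- object$search[order(-object$search$criterion), ]
  structure(list(model = object, top_normalizers = utils::head(sr, 5L)),
            class = "summary.ratio_lda")
}

#' @export
print.summary.ratio_lda <- function(x, ...) {
  print(x$model)
  cat("  LDA coefficients:\n")
  print(round(stats::setNames(x$model$lda$w, x$model$ratios), 4))
  cat("  best normalizer candidates:\n")
  print(x$top_normalizers, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ratio_lda <- function(object, ...) {
  stats::setNames(object$lda$w, object$ratios)
}

#' Plot the fitted ratio classifier
#'
#' For models with at least two ratios, draws the training samples in the
#' plane of the first two ratio features with the decision boundary implied
#' by the LDA weights and threshold (remaining features fixed at their
#' training means); one-ratio models get a strip chart with the threshold.
#'
#' @param x a \code{ratio_lda} model.
#' @param ct optional Ct matrix of extra samples to overlay (open symbols).
#' @param ... passed to \code{plot}.
#' @export
plot.ratio_lda <- function(x, ct = NULL, ...) {
  need_num <- sub("/.*$", "", x$ratios)
  tr_lab <- x$train_labels
  cols <- ifelse(tr_lab == "case", "firebrick", "steelblue")
  feat <- function(ctm) {
    r <- sweep(-ctm[need_num, , drop = FALSE], 2L, -ctm[x$normalizer, ], "-")
    rownames(r) <- x$ratios
    t(r)
  }
  if (x$k >= 2) {
    tf <- x$train_features
    extra <- if (!is.null(ct)) feat(ct)[, x$ratios, drop = FALSE] else NULL
    xs <- c(tf[, 1], extra[, 1]); ys <- c(tf[, 2], extra[, 2])
    graphics::plot(tf[, 1], tf[, 2], col = cols, pch = 19,
                   xlim = range(xs, na.rm = TRUE),
                   ylim = range(ys, na.rm = TRUE),
                   xlab = x$ratios[1], ylab = x$ratios[2], ...)
    w <- x$lda$w
    rest <- if (x$k > 2)
      sum(w[-(1:2)] * colMeans(tf)[-(1:2)]) else 0
    # boundary: w1*r1 + w2*r2 + rest - const = threshold
    if (abs(w[2]) > 1e-12)
      graphics::abline(a = (x$threshold + x$lda$const - rest) / w[2],
                       b = -w[1] / w[2])
    if (!is.null(extra)) graphics::points(extra[, 1], extra[, 2], pch = 1)
  } else {
    graphics::stripchart(x$train_scores ~ factor(tr_lab), vertical = TRUE,
                         method = "jitter", pch = 19, col = c("firebrick",
                                                              "steelblue"),
                         ylab = "LDA score", ...)
    graphics::abline(h = x$threshold, lty = 2)
  }
  invisible(x)
}

#' Write / read a ratio classifier as versioned JSON
#'
#' @param model a \code{ratio_lda}.
#' @param path file path.
#' @return \code{read_ratio_lda} returns the restored model (sufficient for
#'   prediction; the search record is preserved, training scores included).
#' @export
write_ratio_lda <- function(model, path) {
  payload <- list(
    format = "ratio_lda", version = 1L,
    normalizer = model$normalizer, ratios = model$ratios, k = model$k,
    threshold = model$threshold,
    threshold_specificity = model$threshold_specificity,
    criterion = model$criterion,
    lda = list(w = unname(model$lda$w), const = model$lda$const,
               means = model$lda$means, sigma = model$lda$sigma,
               priors = model$lda$priors, features = model$lda$features),
    train_scores = as.list(model$train_scores),
    train_labels = as.list(model$train_labels),
    cfg = unclass(model$cfg)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ratio_lda
#' @export
read_ratio_lda <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ratio_lda"))
    stop("not a ratio_lda model file")
  lda <- structure(list(w = p$lda$w, const = p$lda$const,
                        means = as.matrix(p$lda$means),
                        sigma = as.matrix(p$lda$sigma),
                        priors = unlist(p$lda$priors),
                        features = p$lda$features),
                   class = "lda_fit")
  structure(list(normalizer = p$normalizer, ratios = p$ratios, k = p$k,
                 lda = lda, threshold = p$threshold,
                 threshold_specificity = p$threshold_specificity,
                 criterion = p$criterion,
                 train_scores = unlist(p$train_scores),
                 train_labels = unlist(p$train_labels),
                 cfg = do.call(cv_config, p$cfg)),
            class = "ratio_lda")
}
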