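# ROC/AUC utilities, a stratified-bootstrap AUC-difference test, the
# clinical-covariate comparator, confusion metrics and gestational-age
# subgroup analysis.

auc_rank <- function(scores, labels) {
  ic <- labels == "case"
  n1 <- sum(ic); n0 <- sum(!ic)
  r <- rank(scores)
  (sum(r[ic]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve and AUC
#'
#' The AUC is the Mann-Whitney estimator: the fraction of (case, control)
#' score pairs correctly ordered, ties counted one half. The curve lists
#' every empirical operating point (classify case when score >= threshold).
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels per-sample \code{"case"}/\code{"control"}.
#' @return list of class \code{"roc_result"}: \code{thresholds},
#'   \code{sensitivities}, \code{specificities}, \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  if (!all(c("case", "control") %in% labels))
    stop("both classes must be present")
  ic <- labels == "case"
  th <- c(sort(unique(scores)), max(scores) + 1)
  sens <- vapply(th, function(t) mean(scores[ic] >= t), numeric(1))
  spec <- vapply(th, function(t) mean(scores[!ic] < t), numeric(1))
  structure(list(thresholds = th, sensitivities = sens,
                 specificities = spec, auc = auc_rank(scores, labels)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f over %d operating points\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Sensitivity at fixed specificity cutoffs
#'
#' For each cutoff, the largest sensitivity among empirical operating
#' points whose specificity is at or above the cutoff (step-function
#' convention, no interpolation).
#'
#' @param scores,labels as \code{\link{roc_auc}}.
#' @param cutoffs specificity cutoffs in (0, 1).
#' @return numeric vector, one sensitivity per cutoff.
#' @export
sensitivity_at_specificity <- function(scores, labels,
                                       cutoffs = c(0.80, 0.85, 0.90)) {
  roc <- roc_auc(scores, labels)
  vapply(cutoffs, function(cut) {
    ok <- roc$specificities >= cut
    if (!any(ok)) 0 else max(roc$sensitivities[ok])
  }, numeric(1))
}

#' Stratified bootstrap test comparing two AUCs
#'
#' Both score vectors must come from the same samples (paired comparison).
#' Cases and controls are resampled separately with replacement
#' \code{n_boot} times; the test statistic is
#' \code{D = (auc_1 - auc_2) / sd_boot(auc_1* - auc_2*)} with a two-sided
#' normal reference. Identical models (zero bootstrap sd) give D = 0, p = 1.
#'
#' @param scores_a,scores_b paired score vectors for the two models.
#' @param labels per-sample \code{"case"}/\code{"control"}.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @return list of class \code{"auc_comparison"}: \code{auc_1},
#'   \code{auc_2}, \code{D}, \code{p}, \code{n_boot}, \code{seed}.
#' @export
bootstrap_auc_test <- function(scores_a, scores_b, labels, n_boot = 2000,
                               seed = 1) {
  labels <- as.character(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length")
  auc1 <- auc_rank(scores_a, labels)
  auc2 <- auc_rank(scores_b, labels)
  idx_case <- which(labels == "case")
  idx_ctrl <- which(labels == "control")
  diffs <- numeric(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- c(sample(idx_case, replace = TRUE),
               sample(idx_ctrl, replace = TRUE))
      lab <- labels[idx]
      diffs[b] <- auc_rank(scores_a[idx], lab) - auc_rank(scores_b[idx], lab)
    }
  })
  sdb <- stats::sd(diffs)
  if (!is.finite(sdb) || sdb == 0) {
    D <- 0; p <- 1
  } else {
    D <- (auc1 - auc2) / sdb
    p <- 2 * stats::pnorm(-abs(D))
  }
  structure(list(auc_1 = auc1, auc_2 = auc2, D = D, p = p,
                 n_boot = n_boot, seed = seed),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC %.3f vs %.3f: D = %.3f, two-sided p = %.4g (%d stratified bootstraps)\n",
              x$auc_1, x$auc_2, x$D, x$p, x$n_boot))
  invisible(x)
}

# Encode the birth-time clinical covariates as a numeric model matrix.
encode_covariates <- function(design, drop_constant = TRUE) {
  covs <- c("gestational_age_weeks", "sex", "sga", "apgar5", "labor",
            "chorioamnionitis")
  present <- intersect(covs, names(design))
  if (!length(present)) stop("no clinical covariates in design")
  cols <- lapply(present, function(v) {
    x <- design[[v]]
    if (is.numeric(x)) as.numeric(x)
    else if (is.logical(x)) as.numeric(x)
    else as.numeric(factor(x)) - 1  # binary/categorical indicator coding
  })
  m <- do.call(cbind, cols)
  colnames(m) <- present
  rownames(m) <- design$sample_id
  constant <- drop_constant & apply(m, 2L, function(x) stats::var(x) == 0)
  if (any(constant)) {
    warning("constant covariate(s) dropped: ",
            paste(colnames(m)[constant], collapse = ", "))
    m <- m[, !constant, drop = FALSE]
  }
  if (!ncol(m)) stop("all covariates constant")
  m
}

#' Clinical-covariate comparator model
#'
#' LDA on the encoded birth-time covariates (gestational age, sex,
#' small-for-gestational-age status, 5-minute Apgar score, labor,
#' chorioamnionitis), producing sample scores under the same contract as
#' the gene-ratio model so the two can be compared on one ROC test.
#'
#' @param design a \code{sample_design} holding the training samples'
#'   covariates.
#' @param labels optional labels (defaults to \code{design$group}).
#' @param newdesign design rows to score (defaults to the training design).
#' @return list: \code{scores} (named, for \code{newdesign}), \code{fit}
#'   (the \code{lda_fit}), \code{covariates} used.
#' @export
clinical_model <- function(design, labels = design$group,
                           newdesign = design) {
  x <- encode_covariates(design)
  fit <- fit_lda(x, labels)
  xnew <- encode_covariates(newdesign, drop_constant = FALSE)[, colnames(x),
                                                              drop = FALSE]
  list(scores = stats::setNames(predict(fit, xnew), newdesign$sample_id),
       fit = fit, covariates = colnames(x))
}

#' Confusion metrics from called classes
#'
#' @param predicted per-sample \code{"case"}/\code{"control"} calls
#'   (excluded samples must already be removed).
#' @param labels true labels.
#' @return list of class \code{"confusion"}: counts \code{tp}, \code{fn},
#'   \code{tn}, \code{fp}; \code{sensitivity} and \code{specificity} as
#'   proportions, and \code{sensitivity_pct} / \code{specificity_pct}
#'   rounded half away from zero to integer percent.
#' @export
confusion <- function(predicted, labels) {
  predicted <- as.character(predicted); labels <- as.character(labels)
  tp <- sum(predicted == "case" & labels == "case")
  fn <- sum(predicted == "control" & labels == "case")
  tn <- sum(predicted == "control" & labels == "control")
  fp <- sum(predicted == "case" & labels == "control")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec,
                 sensitivity_pct = round_half_up(100 * sens),
                 specificity_pct = round_half_up(100 * spec)),
            class = "confusion")
}

# round half away from zero (printed-percentage convention)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("sensitivity %d/%d = %d%%, specificity %d/%d = %d%%\n",
              x$tp, x$tp + x$fn, x$sensitivity_pct,
              x$tn, x$tn + x$fp, x$specificity_pct))
  invisible(x)
}

#' Gestational-age subgroup AUCs
#'
#' Splits samples at a gestational-age cutoff (default the median, yielding
#' strata whose sizes differ by at most one) and reports the AUC within
#' each stratum. A stratum lacking one class gets an \code{NA} AUC and a
#' flag.
#'
#' @param scores,labels as \code{\link{roc_auc}}.
#' @param ga_weeks gestational age at delivery (weeks) per sample.
#' @param cutoff split point; default \code{median(ga_weeks)}.
#' @return data.frame with one row per stratum: \code{stratum}, \code{n},
#'   \code{auc}, \code{defined}.
#' @export
subgroup_auc <- function(scores, labels, ga_weeks, cutoff = NULL) {
  if (anyNA(ga_weeks)) stop("gestational age missing for scored sample(s)")
  if (is.null(cutoff)) cutoff <- stats::median(ga_weeks)
  strata <- ifelse(ga_weeks < cutoff, "below_cutoff", "at_or_above_cutoff")
  out <- lapply(c("below_cutoff", "at_or_above_cutoff"), function(s) {
    i <- strata == s
    defined <- all(c("case", "control") %in% labels[i])
    data.frame(stratum = s, n = sum(i),
               auc = if (defined) auc_rank(scores[i], labels[i]) else NA_real_,
               defined = defined, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "cutoff") <- cutoff
  res
}

#' Augment a feature matrix with gestational age
#'
#' Adds gestational age as a main effect, or as interactions with each
#' existing feature, for refitting the classifier with GA information.
#'
#' @param features samples-by-features matrix.
#' @param ga_weeks gestational age per sample.
#' @param mode \code{"main"} or \code{"interaction"}.
#' @return augmented samples-by-features matrix.
#' @export
augment_with_ga <- function(features, ga_weeks,
                            mode = c("main", "interaction")) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  if (mode == "main") {
    cbind(features, ga = ga_weeks)
  } else {
    inter <- features * ga_weeks
    colnames(inter) <- paste0(colnames(features), ":ga")
    cbind(features, inter)
  }
}
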