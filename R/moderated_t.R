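# Empirical-Bayes moderated t statistics. The per-feature sample variance
# s2_g (df d_g) is shrunk toward a prior variance s0sq with prior degrees of
# freedom d0, both estimated by the closed-form method of moments on
# log(s2_g) via digamma/trigamma matching. The moderated statistic uses the
# posterior variance s_tilde2 = (d0*s0sq + d*s2)/(d0 + d) and a t reference
# with d0 + d degrees of freedom.

# Newton solve of trigamma(x) = y (y > 0), vectorized.
trigamma_inverse <- function(y) {
  out <- y
  ok <- is.finite(y) & y > 0
  out[!ok] <- NA_real_
  big <- ok & y > 1e7
  out[big] <- 1 / sqrt(y[big])
  small <- ok & y < 1e-6
  out[small] <- 1 / y[small]
  mid <- ok & !big & !small
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(-dif / x) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

#' Estimate the prior variance and degrees of freedom for moderation
#'
#' Method-of-moments fit on \code{e_g = log(s2_g) - digamma(d_g/2) +
#' log(d_g/2)}: the prior df solves \code{trigamma(d0/2) = var(e) -
#' mean(trigamma(d_g/2))}; if that equation has no positive solution the
#' prior is degenerate (\code{d0 = Inf}, full shrinkage). Features with zero
#' or non-finite variance are excluded from the fit.
#'
#' @param s2 per-feature sample variances.
#' @param df residual degrees of freedom (scalar or per-feature).
#' @return list with \code{d0} and \code{s0sq}.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(ok))
    stop("all features have zero or undefined variance; moment fit undefined")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0sq <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0sq = s0sq)
}

moderated_t_core <- function(mean_diff, s2, df, stderr_scale,
                             d0 = NULL, s0sq = NULL) {
  if (is.null(d0) || (is.null(s0sq) && !is.finite(d0)) ) {
    prior <- fit_variance_prior(s2, df)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0sq)) s0sq <- prior$s0sq
  } else if (is.null(s0sq)) {
    s0sq <- fit_variance_prior(s2, df)$s0sq
  }
  s_tilde2 <- if (is.finite(d0))
    (d0 * s0sq + df * s2) / (d0 + df)
  else rep_len(s0sq, length(s2))
  t_mod <- mean_diff / sqrt(s_tilde2 * stderr_scale)
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  list(t = t_mod, p = p, s_tilde2 = s_tilde2, d0 = d0, s0sq = s0sq,
       df_total = df_total)
}

mt_result <- function(feature_id, logFC, s2, d, core) {
  data.frame(
    feature_id = feature_id,
    logFC = logFC,
    FC = sign(logFC) * 2^abs(logFC) + (logFC == 0) * 1,
    s2 = s2,
    d = d,
    d0 = core$d0,
    s0sq = core$s0sq,
    s_tilde2 = core$s_tilde2,
    t_mod = core$t,
    p = core$p,
    direction = ifelse(logFC >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Paired moderated t-test
#'
#' One-sample moderated t on within-pair log2 differences (case minus
#' control), algebraically identical to a blocked linear model for complete
#' pairs. Per feature: \code{logFC = mean(differences)}, \code{s2 =
#' var(differences)} with \code{d = n_pairs - 1} df, shrunk toward the
#' moment-fit prior; \code{t_mod = logFC / sqrt(s_tilde2 / n_pairs)} with
#' two-sided p from t on \code{d0 + d} df. The signed fold change is
#' \code{sign(logFC) * 2^|logFC|} (negative = lower expression in cases).
#'
#' @param m a log2-normalized \code{expr_matrix} (or plain numeric matrix of
#'   log2 values with sample colnames).
#' @param design a \code{sample_design} with complete pairs (>= 2).
#' @param d0,s0sq optional overrides of the prior; \code{d0 = 0} yields the
#'   ordinary paired t, \code{d0 = Inf} the fully shrunk statistic.
#' @return data.frame (one row per feature) with columns \code{feature_id},
#'   \code{logFC}, \code{FC}, \code{s2}, \code{d}, \code{d0}, \code{s0sq},
#'   \code{s_tilde2}, \code{t_mod}, \code{p}, \code{direction}.
#' @export
paired_moderated_t <- function(m, design, d0 = NULL, s0sq = NULL) {
  if (inherits(m, "expr_matrix") && expr_state(m) != "log2_normalized")
    stop("expression matrix must be log2_normalized; run preprocess() first")
  pairs <- design_pairs(design, samples = colnames(m))
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 complete pairs")
  D <- unclass(m)[, pairs$case, drop = FALSE] -
    unclass(m)[, pairs$control, drop = FALSE]
  logFC <- rowMeans(D)
  s2 <- rowSums((D - logFC)^2) / (n - 1)
  if (all(s2 == 0))
    stop("zero variance across all features; moment fit undefined")
  core <- moderated_t_core(logFC, s2, df = n - 1, stderr_scale = 1 / n,
                           d0 = d0, s0sq = s0sq)
  mt_result(rownames(m), logFC, s2, n - 1, core)
}

#' Two-group (unpaired) moderated t-test
#'
#' Moderated t with pooled within-group variance, used to rank candidate
#' ratio features in the prediction context where single samples must be
#' scorable. Missing cells are dropped per feature; features with fewer
#' than two usable samples in either group get \code{NA} statistics.
#'
#' @param x feature-by-sample numeric matrix (NA allowed).
#' @param labels per-sample \code{"case"}/\code{"control"} labels.
#' @param d0,s0sq optional prior overrides as in
#'   \code{\link{paired_moderated_t}}.
#' @return data.frame as \code{\link{paired_moderated_t}}, where
#'   \code{logFC} is mean(case) - mean(control).
#' @export
twogroup_moderated_t <- function(x, labels, d0 = NULL, s0sq = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (!all(c("case", "control") %in% labels))
    stop("both classes must be present")
  ic <- labels == "case"
  n1 <- rowSums(!is.na(x[, ic, drop = FALSE]))
  n0 <- rowSums(!is.na(x[, !ic, drop = FALSE]))
  m1 <- rowMeans(x[, ic, drop = FALSE], na.rm = TRUE)
  m0 <- rowMeans(x[, !ic, drop = FALSE], na.rm = TRUE)
  ss1 <- rowSums((x[, ic, drop = FALSE] - m1)^2, na.rm = TRUE)
  ss0 <- rowSums((x[, !ic, drop = FALSE] - m0)^2, na.rm = TRUE)
  df <- n1 + n0 - 2
  usable <- n1 >= 2 & n0 >= 2
  s2 <- ifelse(usable, (ss1 + ss0) / pmax(df, 1), NA_real_)
  diff <- ifelse(usable, m1 - m0, NA_real_)
  scale <- 1 / n1 + 1 / n0
  core <- moderated_t_core(diff[usable], s2[usable], df[usable],
                           scale[usable], d0 = d0, s0sq = s0sq)
  t_all <- p_all <- st_all <- rep(NA_real_, nrow(x))
  t_all[usable] <- core$t
  p_all[usable] <- core$p
  st_all[usable] <- core$s_tilde2
  out <- data.frame(
    feature_id = rownames(x),
    logFC = diff,
    FC = sign(diff) * 2^abs(diff) + (!is.na(diff) & diff == 0) * 1,
    s2 = s2, d = df, d0 = core$d0, s0sq = core$s0sq, s_tilde2 = st_all,
    t_mod = t_all, p = p_all,
    direction = ifelse(diff >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Select differentially expressed features
#'
#' Strict thresholds: nominal \code{p < p_max} and absolute fold change
#' \code{|FC| > fc_min}. Probes are not collapsed to genes before testing;
#' the unique-gene count is taken over the annotation map, with unannotated
#' probes counted under their own probe id.
#'
#' @param results a moderated-t result data.frame.
#' @param p_max nominal p-value threshold (default 0.05).
#' @param fc_min fold-change magnitude threshold (default 1.5).
#' @param probe_to_gene optional named character map probe -> gene symbol.
#' @return list (class \code{"de_selection"}) with \code{selected} (feature
#'   ids), \code{n_probes_selected}, \code{n_unique_genes}, and the
#'   thresholds.
#' @export
select_de <- function(results, p_max = 0.05, fc_min = 1.5,
                      probe_to_gene = NULL) {
  if (nrow(results) == 0) stop("empty results")
  pass <- !is.na(results$p) & results$p < p_max & abs(results$FC) > fc_min
  sel <- results$feature_id[pass]
  genes <- if (is.null(probe_to_gene)) sel else {
    g <- probe_to_gene[sel]
    ifelse(is.na(g) | !nzchar(g), sel, g)
  }
  structure(list(selected = sel,
                 n_probes_selected = length(sel),
                 n_unique_genes = length(unique(genes)),
                 p_max = p_max, fc_min = fc_min),
            class = "de_selection")
}

#' @export
print.de_selection <- function(x, ...) {
  cat(sprintf("%d probes selected (p < %g and |FC| > %g), %d unique genes\n",
              x$n_probes_selected, x$p_max, x$fc_min, x$n_unique_genes))
  invisible(x)
}
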