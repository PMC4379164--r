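# Gene-set scoring with down-weighting of genes shared between sets, and
# hypergeometric term enrichment.

#' Per-gene down-weighting of genes shared between sets
#'
#' For each gene appearing in at least one set, let \code{f(g)} be the
#' number of sets containing it. The weight is
#' \code{w(g) = 1 + sqrt((max f - f(g)) / (max f - min f))}, so genes unique
#' to few sets (set-specific evidence) get weight up to 2 while promiscuous
#' genes get weight 1. If all genes have equal frequency, all weights are 1.
#'
#' @param collection a \code{geneset_collection}.
#' @return list (class \code{"gene_weighting"}) with named numeric vectors
#'   \code{f} and \code{w}.
#' @export
compute_weights <- function(collection) {
  if (length(collection) == 0) stop("empty collection")
  f <- table(unlist(unname(collection)))
  f <- stats::setNames(as.numeric(f), names(f))
  if (max(f) == min(f)) {
    w <- stats::setNames(rep(1, length(f)), names(f))
  } else {
    w <- 1 + sqrt((max(f) - f) / (max(f) - min(f)))
  }
  structure(list(f = f, w = w), class = "gene_weighting")
}

#' Gene-set scores with overlap down-weighting and sign-flip permutations
#'
#' The observed score of a set is the weighted mean of absolute moderated-t
#' statistics over its member genes present on the platform,
#' \code{S = sum(w_g |t_g|) / sum(w_g)}, with weights from
#' \code{\link{compute_weights}}. Significance comes from a paired-design
#' permutation null: the signs of the within-pair differences are flipped
#' at random \code{n_perm} times, the moderated t (including its variance
#' prior) and all set scores are recomputed each time, and
#' \code{p_perm = (1 + #[S_perm >= S_obs]) / (1 + n_perm)}. q-values are
#' Benjamini-Hochberg across sets. Sets with no platform genes are dropped
#' with a warning.
#'
#' @param m a log2-normalized \code{expr_matrix} whose rownames are gene ids
#'   matching the collection.
#' @param design a \code{sample_design} with complete pairs.
#' @param collection a \code{geneset_collection}.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param seed integer seed.
#' @param weighted if \code{FALSE}, all gene weights are set to 1 (plain
#'   mean of |t|), for comparing against the down-weighted scoring.
#' @return data.frame with columns \code{set}, \code{n_genes_used},
#'   \code{S_obs}, \code{p_perm}, \code{q}.
#' @export
pathway_scores <- function(m, design, collection, n_perm = 500, seed = 1,
                           weighted = TRUE) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  pairs <- design_pairs(design, samples = colnames(m))
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 complete pairs")
  D <- unclass(m)[, pairs$case, drop = FALSE] -
    unclass(m)[, pairs$control, drop = FALSE]
  platform <- rownames(m)
  members <- lapply(collection, function(g) intersect(g, platform))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("set(s) with no platform genes excluded: ",
            paste(names(collection)[empty], collapse = ", "))
    members <- members[!empty]
  }
  if (length(members) == 0) stop("no set has platform genes")
  wts <- compute_weights(collection)$w
  if (!weighted) wts[] <- 1
  midx <- lapply(members, function(g) match(g, platform))
  mw <- lapply(members, function(g) wts[g])

  row_ss <- rowSums(D^2)
  score_from_signs <- function(s) {
    mu <- as.vector(D %*% s) / n
    s2 <- (row_ss - n * mu^2) / (n - 1)
    s2 <- pmax(s2, 0)
    core <- moderated_t_core(mu, s2, df = n - 1, stderr_scale = 1 / n)
    at <- abs(core$t)
    vapply(seq_along(midx), function(i)
      sum(mw[[i]] * at[midx[[i]]]) / sum(mw[[i]]), numeric(1))
  }
  S_obs <- score_from_signs(rep(1, n))
  exceed <- numeric(length(midx))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      exceed <- exceed + (score_from_signs(s) >= S_obs)
    }
  })
  p_perm <- (1 + exceed) / (1 + n_perm)
  data.frame(set = names(members),
             n_genes_used = lengths(members),
             S_obs = S_obs,
             p_perm = p_perm,
             q = stats::p.adjust(p_perm, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric term enrichment with odds ratios
#'
#' For each term: \code{k} = differentially expressed (DE) genes in the
#' term, \code{m} = term size within the universe, \code{K} = total DE
#' genes, \code{N} = universe size. The upper-tail hypergeometric p-value is
#' \code{P(X >= k)}; the (unconditional) odds ratio is
#' \code{k (N - K - m + k) / ((m - k)(K - k))}, reported as \code{Inf} on a
#' zero cell. FDR adjustment is Benjamini-Hochberg across tested terms.
#'
#' @param de_genes character vector of DE gene ids (subset of universe).
#' @param universe character vector, the gene universe.
#' @param collection a \code{geneset_collection} of terms.
#' @return data.frame with columns \code{term}, \code{k}, \code{m},
#'   \code{K}, \code{N}, \code{p_hyper}, \code{odds_ratio}, \code{p_fdr}.
#' @export
enrich_hypergeometric <- function(de_genes, universe, collection) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  de_genes <- unique(as.character(de_genes))
  if (!all(de_genes %in% universe))
    stop("de_genes must be a subset of the universe")
  N <- length(universe)
  K <- length(de_genes)
  rows <- lapply(names(collection), function(term) {
    memb <- intersect(collection[[term]], universe)
    m <- length(memb)
    k <- length(intersect(memb, de_genes))
    p <- stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    or <- if ((m - k) == 0 || (K - k) == 0) {
      if (k == 0) NaN else Inf
    } else k * (N - K - m + k) / ((m - k) * (K - k))
    data.frame(term = term, k = k, m = m, K = K, N = N,
               p_hyper = p, odds_ratio = or,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p_hyper, method = "BH")
  out
}
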