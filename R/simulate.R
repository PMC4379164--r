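# Synthetic-data generators emulating the matched-pair study design:
# gestational-age-matched case-control pairs on the array, a ~90-gene Ct
# panel with a shared per-sample loading effect, and gene-set collections
# with controlled overlap. Defaults mirror the study conditions (14 training
# pairs, 19+19 blinded test samples, 90-gene panel, 1-cycle plants).

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-stage seed derived from a global seed; kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- c(expression = 101L, ct = 211L, genesets = 307L, cv = 401L,
            boot = 503L, pathways = 601L, confirm = 701L)
  off <- offs[[stage]]
  as.integer((as.numeric(seed) * 1103L + off) %% 2147483647)
}

default_effect_sampler <- function(n) {
  # |log2 FC| between log2(1.5) and log2(3), random sign
  sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, log2(1.5), log2(3))
}

#' Simulate a paired case-control expression experiment
#'
#' Raw intensities follow \code{x = 2^(mu_g + pi_p + beta_g I(case) + eps) - 1}
#' with probe baselines \code{mu_g}, a shared matched-pair effect
#' \code{pi_p ~ N(0, pair_sd)}, planted log2 effects \code{beta_g} on
#' \code{n_de} probes (zero elsewhere) and Gaussian noise
#' \code{eps ~ N(0, noise_sd)} on the log2 scale.
#'
#' @param n_pairs number of matched case-control pairs (> 0).
#' @param n_probes number of probes.
#' @param n_de number of differentially expressed probes (<= n_probes).
#' @param effect_log2 function(n) returning n signed log2 effects; default
#'   draws |log2 FC| uniformly in [log2 1.5, log2 3] with random sign.
#' @param pair_sd,noise_sd standard deviations (log2 scale) of the pair
#'   effect and residual noise; non-negative.
#' @param seed integer seed.
#' @return list with \code{expr} (raw \code{expr_matrix}), \code{design}
#'   (a \code{sample_design}) and \code{truth} (planted effects and seed).
#' @export
simulate_expression <- function(n_pairs, n_probes, n_de = 0,
                                effect_log2 = default_effect_sampler,
                                pair_sd = 0.5, noise_sd = 0.5, seed = 1) {
  if (n_pairs <= 0) stop("n_pairs must be positive")
  if (n_de > n_probes) stop("n_de must not exceed n_probes")
  if (pair_sd < 0 || noise_sd < 0) stop("sds must be non-negative")
  with_seed(seed, {
    probes <- sprintf("P%05d", seq_len(n_probes))
    mu <- stats::runif(n_probes, 5, 11)
    beta <- numeric(n_probes)
    de_idx <- if (n_de > 0) sample.int(n_probes, n_de) else integer(0)
    if (n_de > 0) beta[de_idx] <- effect_log2(n_de)
    pair_eff <- stats::rnorm(n_pairs, 0, pair_sd)
    n_samp <- 2L * n_pairs
    samples <- as.vector(rbind(sprintf("PAIR%02d_case", seq_len(n_pairs)),
                               sprintf("PAIR%02d_ctrl", seq_len(n_pairs))))
    is_case <- rep(c(1, 0), n_pairs)
    pair_of <- rep(seq_len(n_pairs), each = 2L)
    logx <- outer(mu, rep(1, n_samp)) +
      outer(rep(1, n_probes), pair_eff[pair_of]) +
      outer(beta, is_case) +
      matrix(stats::rnorm(n_probes * n_samp, 0, noise_sd), n_probes)
    x <- 2^logx - 1
    dimnames(x) <- list(probes, samples)
    design <- as_sample_design(data.frame(
      sample_id = samples,
      group = ifelse(is_case == 1, "case", "control"),
      pair_id = sprintf("PAIR%02d", pair_of),
      set = "A_train",
      gestational_age_weeks = round(rep(stats::runif(n_pairs, 24, 32),
                                        each = 2L), 1),
      stringsAsFactors = FALSE
    ))
    truth <- list(de_features = probes[de_idx],
                  effects_log2 = stats::setNames(beta[de_idx], probes[de_idx]),
                  seed = seed)
    list(expr = expression_matrix(x, "raw"), design = design, truth = truth)
  })
}

#' Simulate a qRT-PCR Ct panel with planted ratio structure
#'
#' Generates \code{Ct_gs = kappa_g - a_s - beta_g I(case) + eps} with
#' per-gene baselines \code{kappa_g}, a per-sample loading effect
#' \code{a_s ~ N(0, loading_sd)} shared by all genes of a sample (so that
#' gene-gene Ct differences cancel it exactly), planted cycle effects
#' \code{beta_g} and residual noise \code{eps ~ N(0, noise_sd)}. The default
#' plant raises gene \code{"V"} by one cycle in cases and lowers genes
#' \code{"O"} and \code{"H"} by one cycle, so the ratios O/V and H/V carry
#' two-cycle group differences. Training samples form complete matched
#' pairs (set A); test samples are unpaired (set B).
#'
#' @param n_pairs_train matched training pairs (default 14).
#' @param n_per_group_test test cases and test controls (default 19 each).
#' @param n_genes panel size (default 90).
#' @param loading_sd sd of the shared per-sample loading effect (cycles).
#' @param effects named numeric vector of planted cycle effects
#'   (positive = more abundant, i.e. lower Ct, in cases); \code{NULL} uses
#'   the default V/O/H plant.
#' @param noise_sd residual noise sd (cycles).
#' @param missing_rate probability a cell is missing (PCR failure),
#'   in [0, 0.2).
#' @param fail_samples number of test-set control samples given a
#'   whole-sample failure mode (at least five missing genes), to exercise
#'   prediction-time sample discard.
#' @param seed integer seed.
#' @return list with \code{ct} (gene x sample Ct matrix, NA = missing),
#'   \code{design}, and \code{truth} (planted normalizer, discriminative
#'   ratio pairs, effects, seed).
#' @export
simulate_ct_panel <- function(n_pairs_train = 14, n_per_group_test = 19,
                              n_genes = 90, loading_sd = 1.0, effects = NULL,
                              noise_sd = 0.5, missing_rate = 0,
                              fail_samples = 0, seed = 1) {
  if (missing_rate < 0 || missing_rate >= 0.2)
    stop("missing_rate must be in [0, 0.2)")
  if (n_genes < 2) stop("need at least 2 genes")
  genes <- c("V", "O", "H", sprintf("G%03d", seq_len(max(0, n_genes - 3L))))
  genes <- genes[seq_len(n_genes)]
  if (is.null(effects)) {
    effects <- c(V = 1, O = -1, H = -1)
    effects <- effects[names(effects) %in% genes]
  }
  if (length(effects) && (is.null(names(effects)) ||
                          !all(names(effects) %in% genes)))
    stop("effects reference gene(s) absent from the panel: ",
         paste(setdiff(names(effects), genes), collapse = ", "))
  with_seed(seed, {
    beta <- stats::setNames(numeric(n_genes), genes)
    beta[names(effects)] <- effects
    train_ids <- as.vector(rbind(sprintf("TR%02d_case", seq_len(n_pairs_train)),
                                 sprintf("TR%02d_ctrl", seq_len(n_pairs_train))))
    test_ids <- c(sprintf("TE%02d_case", seq_len(n_per_group_test)),
                  sprintf("TE%02d_ctrl", seq_len(n_per_group_test)))
    samples <- c(train_ids, test_ids)
    group <- c(rep(c("case", "control"), n_pairs_train),
               rep(c("case", "control"), each = n_per_group_test))
    pair_id <- c(rep(sprintf("TR%02d", seq_len(n_pairs_train)), each = 2L),
                 rep(NA_character_, 2L * n_per_group_test))
    set <- c(rep("A_train", 2L * n_pairs_train),
             rep("B_test", 2L * n_per_group_test))
    n_samp <- length(samples)
    kappa <- stats::runif(n_genes, 20, 30)
    loading <- stats::rnorm(n_samp, 0, loading_sd)
    is_case <- as.numeric(group == "case")
    ct <- outer(kappa, rep(1, n_samp)) -
      outer(rep(1, n_genes), loading) -
      outer(beta, is_case) +
      matrix(stats::rnorm(n_genes * n_samp, 0, noise_sd), n_genes)
    dimnames(ct) <- list(genes, samples)
    if (missing_rate > 0)
      ct[matrix(stats::runif(length(ct)) < missing_rate,
                nrow(ct))] <- NA_real_
    if (fail_samples > 0) {
      ctrl_test <- samples[set == "B_test" & group == "control"]
      victims <- ctrl_test[seq_len(min(fail_samples, length(ctrl_test)))]
      for (s in victims) {
        k <- max(5L, ceiling(n_genes * 0.1))
        ct[sample.int(n_genes, k), s] <- NA_real_
      }
    }
    ga <- round(stats::runif(n_samp, 24, 32), 1)
    ga[!is.na(pair_id)] <- rep(round(stats::runif(n_pairs_train, 24, 32), 1),
                               each = 2L)
    design <- as_sample_design(data.frame(
      sample_id = samples, group = group, pair_id = pair_id, set = set,
      gestational_age_weeks = ga,
      sex = sample(c("F", "M"), n_samp, replace = TRUE),
      sga = sample(c(TRUE, FALSE), n_samp, replace = TRUE, prob = c(.2, .8)),
      apgar5 = sample(5:10, n_samp, replace = TRUE),
      labor = sample(c(TRUE, FALSE), n_samp, replace = TRUE),
      chorioamnionitis = sample(c(TRUE, FALSE), n_samp, replace = TRUE,
                                prob = c(.3, .7)),
      stringsAsFactors = FALSE
    ))
    up <- names(effects)[effects > 0]
    down <- names(effects)[effects < 0]
    ratio_plants <- if (length(up) && length(down))
      lapply(down, function(g) c(numerator = g, denominator = up[1L]))
    else list()
    truth <- list(effects_cycles = effects,
                  normalizer_plant = if (length(up)) up[1L] else NULL,
                  discriminative_ratio_plants = ratio_plants,
                  seed = seed)
    list(ct = ct, design = design, truth = truth)
  })
}

#' Simulate gene-set collections with controlled overlap
#'
#' Each set consists of \code{n_shared} genes drawn once into a pool common
#' to all sets plus \code{set_size - n_shared} set-specific genes, drawn
#' without replacement so specific genes belong to exactly one set.
#'
#' @param n_sets number of sets.
#' @param set_size genes per set.
#' @param n_shared genes shared by all sets (<= set_size).
#' @param universe character vector of available gene ids.
#' @param seed integer seed.
#' @return a \code{geneset_collection} with the universe attached.
#' @export
simulate_genesets <- function(n_sets, set_size, n_shared, universe, seed = 1) {
  if (n_shared > set_size) stop("n_shared must not exceed set_size")
  need <- n_shared + n_sets * (set_size - n_shared)
  if (length(universe) < need)
    stop("universe too small: need ", need, " genes, have ", length(universe))
  with_seed(seed, {
    pool <- sample(universe, need)
    shared <- pool[seq_len(n_shared)]
    rest <- if (n_shared > 0) pool[-seq_len(n_shared)] else pool
    k <- set_size - n_shared
    sets <- lapply(seq_len(n_sets), function(i) {
      specific <- if (k > 0) rest[((i - 1L) * k + 1L):(i * k)] else character(0)
      c(shared, specific)
    })
    names(sets) <- sprintf("SET%02d", seq_len(n_sets))
    geneset_collection(sets, universe = universe)
  })
}
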