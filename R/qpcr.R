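#' Directional qRT-PCR confirmation of array candidates
#'
#' For each gene, the hypothesized direction from the microarray stage is
#' tested on Ct data with a one-tailed paired t-test on within-pair
#' differences of -Ct (case minus control; -Ct is the log2-scale abundance
#' surrogate). Pairs in which either member's Ct is missing are dropped for
#' that gene; a gene with fewer than \code{min_pairs} usable pairs is
#' flagged untestable and excluded from the confirmation tally. The qPCR
#' fold change is \code{sign(delta) * 2^|delta|} with a minus sign denoting
#' lower expression in cases.
#'
#' @param ct gene-by-sample Ct matrix (NA = missing).
#' @param design a \code{sample_design} with complete pairs.
#' @param directions named character vector gene -> \code{"up"}/\code{"down"}
#'   (the microarray direction serving as the alternative hypothesis).
#' @param p_max one-tailed significance threshold (default 0.05).
#' @param min_pairs minimum usable pairs for a gene to be testable
#'   (default 3).
#' @return data.frame (class \code{"qpcr_confirmation"}) with columns
#'   \code{gene}, \code{hypothesized_direction}, \code{n_pairs_used},
#'   \code{delta} (mean difference of -Ct), \code{FC_qpcr},
#'   \code{p_one_tailed}, \code{testable}, \code{confirmed}. Attributes
#'   \code{n_confirmed} and \code{n_testable} hold the tally.
#' @export
confirm_genes <- function(ct, design, directions, p_max = 0.05,
                          min_pairs = 3) {
  directions <- stats::setNames(as.character(directions), names(directions))
  if (!all(names(directions) %in% rownames(ct)))
    stop("direction(s) given for gene(s) absent from the Ct table: ",
         paste(setdiff(names(directions), rownames(ct)), collapse = ", "))
  if (!all(directions %in% c("up", "down")))
    stop("directions must be 'up' or 'down'")
  pairs <- design_pairs(design, samples = colnames(ct))
  rows <- lapply(names(directions), function(g) {
    # delta on the -Ct abundance scale: (-Ct_case) - (-Ct_ctrl)
    d <- ct[g, pairs$control] - ct[g, pairs$case]
    d <- d[is.finite(d)]
    dir <- directions[[g]]
    if (length(d) < min_pairs || stats::sd(d) == 0) {
      return(data.frame(gene = g, hypothesized_direction = dir,
                        n_pairs_used = length(d), delta = NA_real_,
                        FC_qpcr = NA_real_, p_one_tailed = NA_real_,
                        testable = FALSE, confirmed = FALSE,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(d, alternative = if (dir == "up") "greater" else "less")
    delta <- mean(d)
    data.frame(gene = g, hypothesized_direction = dir,
               n_pairs_used = length(d), delta = delta,
               FC_qpcr = if (delta == 0) 1 else sign(delta) * 2^abs(delta),
               p_one_tailed = tt$p.value,
               testable = TRUE,
               confirmed = tt$p.value < p_max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_confirmed") <- sum(out$confirmed)
  attr(out, "n_testable") <- sum(out$testable)
  class(out) <- c("qpcr_confirmation", "data.frame")
  out
}

#' @export
print.qpcr_confirmation <- function(x, ...) {
  cat(sprintf("qRT-PCR confirmation: %d of %d testable genes confirmed (%d untestable)\n",
              attr(x, "n_confirmed"), attr(x, "n_testable"),
              sum(!x$testable)))
  NextMethod()
}
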