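#' Validate a sample design table
#'
#' A sample design describes every profiled sample: its identifier, case or
#' control status, optional matched-pair membership (gestational-age matched
#' pairs), the experimental set it belongs to (training set A or blinded test
#' set B), and optional clinical covariates recorded at birth.
#'
#' Required columns are \code{sample_id} and \code{group} (values
#' \code{"case"} / \code{"control"}). Optional columns: \code{pair_id}
#' (matched-pair label; \code{NA} for unpaired samples), \code{set}
#' (\code{"A_train"} or \code{"B_test"}), and the clinical covariates
#' \code{gestational_age_weeks}, \code{sex}, \code{sga}, \code{apgar5},
#' \code{labor}, \code{chorioamnionitis}.
#'
#' Invariants enforced: sample ids unique; every non-missing \code{pair_id}
#' joins exactly one case and one control; gestational age, when present,
#' lies in [20, 37] weeks (the preterm range the design targets).
#'
#' @param design a data.frame with the columns above.
#' @return the validated data.frame, classed \code{"sample_design"}.
#' @export
as_sample_design <- function(design) {
  if (!is.data.frame(design))
    stop("design must be a data.frame")
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design is missing required column(s): ", paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design")
  design$group <- as.character(design$group)
  bad <- setdiff(unique(design$group), c("case", "control"))
  if (length(bad))
    stop("group must be 'case' or 'control'; found: ", paste(bad, collapse = ", "))
  if (!is.null(design$set)) {
    design$set <- as.character(design$set)
    bad <- setdiff(unique(stats::na.omit(design$set)), c("A_train", "B_test"))
    if (length(bad))
      stop("set must be 'A_train' or 'B_test'; found: ", paste(bad, collapse = ", "))
  }
  if (!is.null(design$pair_id)) {
    design$pair_id <- as.character(design$pair_id)
    design$pair_id[design$pair_id %in% c("", "NA")] <- NA_character_
    paired <- design[!is.na(design$pair_id), , drop = FALSE]
    if (nrow(paired)) {
      tab <- table(paired$pair_id, paired$group)
      if (!all(colnames(tab) %in% c("case", "control")) ||
          ncol(tab) < 2L || any(tab != 1L))
        stop("each pair_id must join exactly one case and one control")
    }
  }
  if (!is.null(design$gestational_age_weeks)) {
    ga <- design$gestational_age_weeks
    if (!is.numeric(ga))
      stop("gestational_age_weeks must be numeric")
    if (any(!is.na(ga) & (ga < 20 | ga > 37)))
      stop("gestational_age_weeks outside [20, 37]")
  }
  class(design) <- unique(c("sample_design", class(design)))
  design
}

#' Read a sample design table from a delimited file
#'
#' Tab-delimited by default, with comma fallback detected from the header
#' line. See \code{\link{as_sample_design}} for required columns.
#'
#' @param path file path.
#' @return a validated \code{sample_design} data.frame.
#' @export
read_design <- function(path) {
  as_sample_design(read_delim_sniff(path))
}

#' Extract complete case-control pairs from a design
#'
#' @param design a \code{sample_design}.
#' @param samples optional character vector; only pairs whose two members are
#'   both in \code{samples} are returned.
#' @return data.frame with columns \code{pair_id}, \code{case},
#'   \code{control} (sample ids).
#' @export
design_pairs <- function(design, samples = NULL) {
  design <- as_sample_design(as.data.frame(design))
  if (is.null(design$pair_id) || all(is.na(design$pair_id)))
    stop("design has no pair_id column; paired analysis impossible")
  d <- design[!is.na(design$pair_id), , drop = FALSE]
  if (!is.null(samples))
    d <- d[d$sample_id %in% samples, , drop = FALSE]
  ids <- unique(d$pair_id)
  keep <- vapply(ids, function(p) {
    sum(d$pair_id == p & d$group == "case") == 1L &&
      sum(d$pair_id == p & d$group == "control") == 1L
  }, logical(1))
  ids <- ids[keep]
  data.frame(
    pair_id = ids,
    case = vapply(ids, function(p)
      d$sample_id[d$pair_id == p & d$group == "case"], character(1)),
    control = vapply(ids, function(p)
      d$sample_id[d$pair_id == p & d$group == "control"], character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
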