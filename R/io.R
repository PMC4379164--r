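# Delimited-file helpers. All tables are UTF-8; tab-delimited by default with
# comma fallback sniffed from the header line.

read_delim_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Construct an expression matrix
#'
#' A probe-by-sample intensity matrix tagged with its processing state:
#' \code{"raw"} (non-negative intensities) or \code{"log2_normalized"}
#' (log2-transformed, quantile-normalized values).
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param state \code{"raw"} or \code{"log2_normalized"}.
#' @return the matrix with attribute \code{state}, classed
#'   \code{"expr_matrix"}.
#' @export
expression_matrix <- function(values, state = c("raw", "log2_normalized")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("expression matrix must have no missing cells")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate probe ids")
  if (state == "raw" && any(values < 0))
    stop("raw intensities must be non-negative")
  attr(values, "state") <- state
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d probes x %d samples (state: %s)\n",
              nrow(x), ncol(x), expr_state(x)))
  invisible(x)
}

#' Processing state of an expression matrix
#' @param m an \code{expr_matrix}.
#' @return \code{"raw"} or \code{"log2_normalized"}.
#' @export
expr_state <- function(m) {
  s <- attr(m, "state")
  if (is.null(s)) stop("matrix has no processing-state attribute")
  s
}

#' Read a probe-by-sample expression matrix
#'
#' First column holds probe ids; remaining columns are samples named in the
#' header. Every sample column must be described by the design; columns are
#' returned in the design's order.
#'
#' @param path matrix file (TSV, comma fallback).
#' @param design a \code{sample_design}, or a path to one.
#' @return an \code{expr_matrix} with \code{state = "raw"}.
#' @export
read_expression_matrix <- function(path, design) {
  if (is.character(design)) design <- read_design(design)
  design <- as_sample_design(as.data.frame(design))
  tab <- read_delim_sniff(path)
  probes <- as.character(tab[[1L]])
  if (anyDuplicated(probes))
    stop("duplicated probe id(s) in ", path, ": ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- probes
  unknown <- setdiff(colnames(m), design$sample_id)
  if (length(unknown))
    stop("sample(s) absent from design: ", paste(unknown, collapse = ", "))
  ord <- design$sample_id[design$sample_id %in% colnames(m)]
  m <- m[, ord, drop = FALSE]
  storage.mode(m) <- "double"
  expression_matrix(m, state = "raw")
}

#' Write an expression or Ct matrix as TSV
#'
#' @param m matrix with rownames and colnames.
#' @param path output path.
#' @param id_column name for the first (row id) column.
#' @export
write_matrix_tsv <- function(m, path, id_column = "feature") {
  # 17 significant digits so written doubles round-trip bit-exactly
  fm <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  df <- data.frame(rownames(m), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample Ct table
#'
#' Cycle-threshold (Ct) values from qRT-PCR; lower Ct means higher
#' abundance. Missing reactions (PCR failures) may be encoded as blank
#' cells, \code{"NA"}, \code{"NaN"}, or the sentinel \code{999}; they become
#' \code{NA}. Any other non-numeric cell is an error. Valid Ct values must
#' lie in (0, 45) cycles.
#'
#' @param path Ct table (genes in rows, samples in columns).
#' @param design a \code{sample_design} or path to one.
#' @return numeric matrix (genes x samples) with \code{NA} for missing
#'   cells, columns aligned to the design.
#' @export
read_ct_table <- function(path, design) {
  if (is.character(design)) design <- read_design(design)
  design <- as_sample_design(as.data.frame(design))
  tab <- read_delim_sniff(path)
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes)) stop("duplicated gene id(s) in ", path)
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- trimws(as.character(raw))
  missing_mask <- is.na(vals) | vals %in% c("", "NA", "NaN", "999", "999.0")
  num <- suppressWarnings(as.numeric(vals))
  bad <- !missing_mask & is.na(num)
  if (any(bad))
    stop("non-numeric Ct cell(s): ", paste(unique(vals[bad]), collapse = ", "))
  num[missing_mask] <- NA_real_
  m <- matrix(num, nrow = nrow(raw), dimnames = list(genes, colnames(raw)))
  if (any(!is.na(m) & (m <= 0 | m >= 45)))
    stop("Ct values must lie in (0, 45) cycles")
  unknown <- setdiff(colnames(m), design$sample_id)
  if (length(unknown))
    stop("sample(s) absent from design: ", paste(unknown, collapse = ", "))
  ord <- design$sample_id[design$sample_id %in% colnames(m)]
  m[, ord, drop = FALSE]
}

#' Write a Ct table with the 999 missing-value sentinel
#' @param ct gene-by-sample Ct matrix (NA = missing).
#' @param path output path.
#' @export
write_ct_table <- function(ct, path) {
  out <- ct
  out[is.na(out)] <- 999
  write_matrix_tsv(out, path, id_column = "gene")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields tab-separated — set name,
#' description, then member gene ids. Members are de-duplicated within a
#' set; a set with no members is an error.
#'
#' @param path GMT file.
#' @return named list of character vectors, classed
#'   \code{"geneset_collection"}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L || !any(nzchar(f[-(1:2)])))
      stop("GMT set '", f[1L], "' has no members")
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1L]][1L], character(1))
  geneset_collection(sets)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene ids, unique per set).
#' @param universe optional explicit gene universe.
#' @return the list classed \code{"geneset_collection"}, with attribute
#'   \code{universe} if given.
#' @export
geneset_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name")
  if (any(lengths(sets) == 0L)) stop("empty gene set(s)")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  attr(sets, "universe") <- universe
  class(sets) <- c("geneset_collection", "list")
  sets
}

#' Write a gene-set collection in GMT format
#' @param collection a \code{geneset_collection}.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, "na", collection[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
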