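#' Detection filter for tissue atlas samples
#'
#' A sequence is kept when, in at least one source (tissue or blood-cell
#' type), strictly more than `min_count` raw reads are observed in at least
#' `min_replicates` of that source's replicates. Sequences specific to a
#' single source therefore survive. A source with fewer replicates than
#' `min_replicates` is evaluated against the replicates it has, with a
#' warning.
#'
#' @param x an [srna_set] whose samples are tissues and/or blood cells
#' @param min_count raw-count threshold (strict `>`); default 25
#' @param min_replicates replicates that must pass; default 2
#' @return list with elements `matrix` (the filtered `srna_set`) and
#'   `report` (a `filter_report`: per-row keep flags and totals)
#' @export
filter_tissue <- function(x, min_count = 25, min_replicates = 2) {
  if (any(x$samples$source_class == "biofluid"))
    stop("filter_tissue expects tissue/blood-cell samples; see filter_biofluid")
  sources <- split(seq_len(ncol(x$counts)), x$samples$source)
  short <- names(sources)[lengths(sources) < min_replicates]
  if (length(short) > 0)
    warning("source(s) with fewer than ", min_replicates, " replicates: ",
            paste(short, collapse = ", "),
            " (evaluated against available replicates)")
  keep <- rep(FALSE, nrow(x$counts))
  for (cols in sources) {
    need <- min(min_replicates, length(cols))
    hits <- rowSums(x$counts[, cols, drop = FALSE] > min_count)
    keep <- keep | (hits >= need)
  }
  report <- filter_report(
    keep, sprintf(">%d counts in >=%d replicates of some source",
                  min_count, min_replicates))
  list(matrix = x[keep, ], report = report)
}

#' Detection filter for biofluid samples
#'
#' A sequence is kept iff the fraction of samples with raw count strictly
#' greater than `min_count` is strictly greater than `min_fraction`. Each
#' biofluid type is filtered independently; pass one biofluid at a time.
#'
#' @param x an [srna_set] of one biofluid's samples
#' @param min_count raw-count threshold (strict `>`); default 10
#' @param min_fraction sample fraction threshold (strict `>`); default 0.5
#' @return list with elements `matrix` and `report`, as [filter_tissue()]
#' @export
filter_biofluid <- function(x, min_count = 10, min_fraction = 0.5) {
  n <- ncol(x$counts)
  keep <- if (n == 0 || nrow(x$counts) == 0) {
    rep(FALSE, nrow(x$counts))
  } else {
    rowMeans(x$counts > min_count) > min_fraction
  }
  report <- filter_report(
    keep, sprintf(">%d counts in >%g%% of samples", min_count,
                  100 * min_fraction))
  list(matrix = x[keep, ], report = report)
}

filter_report <- function(keep, rule) {
  structure(list(n_input_rows = length(keep),
                 n_kept_rows = sum(keep),
                 rule = rule,
                 keep = keep),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report: kept", x$n_kept_rows, "of", x$n_input_rows,
      "rows [", x$rule, "]\n")
  invisible(x)
}
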