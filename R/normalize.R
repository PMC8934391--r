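#' Median-of-ratios normalization
#'
#' The size-factor method of Anders & Huber, as used by DESeq2. Reference
#' rows are those with a nonzero count in every sample; each reference row's
#' pseudo-reference is its geometric mean across samples, and a sample's
#' size factor is the median over reference rows of the ratio
#' count / pseudo-reference. Normalized counts are raw counts divided by the
#' sample's size factor. The median of an even number of ratios is the
#' arithmetic mean of the two central values.
#'
#' @param x an [srna_set] (raw counts), or a bare numeric count matrix
#' @return for an `srna_set`: the same object with added elements
#'   `size_factors` (one positive real per sample) and `normalized` (matrix,
#'   `counts[s, j] / size_factors[j]`), class extended by `"srna_norm"`; for
#'   a bare matrix: `list(size_factors, normalized)`.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("A", "B")))
#' median_of_ratios(m)$size_factors  # 1/sqrt(2), sqrt(2)
#' @export
median_of_ratios <- function(x) {
  counts <- if (inherits(x, "srna_set")) x$counts else as.matrix(x)
  if (ncol(counts) == 1) {
    warning("single sample: size factor set to 1")
    sf <- stats::setNames(1, colnames(counts))
  } else {
    log_counts <- log(counts)
    ref_rows <- which(rowSums(counts > 0) == ncol(counts))
    if (length(ref_rows) == 0)
      stop("no reference features: every row has a zero count in some sample")
    log_geo <- rowMeans(log_counts[ref_rows, , drop = FALSE])
    sf <- apply(log_counts[ref_rows, , drop = FALSE], 2,
                function(lc) stats::median(exp(lc - log_geo)))
  }
  normalized <- sweep(counts, 2, sf, "/")
  if (inherits(x, "srna_set")) {
    x$size_factors <- sf
    x$normalized <- normalized
    class(x) <- unique(c("srna_norm", class(x)))
    x
  } else {
    list(size_factors = sf, normalized = normalized)
  }
}

#' Replicate-mean expression profiles per source
#'
#' Averages normalized counts over the biological replicates of each source
#' (arithmetic mean), yielding the sequences x sources matrix on which
#' tissue-specificity is classified.
#'
#' @param x a normalized [srna_set] (see [median_of_ratios()])
#' @return numeric matrix, rows as in `x`, one column per source
#' @export
source_profiles <- function(x) {
  if (is.null(x$normalized))
    stop("normalize with median_of_ratios() first")
  src <- factor(x$samples$source, levels = unique(x$samples$source))
  prof <- t(rowsum(t(x$normalized), src, reorder = FALSE))
  sweep(prof, 2, as.numeric(table(src)), "/")
}
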