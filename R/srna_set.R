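#' Recognised small RNA biotypes, in exceRpt priority order
#'
#' Multi-mapping reads are resolved by assigning the candidate whose biotype
#' comes earliest in this order: miRNA, YRNA, tRNA, piRNA, protein coding,
#' then a bin for any other biotype.
#'
#' @export
BIOTYPES <- c("miRNA", "YRNA", "tRNA", "piRNA", "protein_coding", "other")

SOURCE_CLASSES <- c("tissue", "blood_cell", "biofluid")

#' Construct a unique-sequence count set
#'
#' The central container of the package: a matrix of raw integer counts with
#' one row per unique small RNA sequence and one column per sample, together
#' with per-sequence annotation (biotype, parent gene) and per-sample
#' metadata (source, source class, replicate). It is a plain list with class
#' `"srna_set"`, in the spirit of edgeR's `DGEList`.
#'
#' @param counts integer matrix, sequences in rows and samples in columns.
#'   Row names must be the sequences (uppercase ACGTN), column names the
#'   sample ids.
#' @param features data.frame with columns `sequence`, `biotype`,
#'   `parent_gene` and optionally `is_canonical`, one row per row of
#'   `counts`, in the same order.
#' @param samples data.frame with columns `sample_id`, `source`,
#'   `source_class` (one of tissue, blood_cell, biofluid) and `replicate`,
#'   one row per column of `counts`.
#' @param level `"sequence"` (the default; rows are unique sequences) or
#'   `"gene"` (rows are parent genes, as produced by [collapse_to_genes()];
#'   `features` then needs only `parent_gene` and `biotype`).
#'
#' @return An object of class `srna_set` with elements `counts`, `features`
#'   and `samples`.
#' @examples
#' x <- srna_set(
#'   counts   = matrix(c(5L, 0L, 3L, 9L), 2, 2,
#'                     dimnames = list(c("ACGTACGTACGTACGTACGT",
#'                                       "TGCATGCATGCATGCATGCA"),
#'                                     c("s1", "s2"))),
#'   features = data.frame(sequence = c("ACGTACGTACGTACGTACGT",
#'                                      "TGCATGCATGCATGCATGCA"),
#'                         biotype = c("miRNA", "tRNA"),
#'                         parent_gene = c("MIR-1", "TRF-1")),
#'   samples  = data.frame(sample_id = c("s1", "s2"), source = "LIVER",
#'                         source_class = "tissue", replicate = 1:2)
#' )
#' x
#' @export
srna_set <- function(counts, features, samples,
                     level = c("sequence", "gene")) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 || ncol(counts) > 0) storage.mode(counts) <- "integer"
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  rownames(features) <- NULL
  rownames(samples) <- NULL
  x <- structure(list(counts = counts, features = features, samples = samples,
                      level = level),
                 class = "srna_set")
  validate_srna_set(x)
  x
}

feature_ids <- function(x) {
  if (identical(x$level, "gene")) x$features$parent_gene else x$features$sequence
}

validate_srna_set <- function(x) {
  counts <- x$counts
  features <- x$features
  samples <- x$samples
  gene_level <- identical(x$level, "gene")
  need_f <- if (gene_level) c("parent_gene", "biotype")
            else c("sequence", "biotype", "parent_gene")
  if (!all(need_f %in% names(features)))
    stop("features must have columns: ", paste(need_f, collapse = ", "))
  need_s <- c("sample_id", "source", "source_class", "replicate")
  if (!all(need_s %in% names(samples)))
    stop("samples must have columns: ", paste(need_s, collapse = ", "))
  if (nrow(features) != nrow(counts))
    stop("features rows (", nrow(features), ") != count rows (", nrow(counts), ")")
  if (nrow(samples) != ncol(counts))
    stop("samples rows (", nrow(samples), ") != count columns (", ncol(counts), ")")
  if (nrow(counts) > 0) {
    if (anyNA(counts)) stop("counts contain NA")
    if (any(counts < 0)) {
      bad <- which(counts < 0, arr.ind = TRUE)[1, ]
      stop("negative count at sequence '", rownames(counts)[bad[1]],
           "', sample '", colnames(counts)[bad[2]], "'")
    }
    ids <- feature_ids(x)
    if (anyDuplicated(ids))
      stop("duplicate ", x$level, " row: ", ids[duplicated(ids)][1])
    if (!is.null(rownames(counts)) && !identical(rownames(counts), ids))
      stop("count row names disagree with feature ids")
    bad_bt <- setdiff(unique(features$biotype), BIOTYPES)
    if (length(bad_bt) > 0)
      stop("unknown biotype(s): ", paste(bad_bt, collapse = ", "))
    if (!gene_level && any(grepl("[^ACGTN]", features$sequence)))
      stop("sequences must be uppercase strings over A, C, G, T, N")
  }
  if (nrow(samples) > 0) {
    if (anyDuplicated(samples$sample_id))
      stop("duplicate sample_id: ",
           samples$sample_id[duplicated(samples$sample_id)][1])
    if (!is.null(colnames(counts)) &&
        !identical(colnames(counts), samples$sample_id))
      stop("count column names disagree with samples$sample_id")
    bad_cl <- setdiff(unique(samples$source_class), SOURCE_CLASSES)
    if (length(bad_cl) > 0)
      stop("unknown source_class: ", paste(bad_cl, collapse = ", "))
    if (any(!nzchar(samples$source))) stop("empty source name")
    if (any(samples$replicate < 1) ||
        any(samples$replicate != as.integer(samples$replicate)))
      stop("replicate must be a positive integer")
  }
  invisible(x)
}

#' @export
print.srna_set <- function(x, ...) {
  cat("srna_set:", nrow(x$counts), "unique sequences x",
      ncol(x$counts), "samples\n")
  if (nrow(x$features) > 0) {
    bt <- table(factor(x$features$biotype, levels = BIOTYPES))
    cat("  biotypes:",
        paste(names(bt)[bt > 0], bt[bt > 0], sep = ":", collapse = "  "), "\n")
  }
  if (nrow(x$samples) > 0)
    cat("  sources:", paste(unique(x$samples$source), collapse = ", "), "\n")
  if (!is.null(x$size_factors))
    cat("  normalized (size factors ",
        paste(signif(x$size_factors, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.srna_set <- function(x) dim(x$counts)

#' Subset a count set by row and/or column index
#'
#' Keeps counts, feature annotation, sample metadata (and, for normalized
#' sets, normalized values and size factors) in register.
#'
#' @param x an `srna_set`
#' @param i,j row (sequence) and column (sample) indices
#' @param ... ignored
#' @export
`[.srna_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  out <- x
  out$counts <- x$counts[i, j, drop = FALSE]
  out$features <- x$features[i, , drop = FALSE]
  rownames(out$features) <- NULL
  out$samples <- x$samples[j, , drop = FALSE]
  rownames(out$samples) <- NULL
  if (!is.null(x$normalized)) out$normalized <- x$normalized[i, j, drop = FALSE]
  if (!is.null(x$size_factors)) out$size_factors <- x$size_factors[j]
  out
}

#' Read a unique-sequence count matrix from TSV
#'
#' The count file is tab-separated with header columns `sequence`, `biotype`,
#' `parent_gene`, then one column per sample. The metadata file maps
#' `sample_id` to `source`, `source_class` and `replicate`. Every sample
#' column must have a metadata row; counts must be non-negative integers.
#'
#' @param path path to the count TSV
#' @param meta_path path to the sample metadata TSV
#' @return an [srna_set]
#' @seealso [write_count_matrix()] for the inverse; the pair round-trips
#'   exactly.
#' @export
read_count_matrix <- function(path, meta_path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  fixed <- c("sequence", "biotype", "parent_gene")
  if (!all(fixed %in% names(tab)[seq_along(fixed)]))
    stop("count file must start with columns: ", paste(fixed, collapse = ", "))
  meta <- read_sample_meta(meta_path)
  sample_cols <- setdiff(names(tab), fixed)
  missing_meta <- setdiff(sample_cols, meta$sample_id)
  if (length(missing_meta) > 0)
    stop("no metadata for sample column(s): ",
         paste(missing_meta, collapse = ", "))
  meta <- meta[match(sample_cols, meta$sample_id), , drop = FALSE]
  counts <- matrix(0L, nrow(tab), length(sample_cols),
                   dimnames = list(tab$sequence, sample_cols))
  for (j in seq_along(sample_cols)) {
    raw <- tab[[sample_cols[j]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | val < 0 | val != floor(val))
    if (length(bad) > 0)
      stop("invalid count '", raw[bad[1]], "' at sequence '",
           tab$sequence[bad[1]], "', sample '", sample_cols[j], "'")
    counts[, j] <- as.integer(val)
  }
  features <- tab[fixed]
  srna_set(counts, features, meta)
}

#' Read per-sample metadata from TSV
#'
#' @param path TSV with columns sample_id, source, source_class, replicate
#' @return data.frame of sample metadata
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "source", "source_class", "replicate")
  if (!all(need %in% names(meta)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  meta$replicate <- as.integer(meta$replicate)
  meta[need]
}

#' Write a count set (and its metadata) as TSV
#'
#' @param x an [srna_set]
#' @param path output path for the count TSV
#' @param meta_path optional output path for the sample metadata TSV
#' @return `path`, invisibly
#' @export
write_count_matrix <- function(x, path, meta_path = NULL) {
  validate_srna_set(x)
  if (identical(x$level, "gene"))
    stop("write_count_matrix expects a sequence-level set")
  tab <- cbind(x$features[c("sequence", "biotype", "parent_gene")],
               as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(
      x$samples[c("sample_id", "source", "source_class", "replicate")],
      meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
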