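#' Resolve a multi-mapping read's annotation by biotype priority
#'
#' Small RNA reads frequently map to several annotated features. Following
#' the exceRpt convention, the winning annotation is the candidate whose
#' biotype comes earliest in the priority order miRNA, YRNA, tRNA, piRNA,
#' protein coding, other. Ties within the winning biotype are broken
#' lexicographically on the gene id (the field does not prescribe a rule for
#' same-biotype multi-gene hits; this one is deterministic and documented).
#'
#' @param candidates data.frame with columns `parent_gene` and `biotype`
#'   (duplicates allowed; treated as a set)
#' @param priority character vector, a permutation of [BIOTYPES]
#' @return list with elements `parent_gene` and `biotype`
#' @examples
#' assign_biotype(data.frame(parent_gene = c("GENE-P", "GENE-T"),
#'                           biotype = c("piRNA", "tRNA")))
#' @export
assign_biotype <- function(candidates, priority = BIOTYPES) {
  if (!setequal(priority, BIOTYPES) || anyDuplicated(priority))
    stop("priority must be a permutation of the six biotypes")
  if (is.null(candidates) || nrow(candidates) == 0)
    stop("unannotated read: empty candidate set")
  bad <- setdiff(unique(candidates$biotype), BIOTYPES)
  if (length(bad) > 0) stop("unknown candidate biotype: ", bad[1])
  rank <- match(candidates$biotype, priority)
  best <- which(rank == min(rank))
  pick <- best[order(candidates$parent_gene[best])][1]
  list(parent_gene = candidates$parent_gene[pick],
       biotype = candidates$biotype[pick])
}

#' Collapse adapter-trimmed reads into a single-sample count column
#'
#' Reads that failed genome mapping are dropped; the rest are grouped by
#' their exact (trimmed) sequence, counted, and annotated by
#' [assign_biotype()] applied to the union of alignment candidates over all
#' reads sharing that sequence.
#'
#' @param reads data.frame with columns `read_id` and `sequence`
#' @param evidence data.frame with columns `read_id`, `genome_mapped`
#'   (logical) and `candidates` (string of `gene:biotype` pairs joined by
#'   `;`, possibly empty), one row per read
#' @param priority biotype priority order, see [assign_biotype()]
#' @param sample one-row data.frame of sample metadata (`sample_id`,
#'   `source`, `source_class`, `replicate`)
#' @return a single-column [srna_set]
#' @export
collapse_reads <- function(reads, evidence, priority = BIOTYPES, sample) {
  if (anyDuplicated(reads$read_id))
    stop("duplicate read_id: ", reads$read_id[duplicated(reads$read_id)][1])
  ev_idx <- match(reads$read_id, evidence$read_id)
  if (anyNA(ev_idx))
    stop("evidence missing for read(s): ",
         paste(utils::head(reads$read_id[is.na(ev_idx)], 3), collapse = ", "))
  mapped <- evidence$genome_mapped[ev_idx]
  reads <- reads[mapped, , drop = FALSE]
  cand <- evidence$candidates[ev_idx][mapped]
  if (nrow(reads) == 0) {
    return(srna_set(matrix(integer(0), 0, 1,
                           dimnames = list(NULL, sample$sample_id)),
                    data.frame(sequence = character(0),
                               biotype = character(0),
                               parent_gene = character(0)),
                    sample))
  }
  groups <- split(cand, reads$sequence)
  seqs <- names(groups)
  counts <- lengths(groups)
  ann <- lapply(groups, function(strings) {
    assign_biotype(parse_candidates(paste(strings, collapse = ";")), priority)
  })
  features <- data.frame(
    sequence = seqs,
    biotype = vapply(ann, `[[`, "", "biotype"),
    parent_gene = vapply(ann, `[[`, "", "parent_gene"))
  srna_set(matrix(as.integer(counts), ncol = 1,
                  dimnames = list(seqs, sample$sample_id)),
           features, sample)
}

parse_candidates <- function(string) {
  parts <- strsplit(string, ";", fixed = TRUE)[[1]]
  parts <- unique(parts[nzchar(parts)])
  if (length(parts) == 0)
    return(data.frame(parent_gene = character(0), biotype = character(0)))
  halves <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(halves) != 2))
    stop("malformed candidate '", parts[lengths(halves) != 2][1],
         "'; expected gene:biotype")
  data.frame(parent_gene = vapply(halves, `[`, "", 1),
             biotype = vapply(halves, `[`, "", 2))
}

format_candidates <- function(df) {
  paste(df$parent_gene, df$biotype, sep = ":", collapse = ";")
}

#' Collapse a sequence-level count set to parent genes
#'
#' Per gene and sample, counts (and normalized values, if present) are the
#' sums over that gene's sequences; the gene inherits the common biotype of
#' its sequences. Column (per-sample) totals are preserved exactly.
#'
#' @param x a sequence-level [srna_set]
#' @return a gene-level `srna_set`
#' @export
collapse_to_genes <- function(x) {
  if (identical(x$level, "gene")) return(x)
  bt_per_gene <- tapply(x$features$biotype, x$features$parent_gene,
                        function(b) length(unique(b)))
  if (any(bt_per_gene > 1))
    stop("parent gene '", names(bt_per_gene)[bt_per_gene > 1][1],
         "' is annotated with more than one biotype")
  gene <- factor(x$features$parent_gene)
  counts <- rowsum(x$counts, gene, reorder = TRUE)
  features <- data.frame(
    parent_gene = levels(gene),
    biotype = as.character(
      tapply(x$features$biotype, gene, `[`, 1)[levels(gene)]))
  out <- srna_set(counts, features, x$samples, level = "gene")
  if (!is.null(x$normalized)) {
    out$normalized <- rowsum(x$normalized, gene, reorder = TRUE)
    out$size_factors <- x$size_factors
  }
  out
}

#' Read adapter-trimmed reads from FASTA or FASTQ
#'
#' @param path reads file; format inferred from the extension
#'   (`.fastq`/`.fq` vs FASTA otherwise)
#' @return data.frame with columns `read_id` and `sequence`
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  data.frame(read_id = sub(" .*", "", names(ss)),
             sequence = as.character(ss))
}

#' Read or write per-read alignment evidence as TSV
#'
#' Columns: `read_id`, `genome_mapped` (TRUE/FALSE), `candidates`
#' (semicolon-joined `gene:biotype` pairs, empty when none).
#'
#' @param path TSV path
#' @return data.frame of evidence
#' @export
read_evidence <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "logical", "character"),
                          na.strings = NULL)
  need <- c("read_id", "genome_mapped", "candidates")
  if (!all(need %in% names(ev)))
    stop("evidence file must have columns: ", paste(need, collapse = ", "))
  ev[need]
}

#' @param evidence data.frame as returned by [read_evidence()]
#' @rdname read_evidence
#' @export
write_evidence <- function(evidence, path) {
  utils::write.table(evidence[c("read_id", "genome_mapped", "candidates")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate reads by exact substring match against a reference FASTA
#'
#' A small-fixture stand-in for genome/transcriptome alignment: a read is
#' genome-mapped when its sequence occurs as an exact substring of at least
#' one reference entry, and every containing entry contributes its
#' (gene, biotype) as a candidate. Reference FASTA headers must be
#' `gene biotype` (whitespace-separated).
#'
#' @param reads data.frame with columns `read_id`, `sequence`
#' @param reference_path FASTA of reference small RNA sequences
#' @return evidence data.frame usable with [collapse_reads()]
#' @export
annotate_exact <- function(reads, reference_path) {
  ref <- Biostrings::readDNAStringSet(reference_path)
  hdr <- strsplit(names(ref), "\\s+")
  if (any(lengths(hdr) < 2))
    stop("reference headers must be 'gene biotype'")
  genes <- vapply(hdr, `[`, "", 1)
  biotypes <- vapply(hdr, `[`, "", 2)
  ref_seq <- as.character(ref)
  cand <- vapply(reads$sequence, function(s) {
    hit <- which(vapply(ref_seq, function(r) grepl(s, r, fixed = TRUE), TRUE))
    if (length(hit) == 0) ""
    else paste(genes[hit], biotypes[hit], sep = ":", collapse = ";")
  }, "", USE.NAMES = FALSE)
  data.frame(read_id = reads$read_id,
             genome_mapped = nzchar(cand),
             candidates = cand)
}
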