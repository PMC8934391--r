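test_that("biotype assignment follows the priority order and is order-invariant", {
  # tRNA outranks piRNA
  expect_equal(assign_biotype(data.frame(parent_gene = c("GENE-P", "GENE-T"),
                                         biotype = c("piRNA", "tRNA"))),
               list(parent_gene = "GENE-T", biotype = "tRNA"))
  # miRNA outranks protein coding
  expect_equal(assign_biotype(data.frame(parent_gene = c("MIR-X", "GENE-C"),
                                         biotype = c("miRNA", "protein_coding"))),
               list(parent_gene = "MIR-X", biotype = "miRNA"))
  # singleton
  expect_equal(assign_biotype(data.frame(parent_gene = "GENE-O",
                                         biotype = "other")),
               list(parent_gene = "GENE-O", biotype = "other"))
  # set semantics: any permutation of candidates gives the same answer
  cand <- data.frame(parent_gene = c("G1", "G2", "G3", "G4"),
                     biotype = c("protein_coding", "YRNA", "piRNA", "YRNA"))
  base <- assign_biotype(cand)
  for (seed in 1:10) {
    set.seed(seed)
    expect_equal(assign_biotype(cand[sample(nrow(cand)), ]), base)
  }
  # same-priority tie broken lexicographically on gene id
  expect_equal(assign_biotype(data.frame(parent_gene = c("MIR-B", "MIR-A"),
                                         biotype = c("miRNA", "miRNA"))),
               list(parent_gene = "MIR-A", biotype = "miRNA"))
  expect_error(assign_biotype(data.frame(parent_gene = character(0),
                                         biotype = character(0))),
               "unannotated")
})

test_that("read collapsing counts unique sequences of genome-mapped reads", {
  s1 <- "ACGTACGTACGTACGTACGT"
  s2 <- "TTTTCCCCGGGGAAAATTTT"
  s3 <- "GGGGAAAACCCCTTTTGGGG"
  reads <- data.frame(read_id = paste0("r", 1:5),
                      sequence = c(s1, s1, s1, s2, s3))
  ev <- data.frame(read_id = paste0("r", 1:5),
                   genome_mapped = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                   candidates = c(rep("MIR-1:miRNA", 3), "TRF-1:tRNA",
                                  "PIR-1:piRNA"))
  sm <- data.frame(sample_id = "s1", source = "LIVER",
                   source_class = "tissue", replicate = 1L)
  out <- collapse_reads(reads, ev, sample = sm)
  expect_equal(nrow(out$counts), 2)  # unmapped s3 dropped
  expect_equal(unname(out$counts[s1, 1]), 3L)
  expect_equal(unname(out$counts[s2, 1]), 1L)
  expect_equal(out$features$biotype[out$features$sequence == s1], "miRNA")
  expect_equal(out$features$biotype[out$features$sequence == s2], "tRNA")

  # total conservation: genome-mapped reads == sum of all cells
  expect_equal(sum(out$counts), 4)

  # empty input
  empty <- collapse_reads(reads[0, ], ev[0, ], sample = sm)
  expect_equal(dim(empty$counts), c(0, 1))

  # n identical reads, one annotation -> one row with count n
  n <- 17
  reads_n <- data.frame(read_id = paste0("r", 1:n), sequence = s1)
  ev_n <- data.frame(read_id = paste0("r", 1:n), genome_mapped = TRUE,
                     candidates = "MIR-1:miRNA")
  out_n <- collapse_reads(reads_n, ev_n, sample = sm)
  expect_equal(unname(out_n$counts[1, 1]), n)

  # deterministic: bit-identical on re-run
  expect_identical(collapse_reads(reads, ev, sample = sm), out)

  # missing evidence is a hard error
  expect_error(collapse_reads(reads, ev[-2, ], sample = sm), "r2")
})

test_that("multi-mapper conflicts across reads of one sequence resolve by priority", {
  s <- "ACGTACGTACGTACGTACGT"
  reads <- data.frame(read_id = c("a", "b"), sequence = s)
  ev <- data.frame(read_id = c("a", "b"), genome_mapped = TRUE,
                   candidates = c("PIR-9:piRNA", "YRF-2:YRNA"))
  sm <- data.frame(sample_id = "s1", source = "LIVER",
                   source_class = "tissue", replicate = 1L)
  out <- collapse_reads(reads, ev, sample = sm)
  expect_equal(out$features$biotype, "YRNA")  # YRNA outranks piRNA
  expect_equal(unname(out$counts[1, 1]), 2L)
})

test_that("gene collapsing sums isoform counts and preserves totals", {
  x <- toy_set(matrix(c(3, 4, 10), 3, 1))
  x$features$parent_gene <- c("GENE-X", "GENE-X", "GENE-Y")
  g <- collapse_to_genes(x)
  expect_equal(unname(g$counts["GENE-X", 1]), 7L)
  expect_equal(unname(g$counts["GENE-Y", 1]), 10L)
  expect_equal(g$level, "gene")

  # one-sequence-per-gene input is unchanged
  y <- toy_set(matrix(c(2, 5), 2, 1))
  gy <- collapse_to_genes(y)
  expect_equal(sort(as.vector(gy$counts)), c(2L, 5L))

  # per-sample totals preserved on random matrices
  for (seed in 1:100) {
    r <- random_set(seed)
    expect_equal(colSums(collapse_to_genes(r)$counts), colSums(r$counts))
  }

  # a gene spanning two biotypes is an annotation inconsistency
  bad <- toy_set(matrix(c(1, 1), 2, 1))
  bad$features$parent_gene <- "GENE-Z"
  bad$features$biotype <- c("miRNA", "tRNA")
  expect_error(collapse_to_genes(bad), "GENE-Z")
})

test_that("FASTA/FASTQ reads and evidence TSV round-trip through file IO", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "reads.fasta")
  writeLines(c(">r1 extra", "ACGTACGTACGTACGTACGT",
               ">r2", "TTTTCCCCGGGGAAAATTTT"), fa)
  reads <- read_reads(fa)
  expect_equal(reads$read_id, c("r1", "r2"))
  expect_equal(nchar(reads$sequence), c(20L, 20L))

  fq <- file.path(dir, "reads.fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII"), fq)
  expect_equal(read_reads(fq)$sequence, "ACGTACGT")

  ev <- data.frame(read_id = c("r1", "r2"),
                   genome_mapped = c(TRUE, FALSE),
                   candidates = c("MIR-1:miRNA;TRF-2:tRNA", ""))
  ep <- file.path(dir, "ev.tsv")
  write_evidence(ev, ep)
  expect_identical(read_evidence(ep), ev)
})

test_that("exact-match annotation flags substring hits against a reference", {
  dir <- withr::local_tempdir()
  ref <- file.path(dir, "ref.fasta")
  writeLines(c(">MIR-1 miRNA", "AAACGTACGTACGTACGTACGTAAA",
               ">TRF-1 tRNA", "GGGGTTTTAAAACCCCGGGGTTTT"), ref)
  reads <- data.frame(read_id = c("a", "b", "c"),
                      sequence = c("ACGTACGTACGTACGTACGT",  # inside MIR-1
                                   "TTTTAAAACCCCGGGG",      # inside TRF-1
                                   "CCCCCCCCCCCCCCCC"))     # nowhere
  ev <- annotate_exact(reads, ref)
  expect_equal(ev$genome_mapped, c(TRUE, TRUE, FALSE))
  expect_equal(ev$candidates[1], "MIR-1:miRNA")
  expect_equal(ev$candidates[2], "TRF-1:tRNA")
})
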