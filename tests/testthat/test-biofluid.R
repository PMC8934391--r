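test_that("biofluid detection equals the biofluid filter on the same input", {
  cfg <- pipeline_config()
  x <- toy_set(matrix(c(rep(11, 6), rep(0, 4),
                        rep(10, 10),
                        rep(50, 10)), 3, 10, byrow = TRUE),
               class = "biofluid")
  det <- detect_in_biofluid(x, cfg)
  expect_setequal(det, x$features$sequence[c(1, 3)])

  expect_length(detect_in_biofluid(x[0, ], cfg), 0)

  for (seed in 1:20) {
    y <- random_set(seed, n_seq = 15, n_samp = 8, max_count = 20)
    y$samples$source_class <- "biofluid"
    expect_setequal(detect_in_biofluid(y, cfg),
                    filter_biofluid(y)$matrix$features$sequence)
  }
})

test_that("attribution follows the double-counting rule and hand-worked fractions", {
  att <- attribute(detected = c("s1", "s2", "s3"),
                   elevated = list(A = c("s1", "s2"), B = c("s2", "s3")),
                   mean_counts = c(s1 = 100, s2 = 50, s3 = 50))
  expect_equal(att$n_detected_sequences, c(2L, 2L))
  expect_equal(att$read_sum, c(150, 100))
  expect_equal(att$read_fraction, c(0.6, 0.4))
  expect_equal(sum(att$read_fraction), 1)

  # disjoint detected set: zeros with a warning
  expect_warning(
    z <- attribute(detected = "sX",
                   elevated = list(A = "s1", B = "s2"),
                   mean_counts = c(sX = 5)),
    "fraction")
  expect_equal(z$read_fraction, c(0, 0))
  expect_equal(z$n_detected_sequences, c(0L, 0L))

  # a single contributing tissue takes fraction 1
  s <- attribute(detected = c("s1", "s2"),
                 elevated = list(A = c("s1", "s2"), B = "s9"),
                 mean_counts = c(s1 = 10, s2 = 30))
  expect_equal(s$read_fraction, c(1, 0))

  # the alternative denominator counts shared sequences once
  att2 <- attribute(detected = c("s1", "s2", "s3"),
                    elevated = list(A = c("s1", "s2"), B = c("s2", "s3")),
                    mean_counts = c(s1 = 100, s2 = 50, s3 = 50),
                    denominator = "detected")
  expect_equal(att2$read_fraction, c(150 / 200, 100 / 200))

  expect_error(attribute(detected = "s1", elevated = list(A = "s1"),
                         mean_counts = c(s2 = 1)), "mean_counts")
})

test_that("attribution fractions sum to one whenever anything is detected", {
  for (seed in 1:50) {
    set.seed(seed)
    ids <- paste0("q", 1:30)
    elev <- lapply(1:5, function(i) sample(ids, sample(3:10, 1)))
    names(elev) <- paste0("T", 1:5)
    det <- sample(ids, 20)
    mc <- stats::setNames(rexp(30, 1 / 100), ids)
    att <- attribute(det, elev, mc)
    if (sum(att$read_sum) > 0)
      expect_equal(sum(att$read_fraction), 1, tolerance = 1e-12)
  }
})

test_that("diversity counts sequences and collapsed genes over the cutoff", {
  # gene X isoforms at (12, 11, 4): 2 sequences pass, the collapsed gene
  # (27) passes as one
  x <- toy_set(matrix(c(12, 11, 4), 3, 1), sources = "LIVER")
  x$features$parent_gene <- "GENE-X"
  x$normalized <- x$counts + 0
  x$size_factors <- 1
  d <- diversity(x, cutoff = 10)
  expect_equal(d$sequence_diversity, 2L)
  expect_equal(d$gene_diversity, 1L)

  # collapsing can rescue a gene none of whose isoforms pass alone
  y <- toy_set(matrix(c(6, 6, 0), 3, 1), sources = "LIVER")
  y$features$parent_gene <- c("GENE-X", "GENE-X", "GENE-Y")
  y$normalized <- y$counts + 0
  y$size_factors <- 1
  dy <- diversity(y, cutoff = 10)
  expect_equal(dy$sequence_diversity, 0L)
  expect_equal(dy$gene_diversity, 1L)

  # all-zero source
  z <- toy_set(matrix(0, 2, 1), sources = "LIVER")
  z$normalized <- z$counts * 0
  z$size_factors <- 1
  dz <- diversity(z)
  expect_equal(c(dz$gene_diversity, dz$sequence_diversity), c(0L, 0L))

  # one sequence per gene, all passing: the two counts agree
  w <- toy_set(matrix(c(20, 30, 40), 3, 1), sources = "LIVER")
  w$normalized <- w$counts + 0
  w$size_factors <- 1
  dw <- diversity(w)
  expect_equal(dw$gene_diversity, dw$sequence_diversity)
})

test_that("rarefaction expectation matches closed forms and boundary cases", {
  counts <- c(5, 5)
  expect_equal(rarefaction(counts, 0), 0)
  expect_equal(rarefaction(counts, 10), 2)              # full depth
  expect_equal(rarefaction(counts, 5), 2 * (1 - 1 / choose(10, 5)),
               tolerance = 1e-10)
  expect_equal(rarefaction(c(3, 0, 7), 10), 2)          # zero class absent
  expect_error(rarefaction(counts, 11), "depth")
  expect_error(rarefaction(c(1.5, 2), 1), "integer")
})

test_that("rarefaction agrees with Monte-Carlo subsampling and is concave", {
  set.seed(11)
  mc <- mc_rarefaction(c(5, 5), 5, n_draws = 2e4)
  expect_lt(abs(rarefaction(c(5, 5), 5) - mc$mean), 3 * mc$se)

  for (seed in 1:20) {
    set.seed(seed)
    counts <- sample(0:40, 8, replace = TRUE)
    if (sum(counts) < 4) counts <- counts + 1
    depths <- 0:sum(counts)
    rich <- vapply(depths, function(d) rarefaction(counts, d), 0)
    expect_true(all(diff(rich) >= -1e-9))          # monotone
    expect_true(all(diff(diff(rich)) <= 1e-9))     # concave
    expect_equal(rich[length(rich)], sum(counts > 0))
  }
})

test_that("BH adjustment reproduces the step-up formula in original order", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")

  # permutation equivariance and monotonicity on sorted input
  set.seed(3)
  for (i in 1:20) {
    p <- runif(15)
    perm <- sample(15)
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
    expect_true(all(diff(bh_adjust(sort(p))) >= -1e-12))
  }
})

test_that("DE annotation joins elevation calls and flags significance", {
  calls <- data.frame(id = c("s1", "s2"),
                      category = c("tissue_enriched", "group_enriched"),
                      tissues = c("LIVER", "HEART;LUNG"),
                      fold_change = c(12, 8))
  de <- data.frame(sequence = c("s1", "s9", "s3"),
                   log2fc = c(2.5, -1, 0.2),
                   pvalue = c(0.001, 0.02, 0.9))
  ann <- annotate_de(de, calls, alpha = 0.05)
  expect_equal(attr(ann, "padj_source"), "computed")
  expect_equal(ann$padj, p.adjust(de$pvalue, "BH"))
  expect_true(ann$significant[1])
  expect_equal(ann$category[1], "tissue_enriched")
  expect_equal(ann$tissues[1], "LIVER")
  expect_equal(ann$category[2], "not_elevated")  # absent from calls

  # nothing significant
  none <- annotate_de(data.frame(sequence = "sA", log2fc = 1, pvalue = 0.9),
                      calls)
  expect_false(any(none$significant))

  # supplied adjusted p-values pass through
  pre <- annotate_de(data.frame(sequence = "s1", log2fc = 1, pvalue = 0.04,
                                padj = 0.2), calls)
  expect_equal(attr(pre, "padj_source"), "supplied")
  expect_false(pre$significant)

  expect_error(annotate_de(data.frame(sequence = c("a", "a"), log2fc = 0,
                                      pvalue = 0.5), calls), "duplicate")
})
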