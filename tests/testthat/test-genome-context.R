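test_that("gene BED parsing maps fields and preserves strands", {
  path <- make_gene_bed(c(
    "# comment line",
    "chr1\t1000\t5000\tGENEA\t0\t+",
    "chr1\t2000\t7000\tGENEC\t0\t-",
    "chr2\t100\t900\tGENED\t0\t+"))
  genes <- read_gene_bed(path)
  expect_equal(nrow(genes), 3)
  expect_equal(genes$gene_id, c("GENEA", "GENEC", "GENED"))
  expect_equal(genes$strand, c("+", "-", "+"))
  expect_equal(genes$start[1], 1000)
  expect_equal(genes$end[1], 5000)
})

test_that("gene BED validation rejects malformed records", {
  expect_error(read_gene_bed(make_gene_bed("chr1\t5000\t1000\tGENEB")),
               "start >= end.*line")
  expect_error(read_gene_bed(make_gene_bed("chr1\t10\t2.5\tGENEB")),
               "non-integer")
  expect_error(read_gene_bed(make_gene_bed(c("chr1\t1\t10\tA\t0\t+",
                                             "chr1\t5\t20\tA\t0\t+"))),
               "duplicate")
  expect_error(read_gene_bed(make_gene_bed("chr1\t1\t10")), "4 columns")
  expect_warning(genes <- read_gene_bed(make_gene_bed("chr1\t1\t10\tA")),
                 "strand")
  expect_equal(genes$strand, "+")
})

test_that("promoter intervals are strand-aware and truncated at zero", {
  genes <- data.frame(gene_id = c("GENEA", "GENEC", "GENEE"),
                      chrom = "chr1",
                      start = c(1000, 2000, 500), end = c(5000, 7000, 900),
                      strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  ctx <- context_def("prom", "meth", promoter_rule(1000, 500))
  expect_message(iv <- derive_intervals(genes, ctx), "truncated")
  expect_equal(iv$start[1], 0)
  expect_equal(iv$end[1], 1500)
  # minus strand: upstream extends to larger coordinates from TSS = end
  expect_equal(iv$start[2], 6500)
  expect_equal(iv$end[2], 8000)
  expect_equal(iv$tss[2], 7000)
  # truncation case: TSS 500, upstream 1000
  expect_equal(iv$start[3], 0)
  expect_equal(iv$end[3], 1000)
})

test_that("gene body intervals equal the annotated span", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 300, end = 900,
                      strand = "-", stringsAsFactors = FALSE)
  iv <- derive_intervals(genes, context_def("body", "meth", body_rule()))
  expect_equal(c(iv$start, iv$end), c(300, 900))
  expect_equal(iv$tss, 900)
})

test_that("interval derivation is strand-symmetric under reflection", {
  L <- 100000
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 4000,
                      end = 9000, strand = "+", stringsAsFactors = FALSE)
  mirrored <- data.frame(gene_id = "G1", chrom = "chr1", start = L - 9000,
                         end = L - 4000, strand = "-",
                         stringsAsFactors = FALSE)
  ctx <- context_def("prom", "meth", promoter_rule(1200, 300))
  iv <- derive_intervals(genes, ctx)
  iv_m <- derive_intervals(mirrored, ctx)
  expect_equal(iv_m$start, L - iv$end)
  expect_equal(iv_m$end, L - iv$start)
})

test_that("custom BED intervals link to the nearest TSS within range", {
  genes <- data.frame(gene_id = c("GA", "GB"), chrom = "chr1",
                      start = c(1000, 40000), end = c(5000, 45000),
                      strand = "+", stringsAsFactors = FALSE)
  bed <- write_lines_tmp(c("chr1\t900\t950", "chr1\t200000\t200100"),
                         ext = ".bed")
  ctx <- context_def("enh", "meth", bed_rule(bed, max_distance = 10000))
  expect_message(iv <- derive_intervals(genes, ctx), "dropped")
  expect_equal(nrow(iv), 1)
  expect_equal(iv$gene_id, "GA")
  expect_equal(c(iv$start, iv$end), c(900, 950))
})

test_that("equidistant TSS ties go to the lexicographically smaller gene", {
  genes <- data.frame(gene_id = c("GZ", "GA"), chrom = "chr1",
                      start = c(2000, 4000), end = c(2500, 4500),
                      strand = "+", stringsAsFactors = FALSE)
  bed <- write_lines_tmp("chr1\t2998\t3003", ext = ".bed")
  iv <- derive_intervals(genes,
                         context_def("enh", "meth", bed_rule(bed)))
  expect_equal(iv$gene_id, "GA")
})

test_that("locus association uses half-open semantics", {
  intervals <- data.frame(gene_id = "G1", context = "prom", chrom = "chr1",
                          start = 0, end = 1500, tss = 1000,
                          stringsAsFactors = FALSE)
  loci <- data.frame(chrom = "chr1", position = c(100L, 1499L, 1500L),
                     effect = 1, p = 0.5, stringsAsFactors = FALSE)
  ctx <- context_def("prom", "meth", promoter_rule())
  assoc <- associate_loci(intervals, loci, ctx)
  expect_equal(assoc$intervals$n, 2)
  expect_equal(assoc$loci[[1]]$position, c(100, 1499))
})

test_that("TSS-decay locus weights halve per half-life", {
  intervals <- data.frame(gene_id = "G1", context = "prom", chrom = "chr1",
                          start = 0, end = 3000, tss = 1000,
                          stringsAsFactors = FALSE)
  loci <- data.frame(chrom = "chr1", position = c(1000L, 2000L),
                     effect = 1, p = 0.5, stringsAsFactors = FALSE)
  ctx <- context_def("prom", "meth", promoter_rule(),
                     locus_weighting = "tss_decay", halflife = 1000)
  assoc <- associate_loci(intervals, loci, ctx)
  expect_equal(assoc$loci[[1]]$weight, c(1.0, 0.5))
})

test_that("locus association matches the brute-force overlap scan", {
  set.seed(11)
  intervals <- data.frame(gene_id = c("G1", "G2", "G3"), context = "c",
                          chrom = "chr1", start = c(0, 2000, 5000),
                          end = c(1500, 3500, 6000),
                          tss = c(0, 2000, 5000), stringsAsFactors = FALSE)
  for (rep in 1:5) {
    loci <- data.frame(chrom = "chr1",
                       position = sample.int(7000, 40) - 1L,
                       effect = rnorm(40), p = runif(40),
                       stringsAsFactors = FALSE)
    loci <- loci[order(loci$position), ]
    ctx <- context_def("c", "meth", body_rule())
    assoc <- associate_loci(intervals, loci, ctx)
    truth <- bf_overlap(loci, intervals)
    expect_equal(assoc$intervals$n, unname(colSums(truth)))
    # disjoint intervals: every locus in at most one interval
    expect_true(all(rowSums(truth) <= 1))
    for (j in 1:3) {
      expect_equal(sort(assoc$loci[[j]]$position),
                   sort(loci$position[truth[, j]]))
    }
  }
})

test_that("intervals without loci are retained and flagged", {
  intervals <- data.frame(gene_id = c("G1", "G2"), context = "c",
                          chrom = "chr1", start = c(0, 5000),
                          end = c(100, 5100), tss = c(0, 5000),
                          stringsAsFactors = FALSE)
  loci <- data.frame(chrom = "chr1", position = 50L, effect = 1, p = 0.5,
                     stringsAsFactors = FALSE)
  assoc <- associate_loci(intervals, loci, context_def("c", "m", body_rule()))
  expect_equal(assoc$intervals$n, c(1, 0))
  expect_equal(attr(assoc, "missing_data"), "G2")
})

test_that("score tracks honor declared 1-based coordinates", {
  path <- make_track("chr1", c(10, 5), c(1, -1), c(0.5, 0.1))
  t0 <- read_score_track(path)
  t1 <- read_score_track(path, one_based = TRUE)
  expect_equal(t0$position, c(5, 10))
  expect_equal(t1$position, c(4, 9))
  expect_error(read_score_track(make_track("chr1", 1, 1, 1.5)), "0, 1")
})
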