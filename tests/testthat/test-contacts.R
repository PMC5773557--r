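write_triplets <- function(lines) {
  p <- tempfile(fileext = ".txt")
  writeLines(lines, p)
  p
}

test_that("triplet parser handles records, empties and malformed lines", {
  p <- write_triplets("55000\t150700000\t3")
  rec <- read_contacts(p, "chr14", "chr7")
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$bin_a_start, 55000)
  expect_equal(rec$bin_b_start, 150700000)
  expect_equal(rec$count, 3)
  expect_identical(attr(rec, "resolution"), 5000L)

  empty <- write_triplets(character(0))
  expect_identical(nrow(read_contacts(empty, "a", "b")), 0L)

  hdr <- write_triplets(c("binA\tbinB\tcount", "5000\t10000\t2"))
  expect_error(read_contacts(hdr, "a", "b"), "line 1")
  expect_warning(rec2 <- read_contacts(hdr, "a", "b", lenient = TRUE),
                 "skipped 1")
  expect_identical(nrow(rec2), 1L)

  neg <- write_triplets("5000\t10000\t-2")
  expect_error(read_contacts(neg, "a", "b"), "parse error")
})

test_that("region lookup equals a brute-force overlap scan", {
  rec <- data.frame(
    chrom_a = c("chrA", "chrA", "chrA", "chrA", "chrB", "chrA"),
    bin_a_start = c(0, 5000, 10000, 15000, 5000, 20000),
    chrom_b = "chrB",
    bin_b_start = c(0, 0, 5000, 10000, 0, 0),
    count = c(1, 0, 2, 3, 5, 4), stringsAsFactors = FALSE)
  attr(rec, "resolution") <- 5000L
  class(rec) <- c("contact_records", "data.frame")

  region <- genomic_interval("chrA", 5000, 15000)  # covers two bins
  got <- contacts_for_region(rec, region)
  want <- contacts_region_oracle(rec, region, 5000)
  expect_equal(got$bin_a_start, want$bin_a_start)  # zero-count bin dropped
  expect_identical(nrow(got), 1L)

  # a single-bin region returns only that bin
  one <- contacts_for_region(rec, genomic_interval("chrA", 15000, 20000))
  expect_equal(one$bin_a_start, 15000)

  # a 50-kb region at 5-kb resolution touches exactly 10 bins
  bins <- seq(0, 95000, 5000)
  rec10 <- data.frame(chrom_a = "chrA", bin_a_start = bins, chrom_b = "chrB",
                      bin_b_start = 0, count = 1)
  attr(rec10, "resolution") <- 5000L
  got10 <- contacts_for_region(rec10, genomic_interval("chrA", 25000, 75000))
  expect_identical(nrow(got10), 10L)

  # symmetric lookup also matches B-side bins, swapped onto the A side
  sym <- contacts_for_region(rec, genomic_interval("chrB", 0, 5000),
                             symmetric = TRUE)
  expect_identical(nrow(sym), 3L)
  expect_true(all(sym$chrom_a == "chrB"))
})

test_that("bin annotation uses overlap, nearest gene and the tie rule", {
  genes <- data.frame(
    gene_id = c("X", "Y", "Z"), chrom = "chrB",
    start = c(20000, 62000, 100000), end = c(25000, 70000, 110000),
    strand = "+", stringsAsFactors = FALSE)
  mk <- function(bstarts, counts = 1) {
    r <- data.frame(chrom_a = "chrA", bin_a_start = 0, chrom_b = "chrB",
                    bin_b_start = bstarts, count = counts)
    attr(r, "resolution") <- 5000L
    r
  }
  # bin inside a gene body
  a <- annotate_bins(mk(20000), genes)
  expect_identical(a$gene_id, "X")
  expect_equal(a$distance, 0)

  # bin [30000,35000): 5 kb from X's end, 27 kb from Y -> X
  b <- annotate_bins(mk(30000), genes)
  expect_identical(b$gene_id, "X")
  expect_equal(b$distance, 5000)

  # equidistant bin: X ends 25000, Y starts 62000; bin [41000+?]: choose a
  # bin whose edges are equidistant: bin start 41500 not multiple; use
  # midpoint bin [41000,46000): d(X) = 16000, d(Y) = 16000 -> tie -> X
  tie <- annotate_bins({
    r <- data.frame(chrom_a = "chrA", bin_a_start = 0, chrom_b = "chrB",
                    bin_b_start = 41000, count = 1)
    attr(r, "resolution") <- 5000L
    r
  }, genes)
  expect_identical(tie$gene_id, "X")

  # chromosome absent from annotation -> warning + unassigned bucket
  r2 <- data.frame(chrom_a = "chrA", bin_a_start = 0, chrom_b = "chrZZ",
                   bin_b_start = 0, count = 2)
  attr(r2, "resolution") <- 5000L
  expect_warning(u <- annotate_bins(r2, genes), "unassigned")
  expect_true(is.na(u$gene_id))
})

test_that("chromatin-state calls require the two-mark enhancer signature", {
  region <- genomic_interval("chr1", 1000, 2000)
  mk_track <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  expect_identical(
    classify_chromatin_state(region, list(H3K27ac = mk_track(0, 5000))),
    "none")
  expect_identical(
    classify_chromatin_state(region, list(H3K27ac = mk_track(0, 5000),
                                          H3K4me1 = mk_track(500, 1500))),
    "enhancer")
  expect_identical(
    classify_chromatin_state(region, list(H3K27ac = mk_track(0, 5000),
                                          H3K4me1 = mk_track(0, 5000),
                                          H3K4me3 = mk_track(1900, 2100))),
    "both")
  expect_identical(classify_chromatin_state(region, list()), "none")
})

test_that("the integration funnel matches set algebra and is monotone", {
  bins <- data.frame(chrom = "chrB", bin_start = c(0, 5000, 10000, 15000,
                                                   20000, 25000),
                     gene_id = c("g1", "g2", "g3", "g4", "g5", "g1"),
                     distance = 0, count = c(3, 1, 2, 5, 1, 2))
  de <- c("g1", "g3", "g5")
  corr <- c(g1 = 0.95, g2 = 0.99, g3 = 0.85, g4 = 0.9, g5 = 0.1)
  out <- integrate_contacts(bins, de, corr, 0.8)
  expect_identical(unname(out$funnel), c(5L, 3L, 2L))
  expect_identical(out$table$gene_id, c("g1", "g3"))  # sorted by r desc
  expect_identical(out$table$n_bins[1], 2L)
  expect_equal(out$table$max_contact_count[1], 3)

  empty <- integrate_contacts(bins[0, ], de, corr, 0.8)
  expect_identical(unname(empty$funnel), c(0L, 0L, 0L))

  set.seed(4)
  for (rep in 1:20) {
    ids <- paste0("g", 1:15)
    bb <- data.frame(chrom = "c", bin_start = seq(0, by = 5000, length = 30),
                     gene_id = sample(ids, 30, TRUE), distance = 0,
                     count = rpois(30, 2) + 1)
    dd <- sample(ids, sample(0:15, 1))
    cc <- setNames(runif(15, -1, 1), ids)
    f <- integrate_contacts(bb, dd, cc, runif(1, -1, 1))$funnel
    expect_true(f["n_contacted"] >= f["n_de"] &&
                f["n_de"] >= f["n_correlated"])
  }
})
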