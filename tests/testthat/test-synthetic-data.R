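test_that("genome generation is seeded, uniform, and seed-sensitive", {
  cfg <- world_config(seed = 1, chrom_sizes = c(chrA = 50000, chrB = 50000))
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))

  # different seeds disagree at well over 40% of positions (expected 75%)
  for (s in 1:5) {
    ga <- generate_genome(world_config(seed = s,
                                       chrom_sizes = c(chrA = 20000, chrB = 20000)))
    gb <- generate_genome(world_config(seed = s + 100,
                                       chrom_sizes = c(chrA = 20000, chrB = 20000)))
    da <- strsplit(as.character(ga[[1]]), "")[[1]]
    db <- strsplit(as.character(gb[[1]]), "")[[1]]
    expect_gt(mean(da != db), 0.4)
  }

  # binomial concentration: GC of a 1 Mb chromosome is 0.50 +- 0.01
  gbig <- generate_genome(world_config(seed = 3,
                                       chrom_sizes = c(chrA = 1000000,
                                                       chrB = 100000)))
  gc <- Biostrings::letterFrequency(gbig[[1]], "GC", as.prob = TRUE)
  expect_lt(abs(gc - 0.5), 0.01)

  expect_error(world_config(chrom_sizes = c(chrA = 5000, chrB = 50000)),
               ">= 10 kb")
})

test_that("annotation satisfies the planted-layout invariants", {
  for (s in c(2, 9)) {
    cfg <- small_world_config(seed = s)
    ann <- generate_annotation(NULL, cfg)
    genes <- ann$genes
    truth <- ann$truth

    elnc <- genes[genes$gene_id == truth$elncRNA_id, ]
    tgt <- genes[genes$gene_id == truth$target_id, ]
    expect_false(elnc$chrom == tgt$chrom)
    expect_identical(elnc$strand, "-")

    # interval sanity on every emitted gene and exon
    lens <- cfg$chrom_sizes
    for (df in list(genes, ann$exons)) {
      expect_true(all(df$start >= 0))
      expect_true(all(df$start < df$end))
      expect_true(all(df$end <= lens[df$chrom]))
    }

    # genes do not overlap within a chromosome
    for (cn in unique(genes$chrom)) {
      g <- genes[genes$chrom == cn, ]
      g <- g[order(g$start), ]
      if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    }

    # planted elncRNA has >= 3 exons; neighbors within 500 kb; enhancer
    # overlaps the elncRNA locus
    expect_gte(sum(ann$exons$gene_id == truth$elncRNA_id), 3)
    nbr <- genes[genes$gene_id %in% truth$neighbor_ids, ]
    expect_true(all(pmax(nbr$start - elnc$end, elnc$start - nbr$end) <= 5e5))
    enh <- truth$enhancer_region
    expect_true(enh$start < elnc$end && elnc$start < enh$end)
  }
})

test_that("planted pair converges to perfect correlation in the noise-free limit", {
  cfg <- small_world_config(seed = 5, planted_correlation = 1)
  ann <- generate_annotation(NULL, cfg)
  tc <- simulate_timecourse(ann, cfg)
  fc <- compute_log2fc(tc)
  expect_gt(cor(fc["ELNC1", ], fc["TARGET1", ]), 0.99)
  expect_error(world_config(planted_correlation = 1.2), "\\(-1, 1\\]")
})

test_that("contact matrix respects binning, sparsity and the planted signal", {
  cfg <- small_world_config(seed = 4)
  ann <- generate_annotation(NULL, cfg)
  rec <- simulate_contact_matrix(ann, ann$truth, cfg)
  expect_true(all(rec$bin_a_start %% 5000 == 0))
  expect_true(all(rec$bin_b_start %% 5000 == 0))
  expect_true(all(rec$count > 0 & rec$count == floor(rec$count)))

  # degenerate background: only enhancer x promoter bins carry counts
  cfg0 <- small_world_config(seed = 4, contact_background_rate = 0)
  rec0 <- simulate_contact_matrix(ann, ann$truth, cfg0)
  expect_gt(nrow(rec0), 0)
  enh <- ann$truth$enhancer_region
  prm <- ann$truth$promoter_region
  expect_true(all(rec0$bin_a_start < enh$end &
                  rec0$bin_a_start + 5000 > enh$start))
  expect_true(all(rec0$bin_b_start < prm$end &
                  rec0$bin_b_start + 5000 > prm$start))

  # enrichment 1: planted bins statistically indistinguishable from
  # background (Poisson two-sample rate test)
  cfg1 <- small_world_config(seed = 8, contact_enrichment = 1,
                             contact_background_rate = 1)
  rec1 <- simulate_contact_matrix(ann, ann$truth, cfg1)
  in_planted <- rec1$bin_a_start < enh$end &
    rec1$bin_a_start + 5000 > enh$start &
    rec1$bin_b_start < prm$end & rec1$bin_b_start + 5000 > prm$start
  n_enh_bins <- length(seq(floor(enh$start / 5000) * 5000, enh$end - 1, 5000))
  n_prm_bins <- 1
  n_bins_a <- floor(unname(cfg1$chrom_sizes[1]) / 5000)
  n_bins_b <- floor(unname(cfg1$chrom_sizes[2]) / 5000)
  n_planted_pairs <- n_enh_bins * n_prm_bins
  n_bg_pairs <- n_bins_a * n_bins_b - n_planted_pairs
  pt <- stats::poisson.test(c(sum(rec1$count[in_planted]),
                              sum(rec1$count[!in_planted])),
                            c(n_planted_pairs, n_bg_pairs))
  expect_gt(pt$p.value, 0.01)
})

test_that("4C read simulation is deterministic, conservative and in bounds", {
  cfg <- small_world_config(seed = 6)
  g <- generate_genome(cfg)
  ann <- generate_annotation(g, cfg)
  r1 <- simulate_fourc_reads(g, ann$truth, cfg)
  r2 <- simulate_fourc_reads(g, ann$truth, cfg)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), cfg$fourc_n_reads)
  lens <- setNames(Biostrings::width(g), names(g))
  expect_true(all(r1$start >= 0 & r1$end <= lens[r1$chrom]))
  expect_true(all(r1$end - r1$start == cfg$fourc_read_length))
})

test_that("chromatin tracks cover the planted enhancer and promoter", {
  cfg <- small_world_config(seed = 2)
  ann <- generate_annotation(NULL, cfg)
  tracks <- simulate_chromatin_tracks(ann$truth)
  expect_identical(classify_chromatin_state(ann$truth$enhancer_region, tracks),
                   "enhancer")
  expect_identical(classify_chromatin_state(ann$truth$promoter_region, tracks),
                   "promoter")
})

test_that("qPCR simulation recovers the planted curve exactly without noise", {
  sim <- simulate_qpcr(list(slope = -3.3219, noise_sd = 0), seed = 3)
  curve <- fit_standard_curve(sim$copies, sim$ct)
  expect_equal(curve$slope, -3.3219, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
})

test_that("FISH simulation honors the planted proximity fraction and ranges", {
  f0 <- simulate_fish(200, 0, seed = 1)
  d0 <- sqrt((f0$x1 - f0$x2)^2 + (f0$y1 - f0$y2)^2)
  expect_true(all(d0 >= 1))
  f1 <- simulate_fish(200, 1, seed = 1)
  d1 <- sqrt((f1$x1 - f1$x2)^2 + (f1$y1 - f1$y2)^2)
  expect_true(all(d1 < 1))
  expect_error(simulate_fish(100, 1.5), "\\[0, 1\\]")

  # range property over many seeds
  for (s in 1:100) {
    f <- simulate_fish(20, 0.3, seed = s)
    expect_true(all(is.finite(unlist(f[, c("x1", "y1", "x2", "y2")]))))
    expect_identical(nrow(f), 20L)
  }
})

test_that("generators are byte-identical across repeated runs at a fixed seed", {
  cfg <- small_world_config(seed = 12)
  ann1 <- generate_annotation(NULL, cfg)
  ann2 <- generate_annotation(NULL, cfg)
  expect_identical(ann1, ann2)
  tc1 <- simulate_timecourse(ann1, cfg)
  tc2 <- simulate_timecourse(ann2, cfg)
  expect_identical(tc1, tc2)
  expect_identical(simulate_contact_matrix(ann1, ann1$truth, cfg),
                   simulate_contact_matrix(ann2, ann2$truth, cfg))
  expect_identical(simulate_qpcr(seed = 9), simulate_qpcr(seed = 9))
  expect_identical(simulate_fish(50, 0.1, seed = 9),
                   simulate_fish(50, 0.1, seed = 9))
})
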