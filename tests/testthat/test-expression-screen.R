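make_tc <- function(ps, os, biotype = NULL, hours = NULL) {
  # ps/os: gene x timepoint matrices with shared rownames
  stopifnot(identical(dim(ps), dim(os)))
  if (is.null(hours)) hours <- seq_len(ncol(ps))
  arr <- array(0, dim = c(nrow(ps), 2, ncol(ps)),
               dimnames = list(rownames(ps), c("PS", "OS"), hours))
  arr[, 1, ] <- ps; arr[, 2, ] <- os
  if (is.null(biotype)) biotype <- rep("lncRNA", nrow(ps))
  timecourse_matrix(arr, biotype, hours)
}

test_that("log2FC follows the pseudocounted ratio and its identities", {
  ps <- matrix(40, 1, 3, dimnames = list("g1", NULL))
  os <- matrix(10, 1, 3)
  fc <- compute_log2fc(make_tc(ps, os), pseudocount = 1)
  expect_equal(unname(fc[1, ]), rep(log2(41 / 11), 3), tolerance = 1e-12)
  expect_equal(log2(41 / 11), 1.898, tolerance = 1e-3)

  # identical conditions give the all-zero profile
  fc0 <- compute_log2fc(make_tc(ps, ps))
  expect_true(all(fc0 == 0))

  # antisymmetry under condition swap
  set.seed(1)
  ps <- matrix(rpois(30, 50), 10, 3,
               dimnames = list(paste0("g", 1:10), NULL))
  os <- matrix(rpois(30, 50), 10, 3,
               dimnames = list(paste0("g", 1:10), NULL))
  expect_equal(compute_log2fc(make_tc(ps, os)),
               -compute_log2fc(make_tc(os, ps)))

  expect_error(compute_log2fc(make_tc(ps, os), pseudocount = 0), "> 0")
})

test_that("DE filters match brute-force enumeration and nest correctly", {
  fc <- rbind(A = c(0.1, 1.93), B = c(0.1, 0.2), C = c(-0.3, -1.5),
              D = c(2.5, 0.4))
  attr(fc, "timepoints_h") <- c(9, 24)
  expect_setequal(filter_de_endpoint(fc, 1.0), c("A", "C"))
  expect_setequal(filter_de_endpoint(fc, 1.0, direction = "up"), "A")
  expect_setequal(filter_de_endpoint(fc, 1.0, direction = "down"), "C")
  expect_setequal(filter_de_endpoint(fc, 0), c("A", "B", "C", "D"))
  # D exceeds the threshold only at the early timepoint
  expect_setequal(filter_de_any_timepoint(fc, 1.0), c("A", "C", "D"))

  # membership equals a brute-force check; endpoint set nested in any-set
  set.seed(2)
  for (rep in 1:20) {
    m <- matrix(rnorm(50, 0, 1.2), 10, 5,
                dimnames = list(paste0("g", 1:10), NULL))
    ep <- filter_de_endpoint(m, 1)
    any_t <- filter_de_any_timepoint(m, 1)
    expect_setequal(ep, rownames(m)[abs(m[, 5]) >= 1])
    expect_setequal(any_t,
                    rownames(m)[apply(m, 1, function(x) any(abs(x) >= 1))])
    expect_true(all(ep %in% any_t))
  }
})

test_that("correlation with the target behaves like Pearson's r", {
  fc <- rbind(tgt = c(1, 2, 3), anti = c(3, 2, 1), flat = c(1, 1, 1),
              scaled = c(10, 20, 30))
  r <- correlate_with_target(fc, "tgt")
  expect_equal(unname(r["tgt"]), 1)
  expect_equal(unname(r["anti"]), -1)
  expect_true(is.na(r["flat"]))        # zero variance flagged, not 0
  expect_equal(unname(r["scaled"]), 1) # affine invariance

  set.seed(3)
  m <- matrix(rnorm(40), 4, 10, dimnames = list(c("t", "a", "b", "c"), NULL))
  r1 <- correlate_with_target(m, "t")
  expect_equal(unname(r1["a"]), cor(m["a", ], m["t", ]))
  # invariance under affine rescaling of a profile
  m2 <- m; m2["a", ] <- 3 * m2["a", ] + 7
  expect_equal(correlate_with_target(m2, "t")[["a"]], r1[["a"]])

  expect_error(correlate_with_target(m, "absent"), "not present")
  expect_error(correlate_with_target(m[, 1:2], "t"), ">= 3 timepoints")
})

test_that("candidate ranking applies thresholds, keys and tie-breaks", {
  corr <- c(A = 0.85, B = 0.81, C = 0.9, D = 0.95, E = NA)
  endf <- c(A = 1.9, B = 1.9, C = 1.2, D = 0.5, E = 2.2)
  bio <- c(A = "lncRNA", B = "lncRNA", C = "lncRNA", D = "lncRNA",
           E = "lncRNA")
  tab <- rank_candidates(names(corr), corr, endf, min_correlation = 0.8,
                         biotype = bio)
  # brute-force expected order: by fc desc, then r desc (E dropped: NA r)
  expect_identical(tab$gene_id, c("A", "B", "C", "D"))
  expect_identical(tab$rank, 1:4)

  # strict threshold and biotype filter
  expect_identical(nrow(rank_candidates("A", c(A = 0.8), c(A = 2),
                                        biotype = c(A = "lncRNA"))), 0L)
  bio2 <- c(A = "coding", B = "lncRNA", C = "lncRNA", D = "lncRNA")
  tab2 <- rank_candidates(names(bio2), corr[1:4], endf[1:4], biotype = bio2)
  expect_false("A" %in% tab2$gene_id)

  # gene_id lexical tie-break when fc and r both tie
  corr3 <- c(Z = 0.9, M = 0.9)
  endf3 <- c(Z = 1.5, M = 1.5)
  tab3 <- rank_candidates(names(corr3), corr3, endf3,
                          biotype = c(Z = "lncRNA", M = "lncRNA"))
  expect_identical(tab3$gene_id, c("M", "Z"))

  expect_identical(nrow(rank_candidates(character(0), corr, endf,
                                        biotype = bio)), 0L)
})

test_that("timecourse TSV round-trips and rejects broken schemas", {
  cfg <- small_world_config(seed = 3)
  ann <- generate_annotation(NULL, cfg)
  tc <- simulate_timecourse(ann, cfg)
  path <- tempfile(fileext = ".tsv")
  write_timecourse_tsv(tc, path)
  tc2 <- read_timecourse_tsv(path)
  expect_equal(tc2$values[tc$gene_ids, , ], tc$values)
  expect_identical(tc2$timepoints_h, tc$timepoints_h)

  bad <- tempfile(fileext = ".tsv")
  writeLines("gene\tbiotype\tvalue\nx\tlncRNA\t3", bad)
  expect_error(read_timecourse_tsv(bad), "schema error")
})
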