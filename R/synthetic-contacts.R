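#' Simulate a sparse inter-chromosomal contact matrix
#'
#' Draws independent Poisson counts for every 5-kb bin pair between the first
#' two chromosomes. Bin pairs linking the planted enhancer region to the
#' target promoter have their rate multiplied by `contact_enrichment`; when
#' the background rate is exactly zero, the planted rate is
#' `contact_enrichment - 1` so an enrichment above 1 still leaves a visible
#' planted signal (and an enrichment of exactly 1 still means no signal
#' anywhere). Only non-zero counts are returned, the sparse triplet
#' convention of 5-kb inter-chromosomal matrix dumps.
#'
#' @param annotation A `world_annotation`.
#' @param truth Its `planted_truth` (defaults to `annotation$truth`).
#' @param config The [world_config()].
#' @return A `contact_records` data.frame with columns `chrom_a`,
#'   `bin_a_start`, `chrom_b`, `bin_b_start`, `count` and a `resolution`
#'   attribute.
#' @export
simulate_contact_matrix <- function(annotation, truth = annotation$truth,
                                    config) {
  validate_world_config(config)
  res <- config$resolution
  cs <- annotation$chrom_sizes
  chrA <- names(cs)[1]; chrB <- names(cs)[2]
  bins_a <- seq(0L, round_down(cs[[1]] - 1L, res), by = res)
  bins_b <- seq(0L, round_down(cs[[2]] - 1L, res), by = res)

  enh <- truth$enhancer_region
  prm <- truth$promoter_region
  enh_bins <- bins_a[overlaps_halfopen(bins_a, bins_a + res,
                                       enh$start, enh$end)]
  prm_bins <- bins_b[overlaps_halfopen(bins_b, bins_b + res,
                                       prm$start, prm$end)]

  lambda_bg <- config$contact_background_rate
  lambda_planted <- if (lambda_bg > 0) {
    lambda_bg * config$contact_enrichment
  } else {
    config$contact_enrichment - 1
  }

  grid <- expand.grid(bin_a = bins_a, bin_b = bins_b,
                      KEEP.OUT.ATTRS = FALSE)
  planted <- grid$bin_a %in% enh_bins & grid$bin_b %in% prm_bins
  rate <- ifelse(planted, lambda_planted, lambda_bg)
  counts <- with_seed(substream(config$seed, 5L), rpois(nrow(grid), rate))
  keep <- counts > 0
  out <- data.frame(chrom_a = chrA, bin_a_start = grid$bin_a[keep],
                    chrom_b = chrB, bin_b_start = grid$bin_b[keep],
                    count = counts[keep], stringsAsFactors = FALSE)
  attr(out, "resolution") <- res
  class(out) <- c("contact_records", "data.frame")
  out
}

#' Simulate mapped 4C reads
#'
#' Read start positions are drawn from a mixture of a uniform background over
#' the whole genome and an excess component uniform over the planted enhancer
#' region, with per-bp weight `contact_enrichment` inside the enhancer and 1
#' elsewhere — the read pile a 4C library with the target promoter as bait
#' would produce over this synthetic world. Reads have a fixed length and are
#' kept within chromosome bounds; exactly `fourc_n_reads` intervals are
#' returned.
#'
#' @inheritParams simulate_contact_matrix
#' @param genome A `DNAStringSet`; only lengths are used.
#' @return A BED-like data.frame `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
simulate_fourc_reads <- function(genome, truth, config) {
  validate_world_config(config)
  lens <- setNames(Biostrings::width(genome), names(genome))
  rl <- config$fourc_read_length
  n <- config$fourc_n_reads
  enh <- truth$enhancer_region
  enh_len <- enh$end - enh$start
  G <- sum(lens)
  w_excess <- enh_len * (config$contact_enrichment - 1)

  with_seed(substream(config$seed, 6L), {
    in_excess <- runif(n) < w_excess / (G + w_excess)
    chrom <- character(n); start <- integer(n)
    n_bg <- sum(!in_excess)
    if (n_bg > 0) {
      bg_chrom <- sample(names(lens), n_bg, replace = TRUE,
                         prob = lens / sum(lens))
      bg_start <- vapply(bg_chrom, function(cn) {
        as.integer(floor(runif(1, 0, lens[[cn]] - rl)))
      }, integer(1))
      chrom[!in_excess] <- bg_chrom
      start[!in_excess] <- bg_start
    }
    n_ex <- sum(in_excess)
    if (n_ex > 0) {
      lo <- enh$start
      hi <- min(enh$end, lens[[enh$chrom]] - rl)
      chrom[in_excess] <- enh$chrom
      start[in_excess] <- as.integer(floor(runif(n_ex, lo, hi)))
    }
    data.frame(chrom = chrom, start = start, end = start + rl,
               name = sprintf("read%06d", seq_len(n)), score = 0L,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}
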