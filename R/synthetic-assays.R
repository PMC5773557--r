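#' Simulate chromatin-mark peak tracks
#'
#' Emits peak intervals consistent with the planted regulatory architecture:
#' H3K27ac and H3K4me1 peaks covering the planted enhancer region (the
#' two-mark signature of an enhancer state) and an H3K4me3 peak covering the
#' target promoter. Purely deterministic given the truth.
#'
#' @param truth A `planted_truth`.
#' @return Named list of BED-like peak data.frames (`chrom`, `start`, `end`),
#'   one per mark, intervals sorted.
#' @export
simulate_chromatin_tracks <- function(truth) {
  enh <- truth$enhancer_region
  prm <- truth$promoter_region
  list(
    H3K27ac = data.frame(chrom = enh$chrom, start = enh$start, end = enh$end,
                         stringsAsFactors = FALSE),
    H3K4me1 = data.frame(chrom = enh$chrom,
                         start = max(0, enh$start - 2000),
                         end = enh$end + 2000, stringsAsFactors = FALSE),
    H3K4me3 = data.frame(chrom = prm$chrom,
                         start = max(0, prm$start - 1000),
                         end = prm$end + 1000, stringsAsFactors = FALSE))
}

#' Simulate a qPCR dilution series
#'
#' Generates Ct values for a serial dilution of a known standard following
#' `Ct = intercept + slope * log10(copies)` plus Gaussian noise — the
#' absolute-quantification standard-curve model (a slope of
#' -1/log10(2) = -3.3219 corresponds to a perfectly efficient reaction that
#' gains one cycle per two-fold dilution).
#'
#' @param curve_truth List with `slope`, `intercept` (Ct at one copy),
#'   `copies` (vector of input copy numbers, default a 10^9..10^3 series),
#'   `noise_sd` (Ct standard deviation) and `n_replicates`.
#' @param seed Integer seed.
#' @return Data frame `copies`, `replicate`, `ct`.
#' @export
simulate_qpcr <- function(curve_truth = list(), seed = 1L) {
  ct0 <- list(slope = -3.3219, intercept = 40, copies = 10^(9:3),
              noise_sd = 0.1, n_replicates = 3L)
  ct0[names(curve_truth)] <- curve_truth
  if (any(ct0$copies <= 0)) stop("copies must be > 0")
  with_seed(seed, {
    df <- expand.grid(copies = ct0$copies,
                      replicate = seq_len(ct0$n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
    df$ct <- ct0$intercept + ct0$slope * log10(df$copies) +
      rnorm(nrow(df), 0, ct0$noise_sd)
    df
  })
}

#' Simulate DNA-FISH probe-pair coordinates
#'
#' Each cell carries one centroid per probe in a 2D field (microns). With
#' probability `proximity_fraction` the two centroids are placed < 1 micron
#' apart (uniform in 0-0.85 um, leaving a margin below the scoring
#' threshold); otherwise they are 1.15-5 um apart.
#'
#' @param n_cells Number of cells.
#' @param proximity_fraction Planted fraction of proximal cells, in \[0, 1\].
#' @param seed Integer seed.
#' @return Data frame `cell`, `x1`, `y1`, `x2`, `y2` (micron coordinates).
#' @export
simulate_fish <- function(n_cells, proximity_fraction, seed = 1L) {
  if (proximity_fraction < 0 || proximity_fraction > 1) {
    stop("proximity_fraction must lie in [0, 1]")
  }
  if (n_cells < 1) stop("n_cells must be >= 1")
  with_seed(seed, {
    proximal <- runif(n_cells) < proximity_fraction
    d <- ifelse(proximal, runif(n_cells, 0, 0.85), runif(n_cells, 1.15, 5))
    theta <- runif(n_cells, 0, 2 * pi)
    x1 <- runif(n_cells, 0, 100); y1 <- runif(n_cells, 0, 100)
    data.frame(cell = seq_len(n_cells), x1 = x1, y1 = y1,
               x2 = x1 + d * cos(theta), y2 = y1 + d * sin(theta))
  })
}
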