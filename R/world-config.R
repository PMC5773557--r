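#' Configuration for a synthetic regulatory-genomics world
#'
#' Bundles every tunable of the synthetic-data generators: a small genome, a
#' gene annotation with one planted elncRNA/target pair on different
#' chromosomes, a two-condition (PS = pulsatile shear, OS = oscillatory shear)
#' time-course expression matrix, a sparse inter-chromosomal contact matrix
#' with planted enhancer-promoter enrichment, 4C reads drawn from that contact
#' profile, chromatin-mark peak tracks, qPCR dilution-series Cts and DNA-FISH
#' spot pairs.
#'
#' Defaults encode the study conditions the pipeline is designed around: ten
#' timepoints between 1 and 24 h, a planted pair whose expected endpoint
#' log2 fold change is 2 and whose expected temporal correlation is 0.85,
#' negative-binomial count noise, and an enhancer-promoter contact enrichment
#' several-fold above the Poisson background.
#'
#' @param seed Integer master seed; every generator derives its own substream
#'   from it so runs are reproducible.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp); at
#'   least two chromosomes, each >= 10 kb. The planted elncRNA lives on the
#'   first, the planted target gene on the second.
#' @param n_background_lncRNAs,n_coding_genes Numbers of background genes with
#'   exchangeable flat trajectories.
#' @param timepoints_h Strictly increasing hours, first >= 1, last = 24.
#' @param planted_endpoint_log2fc Expected PS/OS log2 fold change of the
#'   planted pair at the last timepoint.
#' @param planted_correlation Expected Pearson correlation of the planted
#'   pair's log2FC profiles, in (-1, 1].
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2) for background genes.
#' @param contact_background_rate Mean Poisson count per inter-chromosomal
#'   5-kb bin pair.
#' @param contact_enrichment Multiplier (>= 1) applied to bin pairs linking
#'   the planted enhancer region to the target promoter.
#' @param fourc_n_reads Number of 4C reads to draw.
#' @param fourc_read_length Fixed mapped-read length in bp.
#' @param proximity_fraction Fraction of FISH cells with probe centroids
#'   closer than 1 micron.
#' @param resolution Contact-matrix bin size in bp.
#' @return An object of class `world_config` (a validated list).
#' @export
#' @examples
#' cfg <- world_config(seed = 1)
#' cfg$timepoints_h
world_config <- function(seed = 1L,
                         chrom_sizes = c(chrA = 800000L, chrB = 600000L),
                         n_background_lncRNAs = 150L,
                         n_coding_genes = 50L,
                         timepoints_h = c(1, 2, 3, 4, 6, 9, 12, 16, 20, 24),
                         planted_endpoint_log2fc = 2.0,
                         planted_correlation = 0.85,
                         nb_dispersion = 0.05,
                         contact_background_rate = 0.2,
                         contact_enrichment = 8,
                         fourc_n_reads = 20000L,
                         fourc_read_length = 75L,
                         proximity_fraction = 0.10,
                         resolution = 5000L) {
  cfg <- list(seed = as.integer(seed),
              chrom_sizes = chrom_sizes,
              n_background_lncRNAs = as.integer(n_background_lncRNAs),
              n_coding_genes = as.integer(n_coding_genes),
              timepoints_h = as.numeric(timepoints_h),
              planted_endpoint_log2fc = planted_endpoint_log2fc,
              planted_correlation = planted_correlation,
              nb_dispersion = nb_dispersion,
              contact_background_rate = contact_background_rate,
              contact_enrichment = contact_enrichment,
              fourc_n_reads = as.integer(fourc_n_reads),
              fourc_read_length = as.integer(fourc_read_length),
              proximity_fraction = proximity_fraction,
              resolution = as.integer(resolution))
  class(cfg) <- "world_config"
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  stopifnot(is.list(cfg))
  cs <- cfg$chrom_sizes
  if (is.null(names(cs)) || any(!nzchar(names(cs)))) {
    stop("invalid config: chrom_sizes must be a named vector")
  }
  if (length(cs) < 2) {
    stop("invalid config: need >= 2 chromosomes so the planted elncRNA and ",
         "its target gene lie on distinct chromosomes")
  }
  if (any(cs < 10000)) {
    stop("invalid config: every chromosome must be >= 10 kb")
  }
  tp <- cfg$timepoints_h
  if (length(tp) < 3 || any(diff(tp) <= 0)) {
    stop("invalid config: timepoints_h must be strictly increasing")
  }
  if (tp[1] < 1 || tp[length(tp)] != 24) {
    stop("invalid config: timepoints_h must start >= 1 h and end at 24 h")
  }
  if (cfg$planted_correlation <= -1 || cfg$planted_correlation > 1) {
    stop("invalid config: planted_correlation must lie in (-1, 1]")
  }
  if (cfg$nb_dispersion <= 0) stop("invalid config: nb_dispersion must be > 0")
  if (cfg$contact_background_rate < 0) {
    stop("invalid config: contact_background_rate must be >= 0")
  }
  if (cfg$contact_enrichment < 1) {
    stop("invalid config: contact_enrichment must be >= 1")
  }
  if (cfg$proximity_fraction < 0 || cfg$proximity_fraction > 1) {
    stop("invalid config: proximity_fraction must lie in [0, 1]")
  }
  counts <- c(cfg$n_background_lncRNAs, cfg$n_coding_genes,
              cfg$fourc_n_reads, cfg$fourc_read_length)
  if (any(counts < 1)) stop("invalid config: all counts must be >= 1")
  if (cfg$resolution < 1) stop("invalid config: resolution must be >= 1")
  invisible(cfg)
}

#' @export
print.world_config <- function(x, ...) {
  cat("synthetic world config\n")
  cat("  seed:", x$seed, "\n")
  cat("  chromosomes:",
      paste(sprintf("%s (%d bp)", names(x$chrom_sizes), x$chrom_sizes),
            collapse = ", "), "\n")
  cat("  genes: 1 planted elncRNA + target + 2 neighbors + 2 TFs + 1",
      "suppressed +", x$n_background_lncRNAs, "background lncRNAs +",
      x$n_coding_genes, "background coding\n")
  cat("  timepoints (h):", paste(x$timepoints_h, collapse = ", "), "\n")
  cat(sprintf("  planted endpoint log2FC %.2f, correlation %.2f\n",
              x$planted_endpoint_log2fc, x$planted_correlation))
  invisible(x)
}
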