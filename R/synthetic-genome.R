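#' Generate a random genome
#'
#' Draws an i.i.d. uniform A/C/G/T sequence for every chromosome in the
#' configuration. Restriction sites and motif occurrences then arise at their
#' natural background frequency (a 4-bp site about every 256 bp) rather than
#' being force-planted.
#'
#' @param config A [world_config()].
#' @return A [Biostrings::DNAStringSet], one entry per chromosome.
#' @export
#' @examples
#' g <- generate_genome(world_config(seed = 1, chrom_sizes = c(chrA = 10000, chrB = 10000)))
#' Biostrings::width(g)
generate_genome <- function(config) {
  validate_world_config(config)
  with_seed(substream(config$seed, 1L), {
    seqs <- vapply(config$chrom_sizes, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(seqs)
  })
}

round_down <- function(x, unit) as.integer(floor(x / unit) * unit)
round_up <- function(x, unit) as.integer(ceiling(x / unit) * unit)

#' Generate a gene annotation with a planted elncRNA/target pair
#'
#' Lays out non-overlapping gene models over the configured chromosomes:
#'
#' * a planted multi-exon elncRNA on the minus strand of the first
#'   chromosome, flanked by two neighbor genes (one ~110 kb away, one
#'   ~321 kb at default sizes, both within 500 kb) that are *not*
#'   flow-responsive — mimicking an enhancer-embedded lncRNA whose neighbors
#'   are transcriptionally inert;
#' * a target gene on the second chromosome with a promoter region one
#'   contact-matrix bin wide at its TSS;
#' * two early-peaking TF-like coding genes and one suppressed
#'   inflammatory-like coding gene;
#' * background lncRNAs and coding genes scattered over the remaining space,
#'   excluding the enhancer neighborhood.
#'
#' @param genome A `DNAStringSet` from [generate_genome()], or `NULL`; only
#'   chromosome lengths are used and they must match `config$chrom_sizes`.
#' @param config A [world_config()].
#' @return A list of class `world_annotation` with elements `genes` (a
#'   data.frame of 0-based half-open gene models: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `biotype`, `role`), `exons` (data.frame `gene_id`,
#'   `chrom`, `start`, `end`, `strand`), and `truth` (a `planted_truth` list:
#'   planted ids, enhancer and promoter regions, true proximity fraction).
#' @export
generate_annotation <- function(genome, config) {
  validate_world_config(config)
  cs <- config$chrom_sizes
  if (!is.null(genome)) {
    w <- Biostrings::width(genome)
    if (!identical(as.integer(w), as.integer(unname(cs)))) {
      stop("genome lengths do not match config$chrom_sizes")
    }
  }
  res <- config$resolution
  chrA <- names(cs)[1]; chrB <- names(cs)[2]
  LA <- as.integer(cs[1]); LB <- as.integer(cs[2])
  if (LA < 100000 || LB < 100000) {
    stop("capacity error: planted layout needs the first two chromosomes ",
         "to be >= 100 kb")
  }

  nlen <- min(20000L, max(1000L, as.integer(LA * 0.025)))
  elnc_len <- min(3000L, max(300L, as.integer(LA * 0.004)))
  elnc_start <- round_down(LA * 0.225, res)
  elnc_end <- elnc_start + elnc_len
  n1_start <- as.integer(LA * 0.0625); n1_end <- n1_start + nlen
  n2_start <- as.integer(LA * 0.63); n2_end <- n2_start + nlen
  if (!(n1_end < elnc_start && elnc_end < n2_start && n2_end <= LA)) {
    stop("capacity error: cannot place elncRNA neighborhood on ", chrA)
  }

  enh_half <- min(25000L, round_down(LA * 0.03125, res))
  enhancer <- genomic_interval(chrA,
                               max(0L, elnc_start - enh_half),
                               min(LA, round_up(elnc_end, res) + enh_half))

  tlen <- min(20000L, max(1000L, as.integer(LB * 0.03)))
  t_start <- round_down(LB * 0.5, res); t_end <- t_start + tlen
  promoter <- genomic_interval(chrB, t_start, t_start + res)
  glen <- min(15000L, max(1000L, as.integer(LB * 0.025)))
  tf1_start <- as.integer(LB * 0.10); tf2_start <- as.integer(LB * 0.20)
  sup_start <- as.integer(LB * 0.75)
  placed_B <- c(tf1_start, tf1_start + glen, tf2_start, tf2_start + glen,
                t_start, t_end, sup_start, sup_start + glen)
  if (any(diff(placed_B) < 0) || sup_start + glen > LB) {
    stop("capacity error: cannot place target/TF/suppressed genes on ", chrB)
  }

  core <- rbind(
    data.frame(gene_id = "NBR_UP", chrom = chrA, start = n1_start,
               end = n1_end, strand = "+", biotype = "coding",
               role = "neighbor"),
    data.frame(gene_id = "ELNC1", chrom = chrA, start = elnc_start,
               end = elnc_end, strand = "-", biotype = "lncRNA",
               role = "elncRNA"),
    data.frame(gene_id = "NBR_DN", chrom = chrA, start = n2_start,
               end = n2_end, strand = "+", biotype = "coding",
               role = "neighbor"),
    data.frame(gene_id = "TF1", chrom = chrB, start = tf1_start,
               end = tf1_start + glen, strand = "+", biotype = "coding",
               role = "tf"),
    data.frame(gene_id = "TF2", chrom = chrB, start = tf2_start,
               end = tf2_start + glen, strand = "+", biotype = "coding",
               role = "tf"),
    data.frame(gene_id = "TARGET1", chrom = chrB, start = t_start,
               end = t_end, strand = "+", biotype = "coding",
               role = "target"),
    data.frame(gene_id = "SUPP1", chrom = chrB, start = sup_start,
               end = sup_start + glen, strand = "+", biotype = "coding",
               role = "suppressed"))

  # background genes fill the free space, keeping the enhancer neighborhood
  # and a margin around every core gene gene-free
  margin <- 1000L
  reserved <- list()
  reserved[[chrA]] <- rbind(
    data.frame(start = pmax(0L, core$start[core$chrom == chrA] - margin),
               end = pmin(LA, core$end[core$chrom == chrA] + margin)),
    data.frame(start = enhancer$start, end = enhancer$end))
  reserved[[chrB]] <-
    data.frame(start = pmax(0L, core$start[core$chrom == chrB] - margin),
               end = pmin(LB, core$end[core$chrom == chrB] + margin))
  for (nm in setdiff(names(cs), c(chrA, chrB))) {
    reserved[[nm]] <- data.frame(start = integer(0), end = integer(0))
  }

  n_bg <- config$n_background_lncRNAs + config$n_coding_genes
  bg <- with_seed(substream(config$seed, 2L), {
    place_background_genes(cs, reserved, n_bg)
  })
  if (nrow(bg) < n_bg) {
    stop("capacity error: could only place ", nrow(bg), " of ", n_bg,
         " background genes; enlarge the chromosomes")
  }
  biotype <- rep(c("lncRNA", "coding"),
                 c(config$n_background_lncRNAs, config$n_coding_genes))
  ids <- ifelse(biotype == "lncRNA",
                sprintf("LNC%03d", cumsum(biotype == "lncRNA")),
                sprintf("COD%03d", cumsum(biotype == "coding")))
  bg$gene_id <- ids
  bg$biotype <- biotype
  bg$role <- "background"
  genes <- rbind(core, bg[, names(core)])
  rownames(genes) <- NULL

  exons <- with_seed(substream(config$seed, 3L), make_exons(genes))

  truth <- list(
    elncRNA_id = "ELNC1", target_id = "TARGET1",
    neighbor_ids = c("NBR_UP", "NBR_DN"), tf_ids = c("TF1", "TF2"),
    suppressed_id = "SUPP1",
    enhancer_region = enhancer, promoter_region = promoter,
    true_proximity_fraction = config$proximity_fraction)
  class(truth) <- "planted_truth"

  ann <- list(genes = genes, exons = exons, truth = truth,
              chrom_sizes = cs, resolution = res)
  class(ann) <- "world_annotation"
  ann
}

merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], iv$end[i])
    } else {
      out_s <- c(out_s, iv$start[i]); out_e <- c(out_e, iv$end[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

# Sequentially tile the free space of each chromosome with genes of random
# length (1-5 kb) separated by random gaps, until the quota is reached.
place_background_genes <- function(chrom_sizes, reserved, n_bg) {
  out <- list()
  n_placed <- 0L
  for (nm in names(chrom_sizes)) {
    L <- as.integer(chrom_sizes[nm])
    res_iv <- merge_intervals(reserved[[nm]])
    # free gaps between reserved blocks
    bounds <- c(0L, as.vector(rbind(res_iv$start, res_iv$end)), L)
    free <- matrix(bounds, ncol = 2, byrow = TRUE)
    for (i in seq_len(nrow(free))) {
      pos <- free[i, 1]
      while (n_placed < n_bg) {
        gap <- as.integer(runif(1, 200, 2000))
        len <- as.integer(runif(1, 1000, 5000))
        if (pos + gap + len > free[i, 2]) break
        start <- pos + gap
        strand <- sample(c("+", "-"), 1)
        out[[length(out) + 1L]] <-
          data.frame(gene_id = NA_character_, chrom = nm, start = start,
                     end = start + len, strand = strand,
                     biotype = NA_character_, role = NA_character_)
        pos <- start + len
        n_placed <- n_placed + 1L
      }
      if (n_placed >= n_bg) break
    }
    if (n_placed >= n_bg) break
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), biotype = character(0),
                      role = character(0)))
  }
  do.call(rbind, out)
}

# Split each gene into exons separated by introns. The planted elncRNA gets
# four exons (its predominant mature transcript joins exons 1, 3 and 4);
# other genes get 1-3.
make_exons <- function(genes) {
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    k <- if (g$role == "elncRNA") 4L else sample(1:3, 1)
    len <- g$end - g$start
    if (len < 8 * k) k <- 1L
    if (k == 1L) {
      rows[[i]] <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                              start = g$start, end = g$end, strand = g$strand)
      next
    }
    # alternate exon/intron blocks of randomized relative size
    w <- runif(2 * k - 1, 0.5, 1.5)
    w <- floor(w / sum(w) * len)
    w[length(w)] <- len - sum(w[-length(w)])
    edges <- g$start + cumsum(c(0, w))
    exon_idx <- seq(1, 2 * k - 1, by = 2)
    rows[[i]] <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                            start = edges[exon_idx],
                            end = edges[exon_idx + 1], strand = g$strand)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.world_annotation <- function(x, ...) {
  cat("synthetic annotation:", nrow(x$genes), "genes on",
      length(x$chrom_sizes), "chromosomes\n")
  cat("  planted elncRNA:", x$truth$elncRNA_id, "at",
      sprintf("%s:%d-%d (-)", x$genes$chrom[x$genes$role == "elncRNA"],
              x$genes$start[x$genes$role == "elncRNA"],
              x$genes$end[x$genes$role == "elncRNA"]), "\n")
  cat("  planted target:", x$truth$target_id, "at",
      sprintf("%s:%d-%d", x$genes$chrom[x$genes$role == "target"],
              x$genes$start[x$genes$role == "target"],
              x$genes$end[x$genes$role == "target"]), "\n")
  invisible(x)
}
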