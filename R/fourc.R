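#' In-silico double digestion of a genome
#'
#' Applies two rounds of restriction digestion: the primary enzyme cuts the
#' whole chromosome at every site occurrence, then the secondary enzyme
#' subdivides each primary fragment at site occurrences *within* that
#' fragment (a secondary site straddling a primary cut no longer exists
#' after the first round and produces no cut). Recognition sequences are
#' IUPAC; each site carries a cut offset within the recognition sequence.
#' The shipped defaults are the two 4-bp cutters of a typical 4C protocol:
#' DpnII (`^GATC`, offset 0) and CviQI (`G^TAC`, offset 1). Palindromic
#' sites are matched on the forward strand only (both strands are
#' equivalent); non-palindromic sites are additionally matched on the
#' reverse strand with cut coordinates mapped back to the forward strand.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param site1,site2 Lists `list(seq = , offset = )`: primary and secondary
#'   recognition site and cut offset (`0 <= offset <= nchar(seq)`).
#' @return A `fragment_map` data.frame: `chrom`, `start`, `end`,
#'   `generation` (`"primary"` if both boundaries are chromosome ends or
#'   primary cuts, `"secondary"` if at least one boundary is a secondary
#'   cut). Fragments tile each chromosome exactly.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AAGATCAAGTACAA"))
#' digest_genome(g)  # fragments [0,2), [2,9), [9,14)
digest_genome <- function(genome,
                          site1 = list(seq = "GATC", offset = 0L),
                          site2 = list(seq = "GTAC", offset = 1L)) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  for (s in list(site1, site2)) {
    check_iupac(s$seq)
    if (s$offset < 0 || s$offset > nchar(s$seq)) {
      stop("cut offset must lie within the recognition site")
    }
  }
  if (length(genome) == 0) {
    return(empty_fragment_map())
  }
  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    L <- Biostrings::width(genome)[ci]
    seq <- genome[[ci]]
    cuts1 <- site_cuts(seq, site1, 0L)
    cuts1 <- cuts1[cuts1 > 0 & cuts1 < L]
    bounds1 <- c(0L, sort(unique(cuts1)), L)
    cuts2_all <- integer(0)
    for (k in seq_len(length(bounds1) - 1)) {
      fs <- bounds1[k]; fe <- bounds1[k + 1]
      sub <- Biostrings::subseq(seq, fs + 1L, fe)
      c2 <- site_cuts(sub, site2, fs)
      cuts2_all <- c(cuts2_all, c2[c2 > fs & c2 < fe])
    }
    all_cuts <- sort(unique(c(cuts1, cuts2_all)))
    bounds <- c(0L, all_cuts, L)
    start <- bounds[-length(bounds)]
    end <- bounds[-1]
    is_sec <- function(x) x %in% cuts2_all & !(x %in% cuts1)
    generation <- ifelse(is_sec(start) | is_sec(end), "secondary", "primary")
    out[[ci]] <- data.frame(chrom = chrom, start = start, end = end,
                            generation = generation, stringsAsFactors = FALSE)
  }
  fm <- do.call(rbind, out)
  rownames(fm) <- NULL
  class(fm) <- c("fragment_map", "data.frame")
  fm
}

empty_fragment_map <- function() {
  fm <- data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), generation = character(0))
  class(fm) <- c("fragment_map", "data.frame")
  fm
}

# 0-based cut coordinates of a site on a (sub)sequence whose first base has
# genomic coordinate `shift`.
site_cuts <- function(seq, site, shift) {
  pat <- Biostrings::DNAString(site$seq)
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, seq, fixed = FALSE))
  cuts <- (fwd - 1L) + site$offset + shift
  rc <- Biostrings::reverseComplement(pat)
  if (as.character(rc) != as.character(pat)) {
    rev <- Biostrings::start(Biostrings::matchPattern(rc, seq, fixed = FALSE))
    # a cut `offset` into the site on the minus strand sits at
    # (site length - offset) on the forward strand
    cuts <- c(cuts, (rev - 1L) + (nchar(site$seq) - site$offset) + shift)
  }
  sort(unique(as.integer(cuts)))
}

check_iupac <- function(s) {
  letters_ok <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  ch <- strsplit(toupper(s), "")[[1]]
  bad <- which(!ch %in% letters_ok)
  if (length(bad)) {
    stop("invalid IUPAC symbol '", ch[bad[1]], "' at position ", bad[1])
  }
  invisible(TRUE)
}

#' Assign mapped reads to fragments or fixed bins
#'
#' Each read is assigned to the single counting unit containing its 5' end
#' (the start for `+` reads, `end - 1` for `-` reads), so no read is counted
#' twice even when it straddles a boundary. Reads extending beyond the
#' chromosome end, or on chromosomes absent from the unit map, are rejected
#' and tallied in the `n_rejected` attribute with a warning.
#'
#' @param reads BED-like data.frame (`chrom`, `start`, `end`, optional
#'   `strand`).
#' @param units A `fragment_map` from [digest_genome()], or `NULL` to use
#'   fixed bins of `bin_size` over `chrom_sizes`.
#' @param bin_size Fixed bin width (used when `units` is `NULL`).
#' @param chrom_sizes Named lengths (required for fixed bins).
#' @return The unit data.frame with a `count` column; attributes `n_assigned`
#'   and `n_rejected`.
#' @export
count_reads <- function(reads, units = NULL, bin_size = NULL,
                        chrom_sizes = NULL) {
  if (is.null(units)) {
    if (is.null(bin_size) || is.null(chrom_sizes)) {
      stop("fixed-bin counting needs bin_size and chrom_sizes")
    }
    units <- do.call(rbind, lapply(names(chrom_sizes), function(nm) {
      s <- seq(0L, chrom_sizes[[nm]] - 1L, by = bin_size)
      data.frame(chrom = nm, start = s,
                 end = pmin(s + bin_size, chrom_sizes[[nm]]),
                 generation = "bin", stringsAsFactors = FALSE)
    }))
  }
  strand <- if ("strand" %in% names(reads)) reads$strand else "+"
  pos5 <- ifelse(strand == "-", reads$end - 1L, reads$start)
  units$count <- 0
  n_rej <- 0L
  for (nm in unique(reads$chrom)) {
    u <- units$chrom == nm
    sel <- reads$chrom == nm
    if (!any(u)) {
      n_rej <- n_rej + sum(sel)
      next
    }
    L <- max(units$end[u])
    p <- pos5[sel]
    in_bounds <- p >= 0 & p < L & reads$end[sel] <= L
    n_rej <- n_rej + sum(!in_bounds)
    p <- p[in_bounds]
    ustart <- units$start[u]
    idx <- findInterval(p, ustart)
    tab <- table(idx)
    counts_u <- units$count[u]
    counts_u[as.integer(names(tab))] <- counts_u[as.integer(names(tab))] +
      as.vector(tab)
    units$count[u] <- counts_u
  }
  if (n_rej > 0) {
    warning(n_rej, " read(s) rejected (out of bounds or unknown chromosome)")
  }
  attr(units, "n_assigned") <- nrow(reads) - n_rej
  attr(units, "n_rejected") <- n_rej
  units
}

#' Reads-per-million normalization of a 4C profile
#'
#' Scales raw per-unit counts by `1e6 / total_mapped`.
#'
#' @param counts Unit data.frame with a `count` column (from
#'   [count_reads()]).
#' @param total_mapped Total mapped reads in the sample (>= 1).
#' @param bait Optional bait interval recorded in the profile.
#' @return A `fourc_profile` list: `units` (with `count` and `rpm` columns),
#'   `bait`, `total_mapped`.
#' @export
normalize_profile <- function(counts, total_mapped, bait = NULL) {
  if (is.null(total_mapped) || total_mapped < 1) {
    stop("total_mapped must be >= 1")
  }
  if (sum(counts$count) > total_mapped) {
    stop("sum of raw counts exceeds total_mapped")
  }
  counts$rpm <- counts$count * 1e6 / total_mapped
  out <- list(units = counts, bait = bait, total_mapped = total_mapped)
  class(out) <- "fourc_profile"
  out
}

#' Bait-centric trans-interaction link table
#'
#' Sums normalized signal over the units overlapping each candidate region,
#' excluding all units on the bait chromosome (cis) by default. One link per
#' candidate, sorted by signal descending; zero-signal links are retained
#' unless `drop_zero = TRUE`. The output is circos-ready: bait coordinates,
#' candidate coordinates, value.
#'
#' @param profile A `fourc_profile` from [normalize_profile()].
#' @param bait Bait interval (defaults to the profile's).
#' @param candidate_regions Data frame of intervals with a `name` column.
#' @param drop_zero Drop zero-signal links.
#' @param exclude_cis Exclude bait-chromosome units (default TRUE).
#' @return Data frame `chrom_bait`, `start_bait`, `end_bait`, `chrom`,
#'   `start`, `end`, `name`, `value`, sorted by `value` descending.
#' @export
trans_links <- function(profile, bait = profile$bait, candidate_regions,
                        drop_zero = FALSE, exclude_cis = TRUE) {
  stopifnot(inherits(profile, "fourc_profile"))
  u <- profile$units
  if (exclude_cis && !is.null(bait)) {
    u <- u[u$chrom != bait$chrom, , drop = FALSE]
  }
  value <- vapply(seq_len(nrow(candidate_regions)), function(i) {
    cr <- candidate_regions[i, ]
    sel <- u$chrom == cr$chrom &
      overlaps_halfopen(u$start, u$end, cr$start, cr$end)
    sum(u$rpm[sel])
  }, numeric(1))
  out <- data.frame(
    chrom_bait = if (is.null(bait)) NA_character_ else bait$chrom,
    start_bait = if (is.null(bait)) NA_real_ else bait$start,
    end_bait = if (is.null(bait)) NA_real_ else bait$end,
    chrom = candidate_regions$chrom, start = candidate_regions$start,
    end = candidate_regions$end, name = candidate_regions$name,
    value = value, stringsAsFactors = FALSE)
  if (drop_zero) out <- out[out$value > 0, , drop = FALSE]
  out <- out[order(-out$value, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
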