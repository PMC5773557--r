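# Independent oracles used across the suite. Each re-derives the quantity it
# checks by a different route than the package implementation.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Waterman-Smith-Beyer local alignment: explicit maximization over all gap
# lengths (gap of length k costs open + (k-1)*ext). Equals the affine-gap
# optimum because the gap cost is concave.
sw_oracle_score <- function(a, b, submat, open, ext) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  S <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      cand <- max(0, S[i, j] + submat[ca[i], cb[j]])
      ks <- 1:i
      cand <- max(cand, max(S[i + 1 - ks, j + 1] - open - (ks - 1) * ext))
      ks <- 1:j
      cand <- max(cand, max(S[i + 1, j + 1 - ks] - open - (ks - 1) * ext))
      S[i + 1, j + 1] <- cand
      best <- max(best, cand)
    }
  }
  best
}

# Naive two-stage digestion: plain fixed-string scans with substring().
# Returns the full boundary set {0, cuts, L}.
digest_boundary_oracle <- function(seq, site1 = "GATC", off1 = 0,
                                   site2 = "GTAC", off2 = 1) {
  find_all <- function(s, pat) {
    k <- nchar(pat); n <- nchar(s)
    if (n < k) return(integer(0))
    i <- 1:(n - k + 1)
    i[substring(s, i, i + k - 1) == pat]
  }
  L <- nchar(seq)
  cuts1 <- find_all(seq, site1) - 1 + off1
  cuts1 <- cuts1[cuts1 > 0 & cuts1 < L]
  bounds1 <- c(0, sort(unique(cuts1)), L)
  cuts2 <- integer(0)
  for (k in seq_len(length(bounds1) - 1)) {
    fs <- bounds1[k]; fe <- bounds1[k + 1]
    c2 <- find_all(substring(seq, fs + 1, fe), site2) - 1 + off2 + fs
    cuts2 <- c(cuts2, c2[c2 > fs & c2 < fe])
  }
  sort(unique(c(0, cuts1, cuts2, L)))
}

# Brute-force sliding-window IUPAC scan on one strand; returns 0-based
# offsets of all (overlapping) occurrences.
iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

motif_scan_oracle <- function(seq, iupac) {
  ch <- strsplit(seq, "")[[1]]
  p <- strsplit(iupac, "")[[1]]
  k <- length(p); n <- length(ch)
  if (n < k) return(integer(0))
  valid <- rep(TRUE, n - k + 1)
  for (j in seq_len(k)) {
    valid <- valid & ch[j:(n - k + j)] %in% iupac_sets_oracle[[p[j]]]
  }
  which(valid) - 1L
}

# Brute-force O(n) overlap scan for contact records against a region.
contacts_region_oracle <- function(records, region, res) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    keep[i] <- r$chrom_a == region$chrom && r$count > 0 &&
      r$bin_a_start < region$end && region$start < r$bin_a_start + res
  }
  records[keep, , drop = FALSE]
}

# A default-condition world, optionally shrunk for cheap unit tests.
small_world_config <- function(seed, ...) {
  world_config(seed = seed, n_background_lncRNAs = 30, n_coding_genes = 10,
               fourc_n_reads = 4000, ...)
}
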