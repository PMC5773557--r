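IUPAC_SETS <- c(A = "A", C = "C", G = "G", T = "T",
                R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Compile an IUPAC consensus into a matcher
#'
#' Translates an IUPAC consensus (e.g. a TF-binding consensus) into a
#' regular-expression character-class pattern and returns a matcher function
#' reporting *all* (overlapping) occurrence start offsets, 0-based, on a
#' given uppercase sequence.
#'
#' @param iupac Consensus string over `ACGTRYSWKMBDHVN`, length >= 4.
#' @return A function `(sequence) -> integer vector of 0-based offsets`, with
#'   attributes `regex` and `length`.
#' @export
#' @examples
#' m <- iupac_to_matcher("RTAC")
#' m("AAGTACAA")  # matches GTAC at offset 2
iupac_to_matcher <- function(iupac) {
  iupac <- toupper(iupac)
  if (nchar(iupac) < 4) stop("motif must be >= 4 bases long")
  ch <- strsplit(iupac, "")[[1]]
  bad <- which(!ch %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC symbol '", ch[bad[1]], "' at position ", bad[1])
  }
  classes <- vapply(ch, function(x) {
    s <- IUPAC_SETS[[x]]
    if (nchar(s) == 1) s else paste0("[", s, "]")
  }, character(1))
  regex <- paste(classes, collapse = "")
  lookahead <- paste0("(?=", regex, ")")
  f <- function(sequence) {
    m <- gregexpr(lookahead, sequence, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  attr(f, "regex") <- regex
  attr(f, "length") <- nchar(iupac)
  f
}

reverse_complement_iupac <- function(iupac) {
  ch <- rev(strsplit(toupper(iupac), "")[[1]])
  paste(IUPAC_COMPLEMENT[ch], collapse = "")
}

#' Extract a strand-aware window around a gene's TSS
#'
#' For a `+` gene the window is `[TSS - upstream, TSS + downstream)` with
#' TSS = gene start; for a `-` gene it is `[TSS - downstream, TSS + upstream)`
#' with TSS = gene end. Windows are clipped to chromosome bounds (flagged via
#' the `clipped` attribute); a window entirely off the chromosome is an
#' error.
#'
#' @param gene One-row gene data.frame (`chrom`, `start`, `end`, `strand`).
#' @param upstream,downstream Extent in bp on the promoter-proximal sides.
#' @param genome A `DNAStringSet` holding the gene's chromosome.
#' @return A one-row interval data.frame with a `sequence` column (uppercase
#'   forward-strand letters) and a `clipped` attribute.
#' @export
extract_window <- function(gene, upstream, downstream, genome) {
  L <- Biostrings::width(genome)[match(gene$chrom, names(genome))]
  if (is.na(L)) stop("chromosome ", gene$chrom, " absent from genome")
  if (gene$strand == "-") {
    tss <- gene$end
    lo <- tss - downstream; hi <- tss + upstream
  } else {
    tss <- gene$start
    lo <- tss - upstream; hi <- tss + downstream
  }
  if (hi <= 0 || lo >= L) stop("window lies entirely off the chromosome")
  clipped <- lo < 0 || hi > L
  lo <- max(0, lo); hi <- min(L, hi)
  seq <- as.character(Biostrings::subseq(genome[[gene$chrom]], lo + 1, hi))
  out <- genomic_interval(gene$chrom, lo, hi, gene$strand)
  out$sequence <- toupper(seq)
  attr(out, "clipped") <- clipped
  out
}

#' Scan a window for motif occurrences on both strands
#'
#' Reports every (overlapping) occurrence of each pattern on the forward
#' strand, and — when `both_strands` — every occurrence of the reverse
#' complement, reported with strand `"-"`. Coordinates are translated back
#' to chromosome space and the matched sequence is stored in forward-strand
#' letters, so re-extracting `genome[start, end)` always reproduces it.
#'
#' @param window A window from [extract_window()] (interval + `sequence`), or
#'   any one-row data.frame with `chrom`, `start` and `sequence`.
#' @param patterns Named character vector of IUPAC consensi (names are motif
#'   names), or a data.frame with `name` and `iupac` columns.
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @return A `data.frame` of hits: `chrom`, `start`, `end`, `strand`,
#'   `match`, `motif`, sorted by position.
#' @export
scan_motifs <- function(window, patterns, both_strands = TRUE) {
  if (is.data.frame(patterns)) {
    patterns <- setNames(patterns$iupac, patterns$name)
  }
  seq <- window$sequence
  hits <- list()
  for (nm in names(patterns)) {
    pat <- patterns[[nm]]
    k <- nchar(pat)
    fwd <- iupac_to_matcher(pat)(seq)
    if (length(fwd)) {
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = window$chrom, start = window$start + fwd,
        end = window$start + fwd + k, strand = "+",
        match = substring(seq, fwd + 1, fwd + k), motif = nm,
        stringsAsFactors = FALSE)
    }
    if (both_strands) {
      rc <- reverse_complement_iupac(pat)
      rev <- iupac_to_matcher(rc)(seq)
      if (length(rev)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = window$chrom, start = window$start + rev,
          end = window$start + rev + k, strand = "-",
          match = substring(seq, rev + 1, rev + k), motif = nm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      match = character(0), motif = character(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$motif, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default KLF-style motif set
#'
#' CACCC-box / GC-box style consensus patterns of the Krueppel-like factor
#' family, shipped as editable placeholders: the exact curated consensus a
#' given TF database assigns to KLF2/KLF4 should be supplied by the user as
#' configuration when available.
#'
#' @return Named character vector of IUPAC consensi.
#' @export
default_klf_motifs <- function() {
  c(KLF_CACCC = "CCMCRCCCN", KLF_GC = "GGGGYGKGGC")
}

#' Read a motif configuration file (name TAB iupac)
#' @param path Two-column tab-separated text file.
#' @return Named character vector.
#' @export
read_motifs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "iupac"),
                          stringsAsFactors = FALSE)
  setNames(df$iupac, df$name)
}
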