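#' EDNAFULL-style nucleotide substitution matrix
#'
#' The standard DNA scoring used by EMBOSS alignment tools: +5 for a match,
#' -4 for a mismatch among A/C/G/T, with ambiguity rows scoring each code
#' pair by the rounded expected score over the base sets the codes denote
#' (so e.g. A vs R scores 1, any base vs N scores -2).
#'
#' @return A symmetric 15 x 15 numeric matrix over the IUPAC alphabet.
#' @export
ednafull <- function() {
  letters15 <- c("A", "T", "G", "C", "S", "W", "R", "Y", "K", "M",
                 "B", "V", "H", "D", "N")
  sets <- IUPAC_SETS[letters15]
  m <- matrix(0, 15, 15, dimnames = list(letters15, letters15))
  for (x in letters15) {
    for (y in letters15) {
      sx <- strsplit(sets[[x]], "")[[1]]
      sy <- strsplit(sets[[y]], "")[[1]]
      hits <- sum(outer(sx, sy, "=="))
      avg <- (hits * 5 + (length(sx) * length(sy) - hits) * -4) /
        (length(sx) * length(sy))
      # round half away from zero, matching the integer EDNAFULL entries
      m[x, y] <- sign(avg) * floor(abs(avg) + 0.5)
    }
  }
  m
}

#' Scoring scheme for local alignment
#'
#' @param submat Symmetric substitution matrix with single-letter dimnames
#'   (default [ednafull()]).
#' @param gap_open Penalty for the first column of a gap run (default 10).
#' @param gap_extend Penalty for each subsequent gap column (default 0.5).
#'   Must satisfy `gap_open >= gap_extend >= 0`.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(submat = ednafull(), gap_open = 10,
                           gap_extend = 0.5) {
  if (!isTRUE(all.equal(submat, t(submat)))) {
    stop("substitution matrix must be symmetric")
  }
  if (gap_open < gap_extend || gap_extend < 0) {
    stop("need gap_open >= gap_extend >= 0")
  }
  out <- list(submat = submat, gap_open = gap_open, gap_extend = gap_extend)
  class(out) <- "scoring_scheme"
  out
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment of two nucleotide sequences under an affine gap
#' model: the first column of a gap run costs `gap_open`, each subsequent
#' column `gap_extend`. Traceback ties are broken deterministically
#' (diagonal, then gap in the second sequence, then gap in the first); an
#' empty alignment (score 0) is returned when no positive-scoring column
#' exists.
#'
#' @param seq_a,seq_b Non-empty uppercase sequences over the alphabet of the
#'   scheme's substitution matrix (character scalars or `DNAString`s).
#' @param scheme A [scoring_scheme()].
#' @return An `alignment_result` list: `score`; 0-based half-open aligned
#'   spans `start_a`/`end_a`/`start_b`/`end_b`; `aligned_a`/`aligned_b`
#'   (alignment rows with `-` gaps); `n_identical`, `n_aligned_columns`,
#'   `n_match_columns`, `n_gaps`.
#' @export
#' @examples
#' smith_waterman("ACGT", "ACGT")$score  # 20
smith_waterman <- function(seq_a, seq_b, scheme = scoring_scheme()) {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  alphabet <- rownames(scheme$submat)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ia <- match(ca, alphabet); ib <- match(cb, alphabet)
  if (anyNA(ia)) {
    stop("unknown character '", ca[which(is.na(ia))[1]], "' at position ",
         which(is.na(ia))[1], " of seq_a")
  }
  if (anyNA(ib)) {
    stop("unknown character '", cb[which(is.na(ib))[1]], "' at position ",
         which(is.na(ib))[1], " of seq_b")
  }
  raw <- .sw_align(ia - 1L, ib - 1L, scheme$submat,
                   scheme$gap_open, scheme$gap_extend)
  cols_a <- strsplit(raw$col_a, "")[[1]]
  cols_b <- strsplit(raw$col_b, "")[[1]]
  # fill residue letters into the M/- column encoding
  aligned_a <- cols_a; aligned_b <- cols_b
  if (length(cols_a)) {
    aligned_a[cols_a == "M"] <- ca[seq(raw$start_a + 1L, raw$end_a)]
    aligned_b[cols_b == "M"] <- cb[seq(raw$start_b + 1L, raw$end_b)]
  }
  is_pair <- aligned_a != "-" & aligned_b != "-"
  out <- list(score = raw$score,
              start_a = raw$start_a, end_a = raw$end_a,
              start_b = raw$start_b, end_b = raw$end_b,
              aligned_a = paste(aligned_a, collapse = ""),
              aligned_b = paste(aligned_b, collapse = ""),
              n_identical = sum(is_pair & aligned_a == aligned_b),
              n_aligned_columns = length(aligned_a),
              n_match_columns = sum(is_pair),
              n_gaps = sum(!is_pair))
  class(out) <- "alignment_result"
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("local alignment: score %.1f, %d columns (%d identical, %d gaps)\n",
              x$score, x$n_aligned_columns, x$n_identical, x$n_gaps))
  cat(sprintf("  a: [%d,%d) %s\n", x$start_a, x$end_a, x$aligned_a))
  cat(sprintf("  b: [%d,%d) %s\n", x$start_b, x$end_b, x$aligned_b))
  invisible(x)
}

#' Recompute an alignment score from its column list
#'
#' Independent of the DP: walks the aligned columns, summing substitution
#' scores for paired columns and charging `gap_open` for the first column of
#' each gap run and `gap_extend` for each subsequent one. Used to verify
#' that a reported score is self-consistent.
#'
#' @param result An `alignment_result`.
#' @param scheme The [scoring_scheme()] used to produce it.
#' @return The recomputed score.
#' @export
rescore_alignment <- function(result, scheme = scoring_scheme()) {
  a <- strsplit(result$aligned_a, "")[[1]]
  b <- strsplit(result$aligned_b, "")[[1]]
  score <- 0
  gap_a <- FALSE; gap_b <- FALSE  # a gap run is consecutive gaps in the SAME row
  for (k in seq_along(a)) {
    if (a[k] == "-") {
      score <- score - if (gap_a) scheme$gap_extend else scheme$gap_open
      gap_a <- TRUE; gap_b <- FALSE
    } else if (b[k] == "-") {
      score <- score - if (gap_b) scheme$gap_extend else scheme$gap_open
      gap_b <- TRUE; gap_a <- FALSE
    } else {
      score <- score + scheme$submat[a[k], b[k]]
      gap_a <- FALSE; gap_b <- FALSE
    }
  }
  score
}

#' Identity summary of an alignment
#'
#' Reports identical positions and aligned columns, with the identity
#' fraction under both denominator conventions (alignment columns, and the
#' shorter input sequence) since "x out of y aligned" claims are read either
#' way in practice.
#'
#' @param result An `alignment_result`.
#' @param len_a,len_b Input sequence lengths (for the shorter-sequence
#'   denominator; optional).
#' @return List `n_identical`, `n_aligned_columns`, `fraction_columns`,
#'   `fraction_shorter` (NA when lengths are not supplied).
#' @export
identity_report <- function(result, len_a = NULL, len_b = NULL) {
  frac_short <- if (is.null(len_a) || is.null(len_b)) {
    NA_real_
  } else {
    result$n_identical / min(len_a, len_b)
  }
  list(n_identical = result$n_identical,
       n_aligned_columns = result$n_aligned_columns,
       fraction_columns = result$n_identical / result$n_aligned_columns,
       fraction_shorter = frac_short)
}
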