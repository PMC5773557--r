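#' Per-timepoint log2 fold changes
#'
#' For every gene, `log2((treatment + pc) / (control + pc))` at each
#' timepoint, with the first condition of the matrix as treatment. The
#' pseudocount guards against zeros; with it, swapping the two conditions
#' exactly negates every profile.
#'
#' @param tc A [timecourse_matrix()].
#' @param pseudocount Positive real added to both conditions (default 1).
#' @return Numeric matrix, genes x timepoints, with gene ids as rownames and
#'   the timepoint grid as a `timepoints_h` attribute.
#' @export
#' @examples
#' v <- array(c(40, 10), c(1, 2, 3), dimnames = list("g1", c("PS", "OS"), c(1, 9, 24)))
#' compute_log2fc(timecourse_matrix(v, "coding"))  # log2(41/11) everywhere
compute_log2fc <- function(tc, pseudocount = 1) {
  stopifnot(inherits(tc, "timecourse"))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  fc <- log2((tc$values[, 1, , drop = TRUE] + pseudocount) /
             (tc$values[, 2, , drop = TRUE] + pseudocount))
  fc <- matrix(fc, nrow = length(tc$gene_ids),
               dimnames = list(tc$gene_ids, tc$timepoints_h))
  if (any(!is.finite(fc))) stop("non-finite log2FC encountered")
  attr(fc, "timepoints_h") <- tc$timepoints_h
  fc
}

#' Endpoint differential-expression filter
#'
#' Keeps genes whose absolute log2FC at the last timepoint meets the
#' threshold, optionally restricted by direction.
#'
#' @param fc A log2FC matrix from [compute_log2fc()].
#' @param min_abs_log2fc Threshold (>= 0).
#' @param direction `"both"` (default), `"up"` or `"down"`.
#' @return Character vector of gene ids.
#' @export
filter_de_endpoint <- function(fc, min_abs_log2fc = 1,
                               direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (nrow(fc) == 0) return(character(0))
  endpoint <- fc[, ncol(fc)]
  pass <- switch(direction,
                 both = abs(endpoint) >= min_abs_log2fc,
                 up = endpoint >= min_abs_log2fc,
                 down = endpoint <= -min_abs_log2fc)
  rownames(fc)[pass]
}

#' Any-timepoint differential-expression filter
#'
#' Keeps genes whose absolute log2FC meets the threshold at *any* timepoint;
#' always a superset of [filter_de_endpoint()] at the same threshold.
#'
#' @inheritParams filter_de_endpoint
#' @return Character vector of gene ids.
#' @export
filter_de_any_timepoint <- function(fc, min_abs_log2fc = 1) {
  if (nrow(fc) == 0) return(character(0))
  rownames(fc)[apply(abs(fc) >= min_abs_log2fc, 1, any)]
}

#' Temporal correlation with a designated target gene
#'
#' Correlates each gene's log2FC profile with the target gene's profile over
#' the whole time course. Zero-variance profiles have no defined correlation
#' and are returned as `NA` (they are excluded from ranking rather than
#' silently treated as 0).
#'
#' @inheritParams filter_de_endpoint
#' @param target_gene_id Gene id present in `fc`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Named numeric vector of correlations in \[-1, 1\] (or `NA`).
#' @export
correlate_with_target <- function(fc, target_gene_id,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!target_gene_id %in% rownames(fc)) {
    stop("target gene ", target_gene_id, " not present")
  }
  if (ncol(fc) < 3) stop("need >= 3 timepoints for a temporal correlation")
  tgt <- fc[target_gene_id, ]
  if (stats::sd(tgt) == 0) {
    stop("target profile has zero variance; correlation undefined")
  }
  sds <- apply(fc, 1, stats::sd)
  r <- rep(NA_real_, nrow(fc))
  names(r) <- rownames(fc)
  ok <- sds > 0
  if (any(ok)) {
    r[ok] <- suppressWarnings(
      as.vector(stats::cor(t(fc[ok, , drop = FALSE]), tgt, method = method)))
  }
  r
}

#' Rank lncRNA candidates from the screen
#'
#' Intersects the differentially expressed set with the genes whose
#' correlation with the target exceeds `min_correlation` (strict), restricted
#' to the requested biotype, and ranks the survivors primarily by endpoint
#' log2FC descending, ties broken by correlation descending and then by gene
#' id.
#'
#' @param de_set Character vector of gene ids passing the DE filter.
#' @param correlations Named vector from [correlate_with_target()].
#' @param endpoint_fc Named numeric vector of endpoint log2FC per gene.
#' @param min_correlation Threshold in \[-1, 1\] (default 0.8).
#' @param biotype Named biotype vector; `biotype_filter` selects which class
#'   is eligible (default lncRNA; use `NULL` to keep all genes).
#' @param biotype_filter `"lncRNA"`, `"coding"`, or `NULL`.
#' @return A `data.frame` (`gene_id`, `endpoint_log2fc`,
#'   `correlation_with_target`, `rank`) sorted by rank.
#' @export
rank_candidates <- function(de_set, correlations, endpoint_fc,
                            min_correlation = 0.8, biotype = NULL,
                            biotype_filter = "lncRNA") {
  if (min_correlation < -1 || min_correlation > 1) {
    stop("min_correlation must lie in [-1, 1]")
  }
  ids <- de_set
  if (!is.null(biotype_filter) && !is.null(biotype)) {
    ids <- ids[biotype[ids] %in% biotype_filter]
  }
  r <- correlations[ids]
  ids <- ids[!is.na(r) & r > min_correlation]
  if (length(ids) == 0) {
    return(data.frame(gene_id = character(0), endpoint_log2fc = numeric(0),
                      correlation_with_target = numeric(0),
                      rank = integer(0)))
  }
  out <- data.frame(gene_id = ids,
                    endpoint_log2fc = unname(endpoint_fc[ids]),
                    correlation_with_target = unname(correlations[ids]),
                    stringsAsFactors = FALSE)
  ord <- order(-out$endpoint_log2fc, -out$correlation_with_target,
               out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full expression screen
#'
#' Convenience wrapper: log2FC profiles, endpoint DE filter, correlation with
#' the target, candidate ranking.
#'
#' @param tc A [timecourse_matrix()].
#' @param target_gene_id The designated target gene (correlation anchor).
#' @param min_abs_log2fc Endpoint DE threshold (default 1).
#' @param min_correlation Correlation threshold (default 0.8, strict).
#' @param pseudocount Passed to [compute_log2fc()].
#' @param method Correlation method.
#' @return List with `log2fc` (matrix), `de_set`, `correlations`, and
#'   `candidates` (the ranked table).
#' @export
screen_candidates <- function(tc, target_gene_id, min_abs_log2fc = 1,
                              min_correlation = 0.8, pseudocount = 1,
                              method = "pearson") {
  fc <- compute_log2fc(tc, pseudocount)
  de <- filter_de_endpoint(fc, min_abs_log2fc)
  r <- correlate_with_target(fc, target_gene_id, method)
  endpoint <- fc[, ncol(fc)]
  cand <- rank_candidates(de, r, endpoint, min_correlation,
                          biotype = tc$biotype)
  list(log2fc = fc, de_set = de, correlations = r, candidates = cand)
}

#' Write a candidate table as TSV
#' @param candidates Ranked candidate data.frame.
#' @param path Output file.
#' @export
write_candidates_tsv <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
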