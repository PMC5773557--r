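#' Construct a time-course expression matrix
#'
#' Container for per-gene expression across exactly two conditions (treatment
#' first, control second; default PS and OS) on a shared timepoint grid.
#'
#' @param values Numeric array `gene x condition x timepoint`, all values
#'   >= 0, with dimnames for genes and conditions.
#' @param biotype Character vector (`"lncRNA"` or `"coding"`) per gene.
#' @param timepoints_h Numeric vector of hours matching the third dimension.
#' @return An object of class `timecourse`.
#' @export
timecourse_matrix <- function(values, biotype,
                              timepoints_h = as.numeric(dimnames(values)[[3]])) {
  stopifnot(length(dim(values)) == 3, dim(values)[2] == 2)
  if (any(values < 0)) stop("expression values must be >= 0")
  gene_ids <- dimnames(values)[[1]]
  if (is.null(gene_ids) || anyDuplicated(gene_ids)) {
    stop("values must carry unique gene ids as rownames")
  }
  if (length(biotype) != length(gene_ids)) {
    stop("biotype must have one entry per gene")
  }
  if (length(timepoints_h) != dim(values)[3]) {
    stop("timepoints_h must match the third dimension of values")
  }
  obj <- list(values = values, gene_ids = gene_ids,
              biotype = setNames(as.character(biotype), gene_ids),
              conditions = dimnames(values)[[2]],
              timepoints_h = as.numeric(timepoints_h))
  class(obj) <- "timecourse"
  obj
}

#' @export
print.timecourse <- function(x, ...) {
  cat("timecourse:", length(x$gene_ids), "genes x",
      paste(x$conditions, collapse = "/"), "x",
      length(x$timepoints_h), "timepoints (",
      paste(x$timepoints_h, collapse = ", "), "h )\n")
  invisible(x)
}

#' Read/write a time-course matrix as long-format TSV
#'
#' The on-disk layout is one row per (gene, condition, timepoint) with columns
#' `gene`, `biotype`, `condition`, `timepoint`, `value`.
#'
#' @param path File path.
#' @param treatment,control Condition labels; `treatment` is the numerator of
#'   downstream fold changes.
#' @return For the reader, a [timecourse_matrix()]; the writer returns `path`
#'   invisibly.
#' @export
read_timecourse_tsv <- function(path, treatment = "PS", control = "OS") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "biotype", "condition", "timepoint", "value")
  if (!all(need %in% names(df))) {
    stop("schema error: expected columns ", paste(need, collapse = ", "))
  }
  conds <- c(treatment, control)
  if (!all(conds %in% df$condition)) {
    stop("schema error: conditions ", paste(conds, collapse = ", "),
         " not both present")
  }
  genes <- unique(df$gene)
  tps <- sort(unique(df$timepoint))
  arr <- array(NA_real_, dim = c(length(genes), 2, length(tps)),
               dimnames = list(genes, conds, tps))
  idx <- cbind(match(df$gene, genes), match(df$condition, conds),
               match(df$timepoint, tps))
  keep <- !is.na(idx[, 2])
  arr[idx[keep, , drop = FALSE]] <- df$value[keep]
  if (anyNA(arr)) {
    stop("schema error: missing (gene, condition, timepoint) combinations")
  }
  biotype <- df$biotype[match(genes, df$gene)]
  timecourse_matrix(arr, biotype, tps)
}

#' @rdname read_timecourse_tsv
#' @param tc A `timecourse` object.
#' @export
write_timecourse_tsv <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  long <- expand.grid(gene = tc$gene_ids, condition = tc$conditions,
                      timepoint = tc$timepoints_h, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  long$biotype <- tc$biotype[long$gene]
  long$value <- as.vector(tc$values)
  long <- long[, c("gene", "biotype", "condition", "timepoint", "value")]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
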