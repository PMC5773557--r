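#' Read a sparse contact-matrix triplet dump
#'
#' Parses the 3-column whitespace-separated text dialect used for 5-kb
#' inter-chromosomal matrix dumps: `bin_a_start  bin_b_start  count`, one
#' file per chromosome pair, coordinates in bp, no header. In strict mode
#' (default) any malformed line is a parse error naming the line number; with
#' `lenient = TRUE` such lines (e.g. a stray header) are skipped with a
#' warning.
#'
#' @param path Path to the triplet file.
#' @param chrom_a,chrom_b Chromosome names of the A (row) and B (column)
#'   side of this file.
#' @param resolution Bin size in bp (default 5000).
#' @param lenient Skip malformed lines instead of failing.
#' @return A `contact_records` data.frame (`chrom_a`, `bin_a_start`,
#'   `chrom_b`, `bin_b_start`, `count`) with a `resolution` attribute.
#' @export
read_contacts <- function(path, chrom_a, chrom_b, resolution = 5000L,
                          lenient = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- data.frame(chrom_a = character(0), bin_a_start = numeric(0),
                      chrom_b = character(0), bin_b_start = numeric(0),
                      count = numeric(0), stringsAsFactors = FALSE)
    attr(out, "resolution") <- as.integer(resolution)
    class(out) <- c("contact_records", "data.frame")
    return(out)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_fields <- lengths(fields)
  m <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(fields, `[`, 1:3))), ncol = 3,
           byrow = TRUE))
  bad <- n_fields != 3 | rowSums(is.na(m)) > 0 | m[, 3] < 0 |
    m[, 1] < 0 | m[, 2] < 0
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    if (!lenient) {
      stop("parse error in ", path, " at line ", which(bad)[1], ": '",
           lines[which(bad)[1]], "'")
    }
    warning("skipped ", sum(bad), " malformed line(s) in ", path)
    m <- m[!bad, , drop = FALSE]
  }
  out <- data.frame(chrom_a = chrom_a, bin_a_start = m[, 1],
                    chrom_b = chrom_b, bin_b_start = m[, 2], count = m[, 3],
                    stringsAsFactors = FALSE)
  attr(out, "resolution") <- as.integer(resolution)
  class(out) <- c("contact_records", "data.frame")
  out
}

#' Write contact records as a triplet dump
#' @param records A `contact_records` data.frame.
#' @param path Output file (`<chrA>_<chrB>.txt` by convention).
#' @export
write_contacts <- function(records, path) {
  utils::write.table(records[, c("bin_a_start", "bin_b_start", "count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Contacts touching a query region
#'
#' Selects records with positive count whose A-side bin
#' `[bin_a_start, bin_a_start + resolution)` overlaps the half-open query
#' region. With `symmetric = TRUE`, records whose B-side bin overlaps the
#' region are also returned (with A and B sides swapped so the query side is
#' always side A).
#'
#' @param records A `contact_records` data.frame.
#' @param region A one-row interval data.frame (see [genomic_interval()]).
#' @param symmetric Also match the B side.
#' @return The matching subset of `records`.
#' @export
contacts_for_region <- function(records, region, symmetric = FALSE) {
  res <- attr(records, "resolution")
  if (is.null(res)) stop("records lack a resolution attribute")
  hit_a <- records$chrom_a == region$chrom & records$count > 0 &
    overlaps_halfopen(records$bin_a_start, records$bin_a_start + res,
                      region$start, region$end)
  out <- records[hit_a, , drop = FALSE]
  if (symmetric) {
    hit_b <- records$chrom_b == region$chrom & records$count > 0 &
      overlaps_halfopen(records$bin_b_start, records$bin_b_start + res,
                        region$start, region$end)
    swapped <- records[hit_b, , drop = FALSE]
    if (nrow(swapped)) {
      swapped <- data.frame(chrom_a = swapped$chrom_b,
                            bin_a_start = swapped$bin_b_start,
                            chrom_b = swapped$chrom_a,
                            bin_b_start = swapped$bin_a_start,
                            count = swapped$count, stringsAsFactors = FALSE)
      out <- rbind(out, swapped)
    }
  }
  attr(out, "resolution") <- res
  class(out) <- c("contact_records", "data.frame")
  out
}

#' Annotate contacted bins by overlapping-else-closest gene
#'
#' Every distinct B-side bin is assigned to each gene it overlaps; a bin that
#' overlaps no gene is assigned to the single nearest gene by genomic
#' distance (bin edge to gene edge), ties broken deterministically toward the
#' gene with the smaller start coordinate. Bins on chromosomes absent from
#' the annotation go to an unassigned bucket (`gene_id = NA`) with a warning.
#'
#' @param records A `contact_records` data.frame.
#' @param annotation A `world_annotation`, or a genes data.frame (`gene_id`,
#'   `chrom`, `start`, `end`).
#' @return Data frame with one row per (bin, assigned gene): `chrom`,
#'   `bin_start`, `gene_id`, `distance` (0 for overlaps), `count` (max count
#'   observed for that bin).
#' @export
annotate_bins <- function(records, annotation) {
  genes <- if (inherits(annotation, "world_annotation")) {
    annotation$genes
  } else {
    annotation
  }
  res <- attr(records, "resolution")
  if (is.null(res)) stop("records lack a resolution attribute")
  key <- paste(records$chrom_b, records$bin_b_start)
  agg <- tapply(records$count, key, max)
  bins <- data.frame(chrom = sub(" .*", "", names(agg)),
                     bin_start = as.numeric(sub(".* ", "", names(agg))),
                     count = as.numeric(agg), stringsAsFactors = FALSE)
  out <- vector("list", nrow(bins))
  missing_chrom <- FALSE
  for (i in seq_len(nrow(bins))) {
    b <- bins[i, ]
    g <- genes[genes$chrom == b$chrom, , drop = FALSE]
    if (nrow(g) == 0) {
      missing_chrom <- TRUE
      out[[i]] <- data.frame(chrom = b$chrom, bin_start = b$bin_start,
                             gene_id = NA_character_, distance = NA_real_,
                             count = b$count, stringsAsFactors = FALSE)
      next
    }
    b_end <- b$bin_start + res
    ov <- overlaps_halfopen(g$start, g$end, b$bin_start, b_end)
    if (any(ov)) {
      out[[i]] <- data.frame(chrom = b$chrom, bin_start = b$bin_start,
                             gene_id = g$gene_id[ov], distance = 0,
                             count = b$count, stringsAsFactors = FALSE)
    } else {
      d <- pmax(g$start - b_end, b$bin_start - g$end)
      best <- which(d == min(d))
      if (length(best) > 1) best <- best[which.min(g$start[best])]
      out[[i]] <- data.frame(chrom = b$chrom, bin_start = b$bin_start,
                             gene_id = g$gene_id[best], distance = min(d),
                             count = b$count, stringsAsFactors = FALSE)
    }
  }
  if (missing_chrom) {
    warning("some contacted bins lie on chromosomes absent from the ",
            "annotation; left unassigned")
  }
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}

#' Classify the chromatin state of a region
#'
#' A region is in an enhancer state iff it overlaps *both* an H3K27ac and an
#' H3K4me1 peak; it is in a promoter state iff it overlaps an H3K4me3 peak.
#'
#' @param region One-row interval data.frame.
#' @param tracks Named list of peak data.frames (`chrom`, `start`, `end`);
#'   names are mark names. Missing marks count as no overlap.
#' @return One of `"enhancer"`, `"promoter"`, `"both"`, `"none"`.
#' @export
classify_chromatin_state <- function(region, tracks) {
  hits_mark <- function(mark) {
    pk <- tracks[[mark]]
    if (is.null(pk) || nrow(pk) == 0) return(FALSE)
    any(pk$chrom == region$chrom &
          overlaps_halfopen(pk$start, pk$end, region$start, region$end))
  }
  enh <- hits_mark("H3K27ac") && hits_mark("H3K4me1")
  prm <- hits_mark("H3K4me3")
  if (enh && prm) "both" else if (enh) "enhancer" else if (prm) "promoter" else "none"
}

#' Integrate contacts with the expression screen
#'
#' The staged prioritization funnel: genes contacted by the query region,
#' the subset differentially expressed at any timepoint, and the subset
#' highly correlated with the anchor gene. Funnel counts are monotone
#' non-increasing by construction.
#'
#' @param bin_annotation Output of [annotate_bins()].
#' @param de_set Character vector from [filter_de_any_timepoint()].
#' @param correlations Named vector from [correlate_with_target()].
#' @param min_correlation Strict threshold (default 0.8).
#' @param endpoint_fc Optional named endpoint log2FC vector, carried into the
#'   output rows.
#' @param query_region The query interval (metadata only).
#' @return A `prioritized_targets` list: `query_region`, `funnel` (named
#'   integer vector `n_contacted`, `n_de`, `n_correlated`), and `table` (one
#'   row per surviving gene, sorted by correlation descending).
#' @export
integrate_contacts <- function(bin_annotation, de_set, correlations,
                               min_correlation = 0.8, endpoint_fc = NULL,
                               query_region = NULL) {
  assigned <- bin_annotation[!is.na(bin_annotation$gene_id), , drop = FALSE]
  contacted <- unique(assigned$gene_id)
  de_genes <- intersect(contacted, de_set)
  r <- correlations[de_genes]
  corr_genes <- de_genes[!is.na(r) & r > min_correlation]
  funnel <- c(n_contacted = length(contacted), n_de = length(de_genes),
              n_correlated = length(corr_genes))
  if (length(corr_genes)) {
    tab <- data.frame(
      gene_id = corr_genes,
      n_bins = vapply(corr_genes, function(g) {
        sum(assigned$gene_id == g)
      }, integer(1)),
      max_contact_count = vapply(corr_genes, function(g) {
        max(assigned$count[assigned$gene_id == g])
      }, numeric(1)),
      endpoint_log2fc = if (is.null(endpoint_fc)) NA_real_ else
        unname(endpoint_fc[corr_genes]),
      correlation = unname(correlations[corr_genes]),
      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$correlation, tab$gene_id), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(gene_id = character(0), n_bins = integer(0),
                      max_contact_count = numeric(0),
                      endpoint_log2fc = numeric(0), correlation = numeric(0))
  }
  out <- list(query_region = query_region, funnel = funnel, table = tab)
  class(out) <- "prioritized_targets"
  out
}

#' @export
print.prioritized_targets <- function(x, ...) {
  cat("contact-integration funnel:", x$funnel["n_contacted"], "contacted ->",
      x$funnel["n_de"], "differentially expressed ->",
      x$funnel["n_correlated"], "correlated\n")
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}
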