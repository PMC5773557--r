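#' Write a synthetic world to disk
#'
#' Emits the standard-format files every downstream stage consumes: genome
#' FASTA, annotation GFF3 (gene + exon features), chromatin-mark peaks as
#' BED, and the planted truth as JSON.
#'
#' @param genome `DNAStringSet`.
#' @param annotation `world_annotation`.
#' @param tracks Named list of peak data.frames.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_world <- function(genome, annotation, tracks, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fa"))
  write_annotation_gff3(annotation, file.path(outdir, "genes.gff3"))
  for (mark in names(tracks)) {
    write_bed(tracks[[mark]], file.path(outdir, paste0(mark, ".bed")),
              name = mark)
  }
  truth <- annotation$truth
  jsonlite::write_json(
    list(elncRNA_id = truth$elncRNA_id, target_id = truth$target_id,
         neighbor_ids = truth$neighbor_ids, tf_ids = truth$tf_ids,
         suppressed_id = truth$suppressed_id,
         enhancer_region = truth$enhancer_region,
         promoter_region = truth$promoter_region,
         true_proximity_fraction = truth$true_proximity_fraction),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Write gene models as GFF3
#' @param annotation A `world_annotation`.
#' @param path Output path.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  genes <- annotation$genes
  exons <- annotation$exons
  exon_n <- stats::ave(seq_len(nrow(exons)), exons$gene_id, FUN = seq_along)
  feat <- rbind(
    data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
               strand = genes$strand, type = "gene", ID = genes$gene_id,
               Parent = NA_character_, biotype = genes$biotype,
               role = genes$role, stringsAsFactors = FALSE),
    data.frame(chrom = exons$chrom, start = exons$start, end = exons$end,
               strand = exons$strand, type = "exon",
               ID = sprintf("%s.exon%d", exons$gene_id, exon_n),
               Parent = exons$gene_id, biotype = NA_character_,
               role = NA_character_, stringsAsFactors = FALSE))
  rtracklayer::export(df_to_granges(feat), path, format = "gff3")
  invisible(path)
}

#' Write intervals as BED
#' @param df Interval data.frame (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @param name Default feature name when `df` lacks one.
#' @export
write_bed <- function(df, path, name = "feature") {
  if (!"name" %in% names(df)) {
    df$name <- sprintf("%s_%d", name, seq_len(nrow(df)))
  }
  if (!"score" %in% names(df)) df$score <- 0L
  gr <- df_to_granges(df)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read BED intervals into the package's 0-based convention
#' @param path BED file.
#' @return Data frame `chrom`, `start`, `end`, `strand` plus any name/score.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- granges_to_df(gr)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(md)) df <- cbind(df, md)
  df
}
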