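#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path, a plain list, or a ready [world_config()];
#' checks for unknown keys (error naming the key), defaults any missing
#' field (a missing seed is defaulted with a warning), and applies all
#' cross-field constraints of [world_config()].
#'
#' @param config Path to a YAML file, a list of `world_config` arguments, or
#'   a `world_config`.
#' @return A validated `world_config`.
#' @export
validate_config <- function(config) {
  if (inherits(config, "world_config")) {
    validate_world_config(config)
    return(config)
  }
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a file path or a list")
  known <- names(formals(world_config))
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) {
    warning("config has no seed; defaulting to 1")
    config$seed <- 1L
  }
  if (!is.null(config$chrom_sizes)) {
    config$chrom_sizes <- unlist(config$chrom_sizes)
  }
  do.call(world_config, config)
}

#' Run the full discovery pipeline on a synthetic world
#'
#' Orchestrates simulate -> expression screen -> contact-funnel integration
#' -> 4C profiling -> motif scan, writing each stage's files under `outdir`
#' and returning a single discovery report with funnel counts, ranked
#' candidates, top trans links, motif hit counts and a planted-truth
#' recovery block. Fully deterministic for a fixed seed.
#'
#' @param config Anything [validate_config()] accepts.
#' @param outdir Output directory.
#' @param min_abs_log2fc Differential-expression threshold (default 1).
#' @param min_correlation Correlation threshold (default 0.8, strict).
#' @param quiet Suppress stage logging.
#' @return A `discovery_report` list (also written to `report.json`).
#' @export
run_discovery <- function(config, outdir = tempfile("elnc_world_"),
                          min_abs_log2fc = 1, min_correlation = 0.8,
                          quiet = FALSE) {
  log_stage <- function(...) if (!quiet) message("[elnc-scout] ", ...)
  cfg <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  log_stage("stage simulate: generating world (seed ", cfg$seed, ")")
  genome <- generate_genome(cfg)
  ann <- generate_annotation(genome, cfg)
  truth <- ann$truth
  tracks <- simulate_chromatin_tracks(truth)
  write_world(genome, ann, tracks, outdir)
  tc <- simulate_timecourse(ann, cfg)
  write_timecourse_tsv(tc, file.path(outdir, "expression.tsv"))
  log_stage("stage simulate: ", nrow(ann$genes), " genes, ",
            length(tc$timepoints_h), " timepoints")

  log_stage("stage screen: target ", truth$target_id)
  screen <- screen_candidates(tc, truth$target_id,
                              min_abs_log2fc = min_abs_log2fc,
                              min_correlation = min_correlation)
  write_candidates_tsv(screen$candidates,
                       file.path(outdir, "screen_candidates.tsv"))
  elnc_rank <- screen$candidates$rank[
    match(truth$elncRNA_id, screen$candidates$gene_id)]
  log_stage("stage screen: ", length(screen$de_set), " DE genes, ",
            nrow(screen$candidates), " ranked lncRNA candidates")

  log_stage("stage contacts: query = planted enhancer region")
  records <- simulate_contact_matrix(ann, truth, cfg)
  contacts_path <- file.path(outdir, paste0(names(cfg$chrom_sizes)[1], "_",
                                            names(cfg$chrom_sizes)[2],
                                            ".txt"))
  write_contacts(records, contacts_path)
  query <- truth$enhancer_region
  hits <- contacts_for_region(records, query)
  bins <- annotate_bins(hits, ann)
  de_any <- filter_de_any_timepoint(screen$log2fc, min_abs_log2fc)
  corr_anchor <- correlate_with_target(screen$log2fc, truth$elncRNA_id)
  funnel <- integrate_contacts(bins, de_any, corr_anchor, min_correlation,
                               endpoint_fc = screen$log2fc[, ncol(screen$log2fc)],
                               query_region = query)
  log_stage("stage contacts: funnel ",
            paste(funnel$funnel, collapse = " -> "))

  log_stage("stage fourc: bait = target promoter")
  reads <- simulate_fourc_reads(genome, truth, cfg)
  write_bed(reads, file.path(outdir, "fourc_reads.bed"))
  frags <- digest_genome(genome)
  counts <- count_reads(reads, frags)
  profile <- normalize_profile(counts, total_mapped = nrow(reads),
                               bait = truth$promoter_region)
  cand_regions <- data.frame(chrom = ann$genes$chrom,
                             start = ann$genes$start, end = ann$genes$end,
                             name = ann$genes$gene_id,
                             stringsAsFactors = FALSE)
  links <- trans_links(profile, candidate_regions = cand_regions)
  utils::write.table(links, file.path(outdir, "fourc_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  top_link <- if (nrow(links)) links$name[1] else NA_character_
  log_stage("stage fourc: top trans link = ", top_link)

  log_stage("stage motifs: window -20/+5 kb around elncRNA TSS")
  elnc <- ann$genes[ann$genes$gene_id == truth$elncRNA_id, ]
  window <- extract_window(elnc, upstream = 20000, downstream = 5000, genome)
  motif_hits <- scan_motifs(window, default_klf_motifs())
  utils::write.table(motif_hits, file.path(outdir, "motif_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("stage motifs: ", nrow(motif_hits), " hits")

  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  cfg_file <- file.path(outdir, "config.json")
  writeLines(cfg_json, cfg_file)

  recovery <- list(
    elncRNA_id = truth$elncRNA_id,
    target_id = truth$target_id,
    screen_rank_of_elncRNA = if (length(elnc_rank)) elnc_rank else NA_integer_,
    target_in_funnel = truth$target_id %in% funnel$table$gene_id,
    top_trans_link = top_link,
    top_trans_link_is_planted = identical(top_link, truth$elncRNA_id),
    pass = isTRUE(elnc_rank == 1L) &&
      truth$target_id %in% funnel$table$gene_id)

  report <- list(
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    outdir = outdir,
    candidates = screen$candidates,
    funnel = as.list(funnel$funnel),
    funnel_table = funnel$table,
    top_links = utils::head(links, 10),
    n_motif_hits = nrow(motif_hits),
    recovery = recovery)
  class(report) <- "discovery_report"
  jsonlite::write_json(report[setdiff(names(report), "outdir")],
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_report_md(report, file.path(outdir, "report.md"))
  report
}

write_report_md <- function(report, path) {
  lines <- c(
    "# Discovery report",
    "",
    paste0("seed: ", report$seed, "  |  config: ", report$config_hash),
    "",
    paste0("Funnel: ", report$funnel$n_contacted, " contacted -> ",
           report$funnel$n_de, " differentially expressed -> ",
           report$funnel$n_correlated, " correlated"),
    "",
    paste0("Top screen candidate: ",
           if (nrow(report$candidates)) report$candidates$gene_id[1] else "none"),
    paste0("Top trans 4C link: ", report$recovery$top_trans_link),
    paste0("Planted-truth recovery: ",
           if (isTRUE(report$recovery$pass)) "PASS" else "FAIL"))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("discovery report (seed ", x$seed, ")\n", sep = "")
  cat("  funnel:", x$funnel$n_contacted, "->", x$funnel$n_de, "->",
      x$funnel$n_correlated, "\n")
  cat("  screen rank of planted elncRNA:",
      x$recovery$screen_rank_of_elncRNA, "\n")
  cat("  recovery:", if (isTRUE(x$recovery$pass)) "PASS" else "FAIL", "\n")
  invisible(x)
}
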