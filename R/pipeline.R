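#' Run the full promoter-substitution pipeline
#'
#' Executes the stages in order — SEG ingestion and state classification,
#' segment merging and no-data filtering, SV calling and filtering,
#' breakpoint annotation, promoter-substitution calling, recurrence
#' tabulation, the expression-induction screen and (when WGS calls are
#' given) concordance — writing every intermediate as TSV into `out_dir`
#' together with a JSON run manifest (configuration snapshot, input
#' checksums, per-stage record counts, package version). When no expression
#' matrix is supplied the pipeline stops cleanly after promoter-substitution
#' calling and says so in the manifest. Reruns on identical inputs produce
#' identical outputs.
#'
#' @param seg_path SEG file of segmented copy-number profiles.
#' @param gtf_path GTF gene annotation.
#' @param genome_path genome reference TSV ([read_genome_ref()] layout).
#' @param labels_path two-column sample-to-cancer-type TSV.
#' @param expr_path optional expression matrix TSV; `NULL` skips the screen.
#' @param wgs_sv_path optional WGS SV TSV (`sample`, `chrom`, `bp1`, `bp2`,
#'   `type`); `NULL` skips concordance.
#' @param config a [ps_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(seg_path, gtf_path, genome_path, labels_path,
                         expr_path = NULL, wgs_sv_path = NULL,
                         config = ps_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(seg = seg_path, gtf = gtf_path, genome = genome_path,
              labels = labels_path, expr = expr_path %||% NA_character_,
              wgs_sv = wgs_sv_path %||% NA_character_)
  manifest <- list(
    tool = "promsub",
    version = as.character(utils::packageVersion("promsub")),
    config = unclass(config),
    inputs = as.list(inputs[!is.na(inputs)]),
    checksums = as.list(tools::md5sum(unname(inputs[!is.na(inputs)]))),
    counts = list(),
    status = "running",
    notes = character()
  )
  finish <- function(status) {
    manifest$status <<- status
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      manifest$notes <<- c(manifest$notes,
                           sprintf("stage '%s' failed: %s", name,
                                   conditionMessage(e)))
      finish("failed")
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  labels <- stage("labels", function() read_labels(labels_path))
  genome <- stage("genome", function() read_genome_ref(genome_path))
  segs <- stage("segio", function() {
    s <- read_seg(seg_path, labels = labels)
    s <- classify_segments(s, config)
    s <- merge_segments(s, config)
    filter_gap_adjacent(s, config)
  })
  manifest$counts$segments <- nrow(segs)
  utils::write.table(segs, file.path(out_dir, "segments_classified.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  svs <- stage("sv_caller", function() call_svs(segs))
  manifest$counts$svs_called <- nrow(svs)
  svs_f <- stage("sv_filter", function() filter_svs(svs, genome, config))
  manifest$counts$svs_filtered <- nrow(svs_f)
  write_svs(svs_f, file.path(out_dir, "svs_filtered.tsv"))
  write_svs(svs_f, file.path(out_dir, "svs_filtered.bedpe"), format = "bedpe")
  utils::write.table(summarize_by_cancer(svs_f),
                     file.path(out_dir, "sv_counts_by_cancer.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  genes <- stage("gene_annot", function() read_gtf(gtf_path))
  manifest$counts$genes <- nrow(genes)
  events <- stage("ps_caller", function() call_ps(svs_f, genes, config))
  manifest$counts$ps_events <- nrow(events)
  utils::write.table(events, file.path(out_dir, "ps_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- stage("recurrence", function() build_recurrence(events, config))
  utils::write.table(rec$by_cancer,
                     file.path(out_dir, "recurrence_by_cancer.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rec$overall,
                     file.path(out_dir, "recurrence_overall.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$counts$recurrent_pairs <- sum(rec$overall$recurrent)

  if (!is.null(wgs_sv_path)) {
    conc <- stage("concordance", function() {
      wgs <- utils::read.delim(wgs_sv_path, stringsAsFactors = FALSE)
      match_svs(svs_f, wgs, config)
    })
    manifest$counts$wgs_matched <- conc$summary$n_matched
    manifest$concordance <- conc$summary
    utils::write.table(conc$matches,
                       file.path(out_dir, "concordance_matches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (is.null(expr_path)) {
    manifest$notes <- c(manifest$notes,
                        "expression matrix not provided; induction screen skipped")
    finish("partial")
    return(invisible(manifest))
  }

  screen <- stage("expr_assoc", function() {
    expr <- read_expr(expr_path)
    screen_recurrent(events, expr, labels, config)
  })
  manifest$counts$pairs_screened <- nrow(screen)
  manifest$counts$pairs_significant <- sum(screen$significant)
  utils::write.table(screen, file.path(out_dir, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  finish("complete")
  invisible(manifest)
}
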