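## End-to-end orchestration: simulate -> preprocess -> discover -> DE ->
## degradome -> enrichment, plus ground-truth evaluation helpers and a
## machine-readable run log.

#' Simulate a complete synthetic study
#'
#' Generates the reference set, one small-RNA FASTQ per library, and one
#' degradome library per small-RNA library.
#'
#' @param cfg A `sim_config`.
#' @param out_dir Output directory.
#' @return The manifest, with `$paths$reads` (named FASTQ paths) and
#'   `$paths$degradome` (named FASTA paths) added.
#' @export
simulate_study <- function(cfg, out_dir) {
  manifest <- generate_reference_set(cfg, out_dir)
  reads <- stats::setNames(
    file.path(out_dir, paste0("reads_", cfg$libraries, ".fastq")),
    cfg$libraries)
  deg <- stats::setNames(
    file.path(out_dir, paste0("degradome_", cfg$libraries, ".fa")),
    cfg$libraries)
  for (lib in cfg$libraries) {
    generate_srna_library(cfg, manifest, lib, reads[[lib]])
    generate_degradome_library(cfg, manifest, deg[[lib]], label = lib)
  }
  manifest$paths$reads <- reads
  manifest$paths$degradome <- deg
  manifest
}

# read contaminant reference FASTAs into the named list annotate expects
read_contaminant_references <- function(paths) {
  lapply(paths, function(p) read_sequences(p))
}

#' Run the full analysis pipeline
#'
#' Chains preprocessing, miRNA discovery, family assignment, differential
#' expression (each treatment library against the control), shared-set
#' summaries, degradome target validation, and term enrichment of the
#' targets of differentially expressed miRNAs. All stages consume data
#' only through the package readers; a JSON run log with parameters and
#' input digests is written when `out_dir` is given.
#'
#' @param libs A `library_spec()` data frame (first control row is the DE
#'   baseline).
#' @param adapter 3' adapter sequence.
#' @param references Contaminant reference list (named list of sequence
#'   vectors) or a named vector of FASTA paths.
#' @param mature_path,hairpin_path Catalog FASTA paths.
#' @param transcriptome_path Transcriptome FASTA path.
#' @param degradome_paths Named (by library) degradome FASTA paths with
#'   collapsed `_x<COUNT>` headers; optional.
#' @param annotation_path Gene-to-term TSV path; optional.
#' @param cfg A `run_config`.
#' @param out_dir Directory for TSV reports and the run log; optional.
#' @return List with `tags`, `summaries`, `valid_totals`, `calls`,
#'   `families`, `de` (named list per pair), `venn`, `degradome`
#'   (`events`, `report`, `summaries`), `enrichment`.
#' @export
run_pipeline <- function(libs, adapter, references, mature_path,
                         hairpin_path, transcriptome_path = NULL,
                         degradome_paths = NULL, annotation_path = NULL,
                         cfg = run_config(), out_dir = NULL) {
  if (is.character(references))
    references <- read_contaminant_references(references)
  pre <- preprocess_libraries(libs, adapter, references, cfg)
  catalog <- build_catalog(read_sequences(mature_path),
                           read_sequences(hairpin_path), cfg)
  calls <- discover_mirnas(pre$tags, catalog, pre$valid_totals, cfg)
  families <- assign_families(
    calls$matched_known[calls$status == "conserved"])

  ctrl <- libs$name[libs$role == "control"][1]
  treats <- setdiff(libs$name, ctrl)
  de <- list()
  for (tr in treats) {
    de[[paste0(tr, "_vs_", ctrl)]] <- call_differential(
      calls$sequence, calls[[paste0("count_", tr)]],
      calls[[paste0("count_", ctrl)]], pre$valid_totals[[tr]],
      pre$valid_totals[[ctrl]], cfg)
  }
  detect_sets <- lapply(stats::setNames(libs$name, libs$name), function(l)
    calls$sequence[calls[[paste0("count_", l)]] > 0])
  venn <- if (length(detect_sets) >= 2L) shared_membership(detect_sets)
          else NULL

  degradome <- NULL
  if (!is.null(degradome_paths) && !is.null(transcriptome_path)) {
    tx <- read_sequences(transcriptome_path)
    mirnas <- stats::setNames(calls$sequence,
                              ifelse(is.na(calls$matched_known),
                                     paste0("novel:", calls$sequence),
                                     calls$matched_known))
    events <- list()
    summaries <- list()
    for (lib in names(degradome_paths)) {
      dseq <- read_sequences(degradome_paths[[lib]])
      parsed <- parse_count_header(names(dseq))
      if (is.list(parsed) && !is.data.frame(parsed))
        parsed <- data.frame(id = parsed$id, count = parsed$count)
      profiles <- map_degradome_tags(dseq, parsed$count, tx)
      events[[lib]] <- validate_cleavage_events(mirnas, tx, profiles,
                                                lib, cfg)
      covered <- sum(vapply(profiles, function(v) any(v > 0L), TRUE))
      summaries[[lib]] <- degradome_summary(
        raw_reads = sum(parsed$count), unique_raw = length(dseq),
        mapped = attr(profiles, "n_mapped"),
        unique_mapped = attr(profiles, "n_unique_mapped"),
        input_cdnas = length(tx), covered_cdnas = covered)
    }
    all_events <- do.call(rbind, events)
    degradome <- list(events = all_events,
                      report = compile_target_report(all_events),
                      summaries = summaries)
  }

  enrichment <- NULL
  if (!is.null(degradome) && !is.null(annotation_path)) {
    annotation <- read_annotation_table(annotation_path)
    de_seqs <- unique(unlist(lapply(de, function(d)
      d$mirna_id[d$verdict %in% c("up", "down")])))
    sel <- unique(degradome$events$transcript_id[
      degradome$events$mirna_seq %in% de_seqs])
    sel <- intersect(sel, unique(annotation$gene_id))
    enrichment <- if (length(sel))
      enrich_terms(sel, annotation, alpha = cfg$alpha) else NULL
  }

  res <- list(tags = pre$tags, summaries = pre$summaries,
              valid_totals = pre$valid_totals, calls = calls,
              families = families, de = de, venn = venn,
              degradome = degradome, enrichment = enrichment)
  if (!is.null(out_dir)) write_pipeline_reports(res, libs, cfg, out_dir,
                                                inputs = c(
                                                  libs$reads_path,
                                                  mature_path, hairpin_path,
                                                  transcriptome_path,
                                                  unlist(degradome_paths),
                                                  annotation_path))
  res
}

# TSV reports + JSON run log (parameters and md5 digests of the inputs)
write_pipeline_reports <- function(res, libs, cfg, out_dir, inputs) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (lib in names(res$summaries))
    write_report_tsv(res$summaries[[lib]],
                     file.path(out_dir, paste0("summary_", lib, ".tsv")))
  write_report_tsv(res$calls, file.path(out_dir, "mirna_calls.tsv"))
  write_report_tsv(res$families, file.path(out_dir, "families.tsv"))
  for (pair in names(res$de))
    write_report_tsv(res$de[[pair]],
                     file.path(out_dir, paste0("de_", pair, ".tsv")))
  if (!is.null(res$venn))
    write_report_tsv(res$venn$regions, file.path(out_dir, "venn.tsv"))
  if (!is.null(res$degradome)) {
    write_report_tsv(res$degradome$report$table,
                     file.path(out_dir, "targets.tsv"))
    write_report_tsv(res$degradome$report$summary,
                     file.path(out_dir, "category_summary.tsv"))
  }
  if (!is.null(res$enrichment))
    write_report_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  log <- list(package = "heatmiR",
              version = as.character(utils::packageVersion("heatmiR")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              parameters = unclass(cfg),
              libraries = libs,
              input_digests = as.list(tools::md5sum(unlist(inputs))))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Evaluate discovery calls against the ground truth
#'
#' @param calls [discover_mirnas()] output.
#' @param manifest Ground-truth manifest.
#' @return List with conserved/novel sensitivity and precision.
#' @export
evaluate_discovery <- function(calls, manifest) {
  planted <- manifest$planted
  mat <- planted$sequence[planted$type == "mature"]
  star <- planted$sequence[planted$type == "star"]
  cons <- calls$sequence[calls$status == "conserved"]
  nov <- calls$sequence[calls$status == "novel_candidate"]
  list(
    conserved_sensitivity = mean(mat %in% cons),
    conserved_precision = if (length(cons)) mean(cons %in% mat) else NA,
    novel_sensitivity = mean(star %in% nov),
    novel_precision = if (length(nov)) mean(nov %in% star) else NA)
}

#' Evaluate differential calls against the planted fold changes
#'
#' A true positive is a planted-DE miRNA called up/down with the planted
#' sign; sensitivity is TP over planted, and the false-discovery
#' proportion is the fraction of up/down calls that are not planted-DE
#' (or carry the wrong sign).
#'
#' @param de One [call_differential()] result (mirna_id = sequence).
#' @param manifest Ground-truth manifest.
#' @param pair Pair label, e.g. `"MET_vs_NT"`.
#' @return List with `sensitivity`, `fdp`, `n_planted`, `n_called`.
#' @export
evaluate_de <- function(de, manifest, pair) {
  truth <- manifest$planted_de[manifest$planted_de$pair == pair, ,
                               drop = FALSE]
  truth$sequence <- manifest$planted$sequence[
    match(truth$seq_id, manifest$planted$seq_id)]
  called <- de[de$verdict %in% c("up", "down"), , drop = FALSE]
  called_sign <- ifelse(called$verdict == "up", 1, -1)
  truth_sign <- stats::setNames(sign(truth$log2fc), truth$sequence)
  tp <- sum(!is.na(truth_sign[called$mirna_id]) &
              truth_sign[called$mirna_id] == called_sign)
  list(sensitivity = if (nrow(truth)) tp / nrow(truth) else NA,
       fdp = if (nrow(called)) (nrow(called) - tp) / nrow(called) else 0,
       n_planted = nrow(truth), n_called = nrow(called))
}

#' Evaluate degradome recovery of planted cleavage sites
#'
#' @param events [validate_cleavage_events()] output for one library.
#' @param manifest Ground-truth manifest.
#' @return List with `recovered` (fraction of planted sites present at
#'   any category), `recovered_cat01`, `recovered_cat0`, `n_planted`.
#' @export
evaluate_degradome <- function(events, manifest) {
  pc <- manifest$planted_cleavages
  key <- paste(events$mirna_seq, events$transcript_id, events$site)
  pkey <- paste(pc$mirna_seq, pc$transcript_id, pc$site)
  hit <- pkey %in% key
  cat_of <- function(k) {
    i <- match(k, key)
    events$category[i]
  }
  cats <- cat_of(pkey)
  list(recovered = mean(hit),
       recovered_cat01 = mean(!is.na(cats) & cats <= 1L),
       recovered_cat0 = mean(!is.na(cats) & cats == 0L),
       n_planted = nrow(pc))
}
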