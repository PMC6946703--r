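# End-to-end orchestration: simulate (optional) -> extract -> classify ->
# calibrate/match -> analyze, with a machine-readable run report.

#' Build a validated pipeline run configuration
#'
#' Either `simulate` (a [sim_config()]) generates the inputs, or `reads`,
#' `refs` and `parental_spacers`/`repeat_seq` point at real data.  All
#' thresholds of the downstream stages are exposed here; the run report
#' echoes every value together with its provenance class (experimental
#' default vs pipeline decision).
#'
#' @param out_dir output directory (created if missing).
#' @param simulate optional [sim_config()]; when given, reads/references
#'   come from [simulate_recording()].
#' @param reads FASTQ/FASTA path or named character vector of reads.
#' @param refs FASTA path or reference set; roles must identify the
#'   recorder entries (see `recorder_ids`).
#' @param recorder_ids ids of the recorder genome and recording plasmid
#'   within `refs`.
#' @param db target database for exogenous spacers: FASTA path or
#'   reference set.  Defaults to the donor references when simulating.
#' @param annotations optional GFF3 path or annotation `data.frame`.
#' @param repeat_seq,parental_spacers array structure (taken from
#'   `simulate` when present).
#' @param max_mismatch repeat-match Hamming tolerance.
#' @param spacer_len_bounds valid spacer length range.
#' @param parental_match_max_mismatch parental-anchor tolerance.
#' @param id_threshold,cov_threshold recorder-filter thresholds (percent).
#' @param min_identity,min_coverage database-match thresholds (percent).
#' @param calibrate run the scrambled-null calibration and report it.
#' @param grid calibration threshold grid.
#' @param control_percent,min_spacers,fold sample-call parameters.
#' @param percent_denominator denominator for percent-exogenous:
#'   `"all_spacers"` (all sequenced spacers) or `"new_spacers"`.
#' @param window coverage window in bp.
#' @param seed seed for calibration scrambling.
#' @param sample_id sample label.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       simulate = NULL,
                       reads = NULL, refs = NULL,
                       recorder_ids = c("recorder_genome", "recorder_plasmid"),
                       db = NULL, annotations = NULL,
                       repeat_seq = NULL, parental_spacers = NULL,
                       max_mismatch = 2L, spacer_len_bounds = c(25L, 45L),
                       parental_match_max_mismatch = 2L,
                       id_threshold = 80, cov_threshold = 80,
                       min_identity = 95, min_coverage = 95,
                       calibrate = TRUE, grid = c(80, 85, 90, 95, 100),
                       control_percent = 0.03, min_spacers = 10L, fold = 3,
                       percent_denominator = c("all_spacers", "new_spacers"),
                       window = 200L, seed = 1L, sample_id = "sample") {
  percent_denominator <- match.arg(percent_denominator)
  if (is.null(simulate)) {
    if (is.null(reads) || is.null(refs)) {
      stop("provide either 'simulate' or both 'reads' and 'refs'", call. = FALSE)
    }
    if (is.null(repeat_seq) || is.null(parental_spacers)) {
      stop("repeat_seq and parental_spacers are required without 'simulate'",
           call. = FALSE)
    }
  } else {
    stopifnot(inherits(simulate, "sim_config"))
    if (is.null(repeat_seq)) repeat_seq <- simulate$repeat_seq
    if (is.null(parental_spacers)) parental_spacers <- simulate$parental_spacers
    spacer_len_bounds <- simulate$spacer_len_bounds
  }
  cfg <- list(out_dir = out_dir, simulate = simulate, reads = reads,
              refs = refs, recorder_ids = recorder_ids, db = db,
              annotations = annotations, repeat_seq = repeat_seq,
              parental_spacers = parental_spacers,
              max_mismatch = as.integer(max_mismatch),
              spacer_len_bounds = as.integer(spacer_len_bounds),
              parental_match_max_mismatch = as.integer(parental_match_max_mismatch),
              id_threshold = id_threshold, cov_threshold = cov_threshold,
              min_identity = min_identity, min_coverage = min_coverage,
              calibrate = isTRUE(calibrate), grid = grid,
              control_percent = control_percent,
              min_spacers = as.integer(min_spacers), fold = fold,
              percent_denominator = percent_denominator,
              window = as.integer(window), seed = as.integer(seed),
              sample_id = sample_id)
  class(cfg) <- "run_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full recording-analysis pipeline
#'
#' Executes simulate (optional) -> extract -> classify -> calibrate/match
#' -> analyze, writes every stage's TSV output plus a JSON run report to
#' `config$out_dir`, and returns the results.  Re-running with the same
#' configuration reproduces identical outputs.  A stage failure aborts with
#' the failing stage named; outputs of earlier stages are retained.
#'
#' @param config a [run_config()].
#' @return list with `summary`, `classified`, `exogenous` (dereplicated
#'   records), `calibration`, `hits`, `filtered`, `profiles`, `coverage`,
#'   `pam`, `cover`, `call`, `annotation_counts`, `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("crisprec")),
                 seed = config$seed,
                 thresholds = list(
                   id_threshold = list(value = config$id_threshold, provenance = "experimental default"),
                   cov_threshold = list(value = config$cov_threshold, provenance = "experimental default"),
                   min_identity = list(value = config$min_identity, provenance = "experimental default"),
                   min_coverage = list(value = config$min_coverage, provenance = "experimental default"),
                   control_percent = list(value = config$control_percent, provenance = "experimental default"),
                   min_spacers = list(value = config$min_spacers, provenance = "experimental default"),
                   fold = list(value = config$fold, provenance = "experimental default"),
                   max_mismatch = list(value = config$max_mismatch, provenance = "pipeline decision"),
                   window = list(value = config$window, provenance = "experimental default")),
                 counts = list())

  # -- inputs ---------------------------------------------------------------
  sim <- NULL
  if (!is.null(config$simulate)) {
    sim <- .stage("simulate", simulate_recording(config$simulate, dir = config$out_dir))
    reads <- stats::setNames(sim$reads$seq, sim$reads$read_id)
    refs <- sim$refs
  } else {
    reads <- .stage("extract", {
      if (is.character(config$reads) && length(config$reads) == 1L &&
          file.exists(config$reads)) {
        if (grepl("\\.(fq|fastq)$", config$reads)) read_fastq(config$reads)
        else read_fasta(config$reads)
      } else if (is.character(config$reads) && length(config$reads) == 1L) {
        stop(sprintf("reads file '%s' not found", config$reads))
      } else config$reads
    })
    refs <- .stage("extract", {
      if (is.character(config$refs) && length(config$refs) == 1L &&
          file.exists(config$refs)) {
        as_reference_set(read_fasta(config$refs), role = "donor")
      } else as_reference_set(config$refs)
    })
  }
  refs <- as_reference_set(refs)
  recorder_mask <- refs$id %in% config$recorder_ids |
    refs$role %in% c("recorder_genome", "recorder_plasmid")
  recorder_db <- refs[recorder_mask, , drop = FALSE]
  if (nrow(recorder_db) == 0L) {
    stop("stage 'classify' failed: no recorder references identified", call. = FALSE)
  }
  db <- if (is.null(config$db)) {
    refs[!recorder_mask, , drop = FALSE]
  } else if (is.character(config$db) && length(config$db) == 1L && file.exists(config$db)) {
    as_reference_set(read_fasta(config$db), role = "plasmid_db")
  } else {
    as_reference_set(config$db)
  }
  report$counts$reads <- length(reads)

  # -- extract --------------------------------------------------------------
  parsed <- .stage("extract", parse_sample(
    reads, config$repeat_seq, config$parental_spacers,
    config$max_mismatch, config$spacer_len_bounds,
    config$parental_match_max_mismatch))
  summary <- .stage("extract", summarize_expansion(parsed, config$sample_id))
  spacer_rows <- .stage("extract", {
    ok <- parsed[parsed$status == "ok", , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(ok)), function(i) {
      sp <- ok$spacers[[i]]
      if (length(sp) == 0L) return(NULL)
      data.frame(read_id = ok$read_id[i],
                 position_in_array = seq_along(sp) - 1L,
                 spacer_seq = sp,
                 is_new = seq_along(sp) <= ok$n_new[i],
                 stringsAsFactors = FALSE)
    }))
  })
  write_tsv(spacer_rows, file.path(config$out_dir, "spacers.tsv"))
  write_tsv(summary, file.path(config$out_dir, "summary.tsv"))
  report$counts$arrays_ok <- summary$n_arrays_total
  report$counts$arrays_expanded <- summary$n_arrays_expanded
  report$counts$new_spacers <- summary$n_new_spacers

  # -- classify -------------------------------------------------------------
  new_spacers <- unlist(parsed$new_spacers[parsed$status == "ok"],
                        use.names = FALSE)
  classified <- .stage("classify", two_step_endogenous_filter(
    new_spacers, recorder_db, config$id_threshold, config$cov_threshold))
  exo_seqs <- classified$seq[classified$classification == "exogenous"]
  exo <- .stage("classify", dereplicate(exo_seqs, config$sample_id))
  write_tsv(classified, file.path(config$out_dir, "classified.tsv"))
  if (nrow(exo) > 0L) {
    write_fasta(stats::setNames(exo$sequence, exo$spacer_id),
                file.path(config$out_dir, "exogenous.fasta"))
  }
  report$counts$exogenous_spacers <- length(exo_seqs)
  report$counts$unique_exogenous <- nrow(exo)

  # -- calibrate / match ----------------------------------------------------
  calibration <- NULL
  if (config$calibrate && nrow(exo) > 0L && nrow(db) > 0L) {
    calibration <- .stage("calibrate", suppressWarnings(calibrate_threshold(
      exo, db, seed = config$seed, grid = config$grid)))
    write_tsv(calibration$curve, file.path(config$out_dir, "calibration.tsv"))
  }
  hits <- .stage("match", {
    if (nrow(exo) > 0L && nrow(db) > 0L) {
      match_to_database(exo, db, config$min_identity, config$min_coverage)
    } else .empty_hits()
  })
  filtered <- .stage("match", filter_multi_mapping(hits))
  spacer_seqs <- stats::setNames(exo$sequence, exo$spacer_id)
  if (nrow(hits) > 0L) {
    write_hits_tsv(hits, spacer_seqs, db, file.path(config$out_dir, "hits.tsv"))
  }
  report$counts$hits <- nrow(hits)
  report$counts$multi_mapping_removed <- filtered$n_removed

  # -- analyze --------------------------------------------------------------
  total_spacers <- sum(vapply(parsed$spacers[parsed$status == "ok"],
                              length, integer(1)))
  denom <- if (config$percent_denominator == "all_spacers") total_spacers
           else max(length(new_spacers), 1L)
  percent_exo <- 100 * length(exo_seqs) / max(denom, 1L)
  lens <- .ref_lengths(db)
  profiles <- .stage("analyze", {
    if (nrow(exo) > 0L && nrow(db) > 0L) {
      normalized_spacer_mapping(filtered$hits, lens, max(nrow(exo), 1L))
    } else NULL
  })
  coverage <- .stage("analyze", {
    cov <- lapply(names(lens), function(rid) {
      wc <- window_coverage(filtered$hits[filtered$hits$ref_id == rid, ,
                                          drop = FALSE],
                            lens[[rid]], config$window)
      cbind(ref_id = rid, wc, stringsAsFactors = FALSE)
    })
    do.call(rbind, cov)
  })
  pam <- .stage("analyze", pam_summary(filtered$hits, db))
  cover <- .stage("analyze", minimal_covering_set(filtered$hits, lens,
                                                  all_spacers = exo$spacer_id))
  call <- .stage("analyze", call_sample(
    config$sample_id, summary$n_arrays_total, percent_exo, nrow(exo),
    config$control_percent, config$min_spacers, config$fold))
  annotation_counts <- NULL
  if (!is.null(config$annotations)) {
    ann <- if (is.character(config$annotations)) read_gff3(config$annotations)
           else config$annotations
    annotation_counts <- .stage("analyze", annotate_hits(filtered$hits, ann))
    write_tsv(annotation_counts, file.path(config$out_dir, "annotations.tsv"))
  }
  if (!is.null(profiles)) write_tsv(profiles, file.path(config$out_dir, "profiles.tsv"))
  if (!is.null(coverage)) write_tsv(coverage, file.path(config$out_dir, "coverage.tsv"))
  write_tsv(call, file.path(config$out_dir, "calls.tsv"))
  write_tsv(cover$cover, file.path(config$out_dir, "cover.tsv"))
  if (pam$n_extractable > 0L) {
    write_tsv(data.frame(pam = names(pam$counts), n = unname(pam$counts)),
              file.path(config$out_dir, "pam.tsv"))
  }
  report$counts$cover_refs <- nrow(cover$cover)
  report$percent_exogenous <- percent_exo
  report$is_hgt_positive <- call$is_hgt_positive
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  list(summary = summary, parsed = parsed, classified = classified,
       exogenous = exo, calibration = calibration, hits = hits,
       filtered = filtered, profiles = profiles, coverage = coverage,
       pam = pam, cover = cover, call = call,
       annotation_counts = annotation_counts, report = report)
}
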