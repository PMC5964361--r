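#' Persist a raw recording as plain text
#'
#' Writes a directory containing `samples.csv` (one column per channel),
#' `markers.csv`, `fsr.csv` (when present) and `meta.json` (sampling rate,
#' layout name, provenance). The layout is rebuilt by name on read, so only
#' the canonical layouts round-trip.
#'
#' @param rec a `raw_recording` with a canonical layout (`cuff16`/`cuff3`).
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  assert_that(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  assert_that(rec$layout$name %in% c("cuff16", "cuff3"),
              "only canonical layouts can be persisted by name")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(t(rec$samples)),
            file.path(path, "samples.csv"), row.names = FALSE)
  write.csv(rec$markers, file.path(path, "markers.csv"), row.names = FALSE)
  if (!is.null(rec$fsr)) {
    write.csv(data.frame(fsr = rec$fsr), file.path(path, "fsr.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(list(fs = rec$fs, layout = rec$layout$name,
                            meta = rec$meta),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#' @param path directory written by [write_recording()].
#' @return a `raw_recording`.
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  samples <- t(as.matrix(read.csv(file.path(path, "samples.csv"))))
  dimnames(samples) <- NULL
  markers <- read.csv(file.path(path, "markers.csv"))
  fsr_path <- file.path(path, "fsr.csv")
  fsr <- if (file.exists(fsr_path)) read.csv(fsr_path)$fsr else NULL
  raw_recording(samples, fs = meta$fs, markers = markers,
                layout = build_cuff_layout(meta$layout), fsr = fsr,
                meta = as.list(meta$meta))
}

#' Persist a feature table as CSV plus JSON sidecar
#'
#' The CSV holds `trial_id`, `class_id` and one `chN` column per channel at
#' full double precision; the sidecar records the `normalised` flag and
#' channel ids, making the round trip lossless.
#'
#' @param table a `feature_table`.
#' @param path CSV file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  assert_that(inherits(table, "feature_table"), "table must be a feature_table")
  df <- data.frame(trial_id = table$trial_ids, class_id = table$labels)
  ch <- as.data.frame(table$values)
  names(ch) <- sprintf("ch%d", table$channel_ids)
  utils::write.table(cbind(df, ch), path, sep = ",", row.names = FALSE,
                     qmethod = "double")
  jsonlite::write_json(list(normalised = table$normalised,
                            channel_ids = table$channel_ids),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV file path.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(df[, grepl("^ch", names(df)), drop = FALSE])
  dimnames(values) <- NULL
  out <- feature_table(values, df$class_id, df$trial_id,
                       normalised = isTRUE(side$normalised))
  out$channel_ids <- as.integer(side$channel_ids)
  out
}

# recursively strip non-serialisable pieces of a run report
report_to_list <- function(report) {
  res <- lapply(report$results, function(r) {
    list(cuff = r$cuff, site = r$site, n_trials = r$n_trials,
         fold_scores = r$cv$fold_scores,
         median_score = r$cv$median_score,
         confusion = unclass(r$cv$confusion),
         best_pair = if (!is.null(r$pair_ranking)) {
           as.list(r$pair_ranking[1, ])
         })
  })
  cfg <- report$config
  cfg$classes <- as.data.frame(cfg$classes)
  list(design = report$config$design,
       config = unclass(cfg),
       n_events = report$n_events,
       rejected_trials = report$rejected_trials,
       results = res,
       distal_minus_proximal = report$comparisons$distal_minus_proximal,
       confusion_difference = report$comparisons$confusion_difference,
       version = report$version)
}

#' Serialise a run report to JSON
#'
#' Fold scores, medians, confusion counts, best pairs, rejection lists and a
#' full config echo — everything needed to audit or rerun the analysis.
#'
#' @param report a `run_report`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  assert_that(inherits(report, "run_report"), "report must be a run_report")
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
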