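#' Write one ECG record as plain text plus JSON sidecar
#'
#' The signal goes to `<subject>_s<session>.txt`, one sample per line at
#' full double precision (the write/read round trip is exact); the metadata
#' (subject, session, fs, ground-truth R peaks when present) goes to a JSON
#' sidecar with the same stem.
#'
#' @param record an `ecg_record`.
#' @param dir output directory (created if needed).
#' @return invisibly, the signal file path.
#' @export
write_ecg_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sprintf("%s_s%d", record$subject_id, record$session_id)
  sig_path <- file.path(dir, paste0(stem, ".txt"))
  writeLines(sprintf("%.17g", record$signal), sig_path)
  meta <- list(subject_id = record$subject_id,
               session_id = record$session_id,
               fs = record$fs, n_samples = length(record$signal),
               index_base = 1L)
  if (!is.null(record$true_r_peaks)) meta$true_r_peaks <- record$true_r_peaks
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(sig_path)
}

#' Read an ECG record written by [write_ecg_record()]
#'
#' @param path signal text file (one sample per line).
#' @param sidecar JSON sidecar path; defaults to `path` with a .json
#'   extension. The sidecar must declare `fs`.
#' @return an `ecg_record`.
#' @export
read_ecg_record <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.[^.]+$", ".json", path)
  if (!file.exists(sidecar))
    stop(sprintf("read_ecg_record: sidecar %s not found", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs))
    stop(sprintf("read_ecg_record: sidecar %s does not declare fs", sidecar))
  x <- as.numeric(readLines(path))
  if (!is.null(meta$n_samples) && length(x) != meta$n_samples)
    warning(sprintf("read_ecg_record: %s has %d samples, sidecar declares %d; trusting the data",
                    path, length(x), meta$n_samples))
  structure(list(subject_id = meta$subject_id %||% NA_character_,
                 session_id = as.integer(meta$session_id %||% NA_integer_),
                 fs = as.numeric(meta$fs), signal = x,
                 true_r_peaks = if (!is.null(meta$true_r_peaks))
                   as.integer(meta$true_r_peaks)),
            class = "ecg_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to disk (signal files, sidecars, manifest)
#'
#' @param cohort an `ecg_cohort`.
#' @param dir output directory.
#' @return invisibly, the manifest path (`manifest.csv` with columns
#'   subject_id, session_id, path).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$records, function(r) {
    p <- write_ecg_record(r, dir)
    data.frame(subject_id = r$subject_id, session_id = r$session_id,
               path = basename(p), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return list of `ecg_record` (class `ecg_cohort` without spec/morphologies).
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp)) stop(sprintf("read_cohort: %s has no manifest.csv", dir))
  manifest <- utils::read.csv(mp, stringsAsFactors = FALSE)
  records <- lapply(manifest$path, function(p) read_ecg_record(file.path(dir, p)))
  structure(list(spec = NULL, morphologies = NULL, records = records),
            class = "ecg_cohort")
}

report_to_list <- function(report) {
  if (inherits(report, "ident_report")) {
    list(kind = "identification", method = report$method,
         configuration = report$configuration,
         accuracy = report$accuracy, precision = report$precision,
         recall = report$recall, f1 = report$f1,
         confusion = unname(as.matrix(report$confusion)),
         subjects = rownames(report$confusion),
         per_subject = report$per_subject)
  } else if (inherits(report, "auth_report")) {
    out <- list(kind = "authentication", configuration = report$configuration,
                accuracy = report$accuracy,
                impostor_score = report$impostor_score,
                decisions = report$decisions,
                per_subject = report$per_subject,
                impostors = report$impostors)
    if (!is.null(report$distance_matrix) &&
        report$distance_matrix$multiplicity == 1)
      out$distance_matrix <- unname(report$distance_matrix$values)
    out
  } else unclass(report)
}

#' Serialize a report to JSON at full precision
#'
#' @param report an `ident_report` or `auth_report` (or plain list).
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_list(report), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Reload a JSON report written by [write_report()]
#'
#' @param path JSON path.
#' @return list with the report's fields (metrics at full precision).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
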