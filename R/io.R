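#' Read and write PPG waveforms as delimited text
#'
#' The dialect is CSV with optional `#`-prefixed comment lines; a
#' `# fs=<Hz>` header carries the sampling rate. Two columns
#' (`time,amplitude`) or a single amplitude column (index implicit) are
#' accepted; with two columns and no header, fs is inferred from the time
#' step.
#'
#' @param path file path
#' @return [ppg_waveform()]
#' @export
read_waveform_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop_domain("empty waveform file: ", path)
  comments <- grep("^\\s*#", lines, value = TRUE)
  fs <- NA_real_
  m <- regmatches(comments, regexpr("fs\\s*=\\s*[0-9.eE+-]+", comments))
  if (length(m)) fs <- as.numeric(sub("fs\\s*=\\s*", "", m[[1]]))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop_domain("no samples in waveform file: ", path)
  has_header <- grepl("[A-Za-z]", body[1])
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        header = has_header)
  if (ncol(df) >= 2) {
    tcol <- df[[1]]; amp <- df[[2]]
    if (!is.finite(fs)) {
      dt <- diff(tcol)
      if (length(dt) < 1 || any(dt <= 0))
        stop_domain("cannot infer fs from the time column in ", path)
      fs <- 1 / stats::median(dt)
    }
    ppg_waveform(amp, fs, t0 = tcol[1])
  } else {
    if (!is.finite(fs))
      stop_domain("single-column waveform needs a '# fs=<Hz>' header: ", path)
    ppg_waveform(df[[1]], fs)
  }
}

#' @rdname read_waveform_csv
#' @param w [ppg_waveform()] to write
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "ppg_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", w$fs), con)
  t <- w$t0 + (seq_along(w$samples) - 1) / w$fs
  writeLines("time,amplitude", con)
  writeLines(sprintf("%.6f,%.10g", t, w$samples), con)
  invisible(path)
}

COHORT_COLUMNS <- c("subject_id", "pi_max", "pi_min", "spo2", "sbp", "dbp",
                    "hr", "dos_pct", "bfv_ml_min", "dos_label", "bfv_label")

#' Read/write subject feature tables
#'
#' CSV with header `subject_id,pi_max,pi_min,spo2,sbp,dbp,hr,dos_pct,
#' bfv_ml_min,dos_label,bfv_label`; the ground-truth columns are optional.
#'
#' @param path file path
#' @return data.frame of subjects
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "pi_max", "pi_min", "spo2", "sbp", "dbp", "hr")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_domain("cohort table lacks columns: ",
                paste(missing_cols, collapse = ", "))
  df
}

#' @rdname read_cohort_csv
#' @param cohort data.frame of subjects
#' @export
write_cohort_csv <- function(cohort, path) {
  keep <- intersect(COHORT_COLUMNS, names(cohort))
  utils::write.csv(cohort[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a run configuration from JSON
#'
#' Recognized top-level keys: `physics` (calibration constants), `synth`
#' (cohort and waveform specs), `classify` (hyperparameter grids), `seed`,
#' `task`. Unknown keys are kept but reported with a warning.
#'
#' @param path JSON file
#' @return named list of class `run_config`
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("physics", "synth", "classify", "seed", "task", "out")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning("unknown config keys ignored: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Calibration constants from a config's `physics` block
#'
#' @param cfg a `run_config` (or plain list with a `physics` entry)
#' @return [calibration_constants()]
#' @export
config_calibration <- function(cfg) {
  p <- cfg$physics
  if (is.null(p)) return(calibration_constants())
  do.call(calibration_constants,
          p[intersect(names(p), names(formals(calibration_constants)))])
}
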