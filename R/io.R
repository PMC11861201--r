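# Columnar text interfaces: sEMG and keypoint CSVs with a time column,
# trial structure and decomposition metadata as JSON.

#' Read and write sEMG recordings as CSV
#'
#' Schema: header `time_s,IF,OF,CS,LLSAN,ZM,DAO,Me`, one row per sample.
#' The sampling rate is recovered from the time column on read.
#'
#' @param rec An [emg_recording].
#' @param path File path.
#' @param stage Processing stage to stamp on the recording on read.
#' @return `write_semg_csv` returns `path` invisibly; `read_semg_csv`
#'   returns an [emg_recording].
#' @export
write_semg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  df <- data.frame(time_s = (seq_len(ncol(rec$samples)) - 1) / rec$fs,
                   t(rec$samples), check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_semg_csv
#' @export
read_semg_csv <- function(path, stage = "raw") {
  df <- data.table::fread(path, data.table = FALSE)
  if (names(df)[1L] != "time_s") stop("expected a time_s column first")
  fs <- 1 / stats::median(diff(df$time_s))
  emg_recording(t(as.matrix(df[, -1L, drop = FALSE])), fs = round(fs, 6),
                stage = stage, muscle_labels = names(df)[-1L])
}

#' Read and write keypoint trajectories as CSV
#'
#' Schema: header
#' `time_s,inner_eyebrow,outer_eyebrow,nose,mouth_corner,chin`; one signed
#' scalar displacement per point per sample.
#'
#' @param kp A [keypoint_trajectories].
#' @param path File path.
#' @return `write_keypoints_csv` returns `path` invisibly;
#'   `read_keypoints_csv` returns a [keypoint_trajectories].
#' @export
write_keypoints_csv <- function(kp, path) {
  stopifnot(inherits(kp, "keypoint_trajectories"))
  df <- data.frame(time_s = (seq_len(ncol(kp$displacements)) - 1) / kp$fs,
                   t(kp$displacements), check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_keypoints_csv
#' @export
read_keypoints_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  fs <- 1 / stats::median(diff(df$time_s))
  keypoint_trajectories(t(as.matrix(df[, -1L, drop = FALSE])),
                        fs = round(fs, 6), point_labels = names(df)[-1L])
}

#' Read and write trial structures as JSON
#'
#' A JSON array of segment objects `{trial, repetition, label, start_s,
#' end_s}`.
#'
#' @param structure A [trial_structure()].
#' @param path File path.
#' @return `write_trial_structure` returns `path` invisibly;
#'   `read_trial_structure` returns a [trial_structure()].
#' @export
write_trial_structure <- function(structure, path) {
  jsonlite::write_json(as.data.frame(structure), path, digits = NA)
  invisible(path)
}

#' @rdname write_trial_structure
#' @export
read_trial_structure <- function(path) {
  trial_structure(jsonlite::fromJSON(path))
}

#' Save a synergy decomposition
#'
#' The synergy matrix, rank and VAF go to JSON; the activation
#' coefficients to CSV (`time_s,syn1..synK`).
#'
#' @param decomp A `synergy_decomposition`.
#' @param json_path,csv_path Output paths.
#' @param fs Sampling rate of the activation coefficients.
#' @return Invisibly, the JSON path.
#' @export
write_decomposition <- function(decomp, json_path, csv_path, fs) {
  stopifnot(inherits(decomp, "synergy_decomposition"))
  jsonlite::write_json(list(Ws = decomp$Ws, rank = decomp$rank,
                            vaf_percent = decomp$vaf_percent,
                            muscles = rownames(decomp$Ws)),
                       json_path, digits = NA, matrix = "rowmajor")
  df <- data.frame(time_s = (seq_len(ncol(decomp$C)) - 1) / fs,
                   t(decomp$C), check.names = FALSE)
  data.table::fwrite(df, csv_path)
  invisible(json_path)
}
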