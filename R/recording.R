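#' Canonical muscle and keypoint names
#'
#' The seven recorded facial muscles, in the fixed channel order used
#' throughout the package: inner frontalis (IF), outer frontalis (OF),
#' corrugator supercilii (CS), levator labii superioris alaeque nasi
#' (LLSAN), zygomaticus major (ZM), depressor anguli oris (DAO) and
#' mentalis (Me).
#'
#' @format Character vectors.
#' @name canonical-names
NULL

#' @rdname canonical-names
#' @export
FACE_MUSCLES <- c("IF", "OF", "CS", "LLSAN", "ZM", "DAO", "Me")

#' @rdname canonical-names
#' @export
FACE_KEYPOINTS <- c("inner_eyebrow", "outer_eyebrow", "nose", "mouth_corner", "chin")

#' @rdname canonical-names
#' @export
FACE_EXPRESSIONS <- c("anger", "disgust", "fear", "happiness", "sadness", "surprise")

EMG_STAGES <- c("raw", "bandpassed", "rectified", "normalized", "envelope", "downsampled")

#' Multichannel sEMG recording container
#'
#' A light S3 container holding a channels-by-time sample matrix together
#' with its sampling rate, channel labels and processing stage. Stages
#' after rectification must be non-negative; the stage field is what the
#' preprocessing operations use to enforce call order.
#'
#' @param samples Numeric matrix, channels x time.
#' @param fs Sampling rate in Hz.
#' @param stage One of `"raw"`, `"bandpassed"`, `"rectified"`,
#'   `"normalized"`, `"envelope"`, `"downsampled"`.
#' @param muscle_labels Channel names; defaults to the canonical 7-muscle
#'   order in [FACE_MUSCLES].
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, stage = "raw", muscle_labels = FACE_MUSCLES) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  stage <- match.arg(stage, EMG_STAGES)
  if (length(muscle_labels) != nrow(samples))
    stop("number of muscle labels (", length(muscle_labels),
         ") does not match channel count (", nrow(samples), ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (stage %in% c("rectified", "normalized", "envelope", "downsampled") &&
      any(samples < 0))
    stop("stage '", stage, "' requires non-negative samples")
  rownames(samples) <- muscle_labels
  structure(list(samples = samples, fs = fs, stage = stage,
                 muscle_labels = muscle_labels),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.1f s), stage: %s\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs, x$stage))
  cat("  channels:", paste(x$muscle_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.emg_recording <- function(x) dim(x$samples)

#' Facial keypoint displacement trajectories
#'
#' Signed scalar displacements of the five tracked facial keypoints along
#' their dominant motion axis (elevation-positive for the eyebrow, nose
#' and chin points; zygomaticus-pull-positive for the mouth corner),
#' sampled at the video rate.
#'
#' @param displacements Numeric matrix, 5 x time.
#' @param fs Sampling rate in Hz (video rate, default 25).
#' @param point_labels Keypoint names, canonical order of [FACE_KEYPOINTS].
#' @return An object of class `keypoint_trajectories`.
#' @export
keypoint_trajectories <- function(displacements, fs = 25,
                                  point_labels = FACE_KEYPOINTS) {
  if (!is.matrix(displacements)) displacements <- matrix(displacements, nrow = 1L)
  if (nrow(displacements) != length(point_labels))
    stop("displacements must have one row per keypoint")
  rownames(displacements) <- point_labels
  structure(list(displacements = displacements, fs = fs,
                 point_labels = point_labels),
            class = "keypoint_trajectories")
}

#' @export
print.keypoint_trajectories <- function(x, ...) {
  cat(sprintf("<keypoint_trajectories> %d points x %d samples @ %g Hz\n",
              nrow(x$displacements), ncol(x$displacements), x$fs))
  invisible(x)
}

#' Trial structure: labelled, non-overlapping segments
#'
#' Ordered annotation of a recording as half-open time segments
#' `[start_s, end_s)` carrying the trial index, the repetition index and a
#' label (`"neutral"` or one of the six expressions).
#'
#' @param segments A data.frame with columns `trial`, `repetition`,
#'   `label`, `start_s`, `end_s`.
#' @return An object of class `trial_structure` (a data.frame).
#' @export
trial_structure <- function(segments) {
  need <- c("trial", "repetition", "label", "start_s", "end_s")
  if (!all(need %in% names(segments)))
    stop("segments must have columns: ", paste(need, collapse = ", "))
  segments <- as.data.frame(segments)[, need]
  if (nrow(segments) > 1L) {
    o <- order(segments$start_s)
    segments <- segments[o, , drop = FALSE]
    if (any(segments$end_s[-nrow(segments)] > segments$start_s[-1L] + 1e-9))
      stop("segments overlap")
  }
  if (any(segments$end_s <= segments$start_s))
    stop("segments must have positive duration")
  rownames(segments) <- NULL
  class(segments) <- c("trial_structure", "data.frame")
  segments
}

#' @export
print.trial_structure <- function(x, ...) {
  cat(sprintf("<trial_structure> %d segments, %.1f s total\n",
              nrow(x), sum(x$end_s - x$start_s)))
  NextMethod()
}

# label of the segment containing each time point (NA outside all segments)
segment_labels_at <- function(structure, times) {
  lab <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(structure))) {
    sel <- times >= structure$start_s[i] - 1e-9 & times < structure$end_s[i] - 1e-9
    lab[sel] <- structure$label[i]
  }
  lab
}

# evaluate .Random.seed-safe seeded expressions
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed derivation; keeps results < 2^31
derive_seed <- function(master, ...) {
  ids <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in ids) s <- (s * 69069 + as.double(k) * 1234567 + 1) %% 2147483647
  as.integer(s)
}
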