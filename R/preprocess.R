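# Filter designs are standard sEMG practice: zero-phase (filtfilt)
# 4th-order Butterworth, 20-450 Hz band-pass for raw sEMG and 2 Hz
# low-pass for enveloping. Zero-phase filtering avoids lag between the
# sEMG envelopes and the video-tracked keypoints.

butter_bandpass <- function(fs, low = 20, high = 450, order = 4L) {
  if (fs <= 2 * high) stop("sampling rate ", fs, " Hz too low for a ", high,
                           " Hz band edge")
  signal::butter(order, c(low, high) / (fs / 2), type = "pass")
}

butter_lowpass <- function(fs, cutoff = 2, order = 4L) {
  signal::butter(order, cutoff / (fs / 2), type = "low")
}

# zero-phase filtering with odd-reflection end padding, so edge
# transients decay inside the pad instead of ringing into the data
# (plain filtfilt zero-pads, which distorts segment ends badly at a
# 2 Hz corner)
filtfilt_padded <- function(flt, x) {
  n <- length(x)
  L <- min(n - 1L, 3072L)
  head_pad <- 2 * x[1L] - x[(L + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - L)]
  y <- signal::filtfilt(flt, c(head_pad, x, tail_pad))
  y[(L + 1L):(L + n)]
}

apply_filtfilt <- function(samples, flt) {
  t(apply(samples, 1L, function(x) filtfilt_padded(flt, x)))
}

# indices of the samples nearest each 1/fs_out tick from t = 0
video_tick_index <- function(n, fs, fs_out) {
  ticks <- seq(0, by = 1 / fs_out, length.out = floor((n - 1) / fs * fs_out) + 1L)
  pmin(n, round(ticks * fs) + 1L)
}

#' Band-pass filter and rectify raw sEMG
#'
#' Zero-phase 4th-order Butterworth band-pass (20-450 Hz) followed by
#' full-wave rectification.
#'
#' @param raw An [emg_recording] at stage `"raw"`.
#' @return An [emg_recording] at stage `"rectified"`, same length.
#' @export
bandpass_rectify <- function(raw) {
  stopifnot(inherits(raw, "emg_recording"))
  if (raw$stage != "raw") stop("bandpass_rectify expects stage 'raw', got '",
                               raw$stage, "'")
  if (raw$fs <= 900) stop("fs = ", raw$fs, " Hz is too low for the 450 Hz band edge")
  flt <- butter_bandpass(raw$fs)
  emg_recording(abs(apply_filtfilt(raw$samples, flt)), fs = raw$fs,
                stage = "rectified", muscle_labels = raw$muscle_labels)
}

#' Per-muscle MVC profile from a rectified MVC-task recording
#'
#' The per-channel maximum of the 2 Hz low-pass filtered rectified signal
#' over the whole MVC task. The smoothed maximum is used rather than the
#' raw rectified peak so single-sample spikes cannot inflate the profile.
#'
#' @param mvc_rectified An [emg_recording] at stage `"rectified"`, or a
#'   list of them (multiple MVC trials; the maximum is taken across all).
#' @return Named numeric vector of per-muscle maxima (class `mvc_profile`).
#' @export
compute_mvc <- function(mvc_rectified) {
  recs <- if (inherits(mvc_rectified, "emg_recording")) list(mvc_rectified)
          else mvc_rectified
  prof <- NULL
  for (rec in recs) {
    stopifnot(inherits(rec, "emg_recording"))
    if (rec$stage != "rectified") stop("compute_mvc expects stage 'rectified'")
    flt <- butter_lowpass(rec$fs)
    sm <- apply_filtfilt(rec$samples, flt)
    mx <- apply(sm, 1L, max)
    prof <- if (is.null(prof)) mx else pmax(prof, mx)
    labels <- rec$muscle_labels
  }
  names(prof) <- labels
  if (any(prof <= 0)) stop("dead channel(s) in MVC task: ",
                           paste(labels[prof <= 0], collapse = ", "))
  class(prof) <- "mvc_profile"
  prof
}

#' @export
print.mvc_profile <- function(x, ...) {
  cat("<mvc_profile>\n"); print(unclass(x)); invisible(x)
}

#' Normalize by MVC and extract the linear envelope
#'
#' Divides each rectified channel by its MVC profile value, then applies
#' a zero-phase 4th-order Butterworth low-pass at 2 Hz. Small negative
#' undershoots of the zero-phase filter are clipped at 0 so the envelope
#' satisfies the non-negativity required by NMF.
#'
#' @param rectified An [emg_recording] at stage `"rectified"`.
#' @param mvc An `mvc_profile` from [compute_mvc()].
#' @return An [emg_recording] at stage `"envelope"` (dimensionless,
#'   fraction of MVC).
#' @export
normalize_and_envelope <- function(rectified, mvc) {
  stopifnot(inherits(rectified, "emg_recording"))
  if (rectified$stage != "rectified")
    stop("normalize_and_envelope expects stage 'rectified'")
  if (length(mvc) != nrow(rectified$samples))
    stop("MVC profile has ", length(mvc), " channels but recording has ",
         nrow(rectified$samples))
  x <- sweep(rectified$samples, 1L, as.numeric(mvc), "/")
  flt <- butter_lowpass(rectified$fs)
  env <- pmax(apply_filtfilt(x, flt), 0)
  emg_recording(env, fs = rectified$fs, stage = "envelope",
                muscle_labels = rectified$muscle_labels)
}

#' Downsample an envelope to the video rate
#'
#' Picks the sample nearest each 40 ms tick from t = 0 (nearest-tick
#' selection, not anti-alias decimation: the 2 Hz envelope is already
#' band-limited far below the 12.5 Hz output Nyquist).
#'
#' @param envelope An [emg_recording] at stage `"envelope"`.
#' @param fs_out Output rate in Hz (default 25).
#' @return An [emg_recording] at stage `"downsampled"`.
#' @export
downsample_to_video <- function(envelope, fs_out = 25) {
  stopifnot(inherits(envelope, "emg_recording"))
  if (envelope$stage != "envelope")
    stop("downsample_to_video expects stage 'envelope'")
  if (fs_out > envelope$fs) stop("fs_out exceeds the input sampling rate")
  idx <- video_tick_index(ncol(envelope$samples), envelope$fs, fs_out)
  emg_recording(envelope$samples[, idx, drop = FALSE], fs = fs_out,
                stage = "downsampled", muscle_labels = envelope$muscle_labels)
}

# ---- transition trimming --------------------------------------------------

# Trimmed [start, end) per segment. Boundaries shared with an adjacent
# segment are label transitions and lose `margin` seconds; the recording
# start/end are not transitions. Interior segments too short to trim are
# an error; edge segments trimmed to nothing are dropped.
trim_segment_table <- function(structure, margin) {
  n <- nrow(structure)
  has_prev <- c(FALSE, abs(structure$start_s[-1L] - structure$end_s[-n]) < 1e-9)
  has_next <- c(has_prev[-1L], FALSE)
  new_start <- structure$start_s + ifelse(has_prev, margin, 0)
  new_end <- structure$end_s - ifelse(has_next, margin, 0)
  keep <- new_end > new_start + 1e-9
  interior <- has_prev & has_next
  if (any(interior & !keep)) {
    i <- which(interior & !keep)[1L]
    stop(sprintf("segment too short to trim %gs margins: trial %d, '%s' [%g, %g)",
                 margin, structure$trial[i], structure$label[i],
                 structure$start_s[i], structure$end_s[i]))
  }
  out <- structure[keep, , drop = FALSE]
  out$start_s <- new_start[keep]
  out$end_s <- new_end[keep]
  out
}

#' Discard data adjacent to expression transitions
#'
#' Removes `margin` seconds of data on each side of every label
#' transition, from the signal and the trial structure alike. The same
#' call applies to sEMG recordings and keypoint trajectories so both
#' streams stay aligned. Returned times are re-based to a contiguous
#' timeline.
#'
#' @param x An [emg_recording] or [keypoint_trajectories].
#' @param structure The matching [trial_structure()].
#' @param margin Seconds trimmed on each side of a transition (default 1).
#' @return `list(data = <trimmed x>, structure = <updated structure>)`.
#' @export
trim_transitions <- function(x, structure, margin = 1) {
  stopifnot(inherits(structure, "trial_structure"))
  if (margin < 0) stop("margin must be >= 0")
  if (margin == 0) return(list(data = x, structure = structure))
  tab <- trim_segment_table(structure, margin)
  mat <- if (inherits(x, "emg_recording")) x$samples else x$displacements
  fs <- x$fs
  times <- (seq_len(ncol(mat)) - 1) / fs
  keep_idx <- integer(0)
  new_segs <- tab
  t_acc <- 0
  for (i in seq_len(nrow(tab))) {
    sel <- which(times >= tab$start_s[i] - 1e-9 & times < tab$end_s[i] - 1e-9)
    keep_idx <- c(keep_idx, sel)
    dur <- length(sel) / fs
    new_segs$start_s[i] <- t_acc
    new_segs$end_s[i] <- t_acc + dur
    t_acc <- t_acc + dur
  }
  out_mat <- mat[, keep_idx, drop = FALSE]
  data <- if (inherits(x, "emg_recording"))
    emg_recording(out_mat, fs = fs, stage = x$stage, muscle_labels = x$muscle_labels)
  else keypoint_trajectories(out_mat, fs = fs, point_labels = x$point_labels)
  list(data = data, structure = trial_structure(new_segs))
}

# ---- trial reordering -----------------------------------------------------

# slice [t0, t1) out of a trimmed trial's emg/keypoints
slice_stream <- function(x, t0, t1) {
  mat <- if (inherits(x, "emg_recording")) x$samples else x$displacements
  times <- (seq_len(ncol(mat)) - 1) / x$fs
  sel <- times >= t0 - 1e-9 & times < t1 - 1e-9
  mat[, sel, drop = FALSE]
}

#' Build reordered trials mixing all six expressions
#'
#' For each repetition slot, draws (without replacement) one expression
#' segment together with its preceding neutral context from each of the
#' six single-expression trials, shuffles the order of the six chunks and
#' concatenates them. Each reordered trial therefore contains every
#' expression exactly once, interleaved with neutral segments.
#'
#' @param trials List of 6 trimmed trials; each element is a list with
#'   `emg` ([emg_recording]), optional `keypoints`
#'   ([keypoint_trajectories]) and `structure` ([trial_structure]).
#' @param seed Integer seed controlling repetition draws and chunk order.
#' @param context_s Seconds of preceding neutral kept with each
#'   expression segment (default 3).
#' @return List of `n_repetitions` reordered trials, each a list with
#'   `emg`, `keypoints` (if supplied) and `structure`.
#' @export
reorder_trials <- function(trials, seed, context_s = 3) {
  if (length(trials) != 6L) stop("expected 6 single-expression trials")
  n_rep <- length(unique(trials[[1L]]$structure$repetition[
    trials[[1L]]$structure$label != "neutral"]))
  for (tr in trials) {
    reps <- unique(tr$structure$repetition[tr$structure$label != "neutral"])
    if (length(reps) != n_rep) stop("missing repetition in a trial: found ",
                                    length(reps), ", expected ", n_rep)
  }
  # per trial: random assignment of repetitions to slots; per slot: order
  draws <- with_seed(seed, {
    perm <- lapply(1:6, function(i) sample.int(n_rep))
    ord <- lapply(seq_len(n_rep), function(r) sample.int(6L))
    list(perm = perm, ord = ord)
  })
  has_kp <- !is.null(trials[[1L]]$keypoints)
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    emg_parts <- list(); kp_parts <- list(); seg_parts <- list()
    t_acc <- 0
    for (trial in draws$ord[[r]]) {
      st <- trials[[trial]]$structure
      rep_id <- draws$perm[[trial]][r]
      ei <- which(st$label != "neutral" & st$repetition == rep_id)
      if (length(ei) != 1L) stop("missing repetition ", rep_id, " in trial ", trial)
      ni <- ei - 1L
      if (ni < 1L || st$label[ni] != "neutral")
        stop("expression segment lacks preceding neutral context")
      ctx <- min(context_s, st$end_s[ni] - st$start_s[ni])
      t0 <- st$end_s[ni] - ctx
      emg_parts[[length(emg_parts) + 1L]] <- slice_stream(trials[[trial]]$emg, t0, st$end_s[ei])
      if (has_kp)
        kp_parts[[length(kp_parts) + 1L]] <-
          slice_stream(trials[[trial]]$keypoints, t0, st$end_s[ei])
      expr_dur <- st$end_s[ei] - st$start_s[ei]
      seg_parts[[length(seg_parts) + 1L]] <- data.frame(
        trial = st$trial[ei], repetition = rep_id,
        label = c("neutral", st$label[ei]),
        start_s = t_acc + c(0, ctx),
        end_s = t_acc + c(ctx, ctx + expr_dur))
      t_acc <- t_acc + ctx + expr_dur
    }
    emg0 <- trials[[1L]]$emg
    res <- list(emg = emg_recording(do.call(cbind, emg_parts), fs = emg0$fs,
                                    stage = emg0$stage,
                                    muscle_labels = emg0$muscle_labels),
                structure = trial_structure(do.call(rbind, seg_parts)))
    if (has_kp)
      res$keypoints <- keypoint_trajectories(do.call(cbind, kp_parts),
                                             fs = trials[[1L]]$keypoints$fs)
    out[[r]] <- res
  }
  out
}
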