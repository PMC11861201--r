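# Sliding-window time-domain features: per window and channel the root
# mean square RMS = sqrt(mean(x^2)), population variance
# VAR = mean((x - mean)^2), mean absolute value MAV = mean(|x|) and
# integrated EMG IEMG = sum(|x|) = R * MAV.

#' Sliding-window feature extraction
#'
#' Computes RMS, VAR (1/R normalisation), MAV and IEMG per channel over a
#' sliding window, separately within every labelled segment so that no
#' window straddles a label boundary. The window label is the segment
#' label.
#'
#' @param X Channels x time matrix (synergy activations or sEMG
#'   envelopes) or an [emg_recording].
#' @param structure [trial_structure()] labelling the samples of `X`.
#' @param fs Sampling rate of `X` (taken from the recording if omitted).
#' @param window Window length in samples (default 125; about 122 ms at
#'   1024 Hz, the count entering the feature formulas; 150 ms is the
#'   nominal design value).
#' @param step Step between window starts in samples (default: 40 ms at
#'   `fs`).
#' @return A data.frame of class `feature_table` with columns
#'   `t_center_s`, `label`, then `<channel>_{rms,var,mav,iemg}`.
#' @export
sliding_features <- function(X, structure, fs = NULL, window = 125L,
                             step = NULL) {
  if (inherits(X, "emg_recording")) {
    if (is.null(fs)) fs <- X$fs
    chan <- X$muscle_labels
    X <- X$samples
  } else {
    X <- as.matrix(X)
    if (is.null(fs)) stop("fs is required for a plain matrix")
    chan <- rownames(X)
    if (is.null(chan)) chan <- paste0("ch", seq_len(nrow(X)))
  }
  if (is.null(step)) step <- max(1L, round(0.040 * fs))
  window <- as.integer(window); step <- as.integer(step)
  if (window < 2L) stop("window must be >= 2 samples")
  if (step < 1L) stop("step must be >= 1 sample")

  seg_rows <- list()
  for (i in seq_len(nrow(structure))) {
    i0 <- round(structure$start_s[i] * fs) + 1L
    i1 <- min(round(structure$end_s[i] * fs), ncol(X))
    nseg <- i1 - i0 + 1L
    if (nseg < window)
      stop(sprintf("window (%d samples) longer than segment: trial %d, '%s' [%g, %g)",
                   window, structure$trial[i], structure$label[i],
                   structure$start_s[i], structure$end_s[i]))
    starts <- seq.int(i0, i1 - window + 1L, by = step)
    feats <- matrix(0, length(starts), 4L * nrow(X))
    for (j in seq_len(nrow(X))) {
      x <- X[j, i0:i1]
      cs2 <- c(0, cumsum(x^2)); csa <- c(0, cumsum(abs(x))); cs <- c(0, cumsum(x))
      s_rel <- starts - i0 + 1L
      sum2 <- cs2[s_rel + window] - cs2[s_rel]
      suma <- csa[s_rel + window] - csa[s_rel]
      sum1 <- cs[s_rel + window] - cs[s_rel]
      mav <- suma / window
      feats[, 4L * (j - 1L) + 1L] <- sqrt(sum2 / window)
      feats[, 4L * (j - 1L) + 2L] <- pmax(0, sum2 / window - (sum1 / window)^2)
      feats[, 4L * (j - 1L) + 3L] <- mav
      feats[, 4L * (j - 1L) + 4L] <- suma
    }
    colnames(feats) <- as.vector(t(outer(chan, c("rms", "var", "mav", "iemg"),
                                         paste, sep = "_")))
    seg_rows[[i]] <- data.frame(
      t_center_s = (starts - 1L + (window - 1L) / 2) / fs,
      label = structure$label[i], feats, check.names = FALSE)
  }
  out <- do.call(rbind, seg_rows)
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "channels") <- chan
  class(out) <- c("feature_table", "data.frame")
  out
}
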