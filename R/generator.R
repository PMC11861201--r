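#' Default ground-truth synergy matrix
#'
#' Three muscle synergies over the seven canonical channels, encoding the
#' coordination structure observed for basic facial expressions: synergy 1
#' loads corrugator supercilii, levator labii and depressor anguli oris;
#' synergy 2 loads the inner/outer frontalis, depressor anguli oris and
#' mentalis; synergy 3 loads zygomaticus major and depressor anguli oris.
#' Columns are normalised to unit Euclidean norm.
#'
#' @return A 7 x 3 non-negative matrix with unit-norm columns.
#' @export
default_synergy_matrix <- function() {
  W <- matrix(0, nrow = 7L, ncol = 3L,
              dimnames = list(FACE_MUSCLES, paste0("syn", 1:3)))
  W[c("CS", "LLSAN", "DAO"), 1L] <- c(0.80, 0.70, 0.40)
  W[c("IF", "OF", "DAO", "Me"), 2L] <- c(0.70, 0.70, 0.30, 0.50)
  W[c("ZM", "DAO"), 3L] <- c(0.90, 0.45)
  sweep(W, 2L, sqrt(colSums(W^2)), "/")
}

#' Default expression-to-synergy activation map
#'
#' Mean synergy amplitudes (fraction of MVC) driving each expression:
#' anger, surprise and happiness are single-synergy expressions (synergies
#' 1, 2 and 3 respectively); sadness combines synergies 1+2, fear 2+3 and
#' disgust all three. Neutral maps to zero.
#'
#' @return A 7 x 3 matrix (expressions incl. neutral, by synergy).
#' @export
default_activation_map <- function() {
  m <- rbind(
    neutral   = c(0.0, 0.0, 0.0),
    anger     = c(0.8, 0.0, 0.0),
    disgust   = c(0.5, 0.4, 0.5),
    fear      = c(0.0, 0.5, 0.5),
    happiness = c(0.0, 0.0, 0.8),
    sadness   = c(0.5, 0.5, 0.0),
    surprise  = c(0.0, 0.8, 0.0)
  )
  colnames(m) <- paste0("syn", 1:3)
  m
}

#' Default cross-keypoint skin-coupling matrix
#'
#' Identity plus mild positive off-diagonal coupling between anatomically
#' adjacent points (inner/outer eyebrow; nose/inner structures;
#' mouth corner/chin), representing skin continuity between keypoints
#' that the per-point spring systems do not capture.
#'
#' @return A 5 x 5 matrix.
#' @export
default_coupling_matrix <- function() {
  K <- diag(5)
  dimnames(K) <- list(FACE_KEYPOINTS, FACE_KEYPOINTS)
  K["inner_eyebrow", "outer_eyebrow"] <- 0.20
  K["outer_eyebrow", "inner_eyebrow"] <- 0.20
  K["nose", "inner_eyebrow"] <- 0.10
  K["mouth_corner", "chin"] <- 0.15
  K["chin", "mouth_corner"] <- 0.10
  K
}

#' Generator configuration
#'
#' Bundles every parameter of the synthetic facial-sEMG study: task
#' timing, the ground-truth synergy structure, the expression activation
#' map, the noise model and the ground-truth skin-musculoskeletal
#' parameters and coupling used to produce keypoint displacements.
#'
#' The noise model has four dials: `baseline_sd` (white sensor noise, as a
#' fraction of the mean MVC amplitude), `signal_dependent_coeff`
#' (multiplicative noise whose amplitude is proportional to the momentary
#' envelope), `crosstalk_fraction` (fraction of each channel mixed into
#' the others) and `keypoint_noise_sd` (additive tracking noise on the
#' displacements, in displacement units).
#'
#' @param seed Master seed; all participant streams derive from it.
#' @param n_participants Number of simulated participants.
#' @param n_repetitions Expression repetitions per trial (default 12).
#' @param fs_emg sEMG sampling rate in Hz (default 1024).
#' @param fs_video Video/keypoint rate in Hz (default 25).
#' @param expression_duration Expression hold duration in seconds (default 5).
#' @param neutral_duration Leading neutral duration per cycle in seconds
#'   (default 5); each cycle ends with a fixed 1 s neutral tail.
#' @param synergy_matrix_true 7 x 3 non-negative matrix, unit-norm columns.
#' @param expression_activation_map Matrix of mean synergy amplitudes per
#'   expression (rows named neutral + six expressions).
#' @param noise Named list; see Details above.
#' @param smsm_params_true Ground-truth [smsm_parameters()].
#' @param coupling_true 5 x 5 cross-keypoint coupling matrix.
#' @param amp_jitter_sdlog Log-normal sd of the trial-to-trial amplitude
#'   jitter (default 0.1).
#' @param participant_sd Per-participant perturbation sd applied to the
#'   synergy matrix (columns renormalised; default 0.05).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 0L,
                             n_participants = 10L,
                             n_repetitions = 12L,
                             fs_emg = 1024,
                             fs_video = 25,
                             expression_duration = 5,
                             neutral_duration = 5,
                             synergy_matrix_true = default_synergy_matrix(),
                             expression_activation_map = default_activation_map(),
                             noise = list(baseline_sd = 0.02,
                                          signal_dependent_coeff = 0.1,
                                          crosstalk_fraction = 0.05,
                                          keypoint_noise_sd = 2e-4),
                             smsm_params_true = default_smsm_parameters(),
                             coupling_true = default_coupling_matrix(),
                             amp_jitter_sdlog = 0.1,
                             participant_sd = 0.05) {
  if (expression_duration <= 0 || neutral_duration <= 0 || fs_emg <= 0 || fs_video <= 0)
    stop("durations and sampling rates must be positive")
  W <- as.matrix(synergy_matrix_true)
  if (any(W < 0)) stop("synergy_matrix_true must be non-negative")
  if (any(abs(sqrt(colSums(W^2)) - 1) > 1e-8))
    stop("synergy_matrix_true columns must have unit Euclidean norm")
  A <- as.matrix(expression_activation_map)
  want <- c("neutral", FACE_EXPRESSIONS)
  if (!setequal(rownames(A), want))
    stop("expression_activation_map must cover exactly neutral + the six expressions")
  A <- A[want, , drop = FALSE]
  if (any(abs(A["neutral", ]) > 0)) stop("neutral must map to the zero activation vector")
  for (nm in c("baseline_sd", "signal_dependent_coeff", "crosstalk_fraction",
               "keypoint_noise_sd")) {
    if (is.null(noise[[nm]]) || noise[[nm]] < 0)
      stop("noise$", nm, " must be present and >= 0")
  }
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 n_repetitions = as.integer(n_repetitions),
                 fs_emg = fs_emg, fs_video = fs_video,
                 expression_duration = expression_duration,
                 neutral_duration = neutral_duration,
                 post_neutral = 1,
                 ramp = 0.5,
                 synergy_matrix_true = W,
                 expression_activation_map = A,
                 noise = noise,
                 smsm_params_true = smsm_params_true,
                 coupling_true = as.matrix(coupling_true),
                 amp_jitter_sdlog = amp_jitter_sdlog,
                 participant_sd = participant_sd),
            class = "generator_config")
}

# ---- internal helpers -----------------------------------------------------

# stream ids used to fan the master seed out per participant
.GEN_STREAMS <- c(amp = 1L, synergy = 2L, jitter = 3L, carrier = 4L,
                  keypoint = 5L, mvc_carrier = 6L)

gen_seed <- function(config, participant, stream) {
  derive_seed(config$seed, participant, .GEN_STREAMS[[stream]])
}

# participant-level ground truth that both tasks must agree on
participant_truth <- function(config, participant) {
  amp <- with_seed(gen_seed(config, participant, "amp"), stats::runif(1, 0.5, 1.5))
  Ws <- with_seed(gen_seed(config, participant, "synergy"), {
    P <- abs(matrix(stats::rnorm(21, sd = config$participant_sd), 7L, 3L))
    W <- config$synergy_matrix_true + P * (config$synergy_matrix_true > 0)
    sweep(W, 2L, sqrt(colSums(W^2)), "/")
  })
  # per (trial, repetition, synergy) log-normal amplitude jitter
  jit <- with_seed(gen_seed(config, participant, "jitter"),
                   array(stats::rlnorm(6L * config$n_repetitions * 3L,
                                       sdlog = config$amp_jitter_sdlog),
                         dim = c(6L, config$n_repetitions, 3L)))
  list(amp = amp, Ws = Ws, jitter = jit)
}

# smoothed trapezoid rising over `ramp` s, holding, falling over `ramp` s
trapezoid <- function(n, fs, ramp) {
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  pmin(1, pmin(t / ramp, pmax(0, (dur - t) / ramp)))
}

# band-limited unit-variance Gaussian carrier (20-450 Hz at fs)
bandlimited_carrier <- function(n, fs) {
  x <- stats::rnorm(n)
  flt <- butter_bandpass(fs)
  y <- signal::filtfilt(flt, x)
  y / stats::sd(y)
}

# segment table for one expression-task trial (trial index `trial`,
# expression `label`): N(neu) E(expr) N(1+neu) E ... E N(1)
expression_trial_structure <- function(config, trial, label) {
  neu <- config$neutral_duration
  expd <- config$expression_duration
  post <- config$post_neutral
  segs <- list()
  t0 <- 0
  for (r in seq_len(config$n_repetitions)) {
    lead <- if (r == 1L) neu else post + neu
    segs[[length(segs) + 1L]] <- data.frame(trial = trial, repetition = r,
                                            label = "neutral",
                                            start_s = t0, end_s = t0 + lead)
    t0 <- t0 + lead
    segs[[length(segs) + 1L]] <- data.frame(trial = trial, repetition = r,
                                            label = label,
                                            start_s = t0, end_s = t0 + expd)
    t0 <- t0 + expd
  }
  segs[[length(segs) + 1L]] <- data.frame(trial = trial,
                                          repetition = config$n_repetitions,
                                          label = "neutral",
                                          start_s = t0, end_s = t0 + post)
  trial_structure(do.call(rbind, segs))
}

# 3 x n synergy activation envelopes for one trial
trial_activation <- function(config, structure, truth, trial, fs) {
  n <- round(max(structure$end_s) * fs)
  C <- matrix(0, 3L, n)
  amap <- config$expression_activation_map
  expr_rows <- which(structure$label != "neutral")
  for (i in expr_rows) {
    lab <- structure$label[i]
    r <- structure$repetition[i]
    i0 <- round(structure$start_s[i] * fs) + 1L
    i1 <- round(structure$end_s[i] * fs)
    tz <- trapezoid(i1 - i0 + 1L, fs, config$ramp)
    for (k in 1:3) {
      a <- amap[lab, k] * truth$jitter[trial, r, k]
      if (a > 0) C[k, i0:i1] <- C[k, i0:i1] + a * tz
    }
  }
  C
}

# raw-like sEMG from muscle envelopes: amplitude-modulated band-limited
# Gaussian carrier whose momentary sd combines the signal envelope, the
# signal-dependent noise (sd proportional to the envelope) and the
# baseline noise in quadrature (the three terms are independent
# zero-mean Gaussians sharing the 20-450 Hz band, so their sum is a
# Gaussian with the summed variance), then crosstalk mixing
synthesize_raw <- function(E, fs, noise, baseline_abs) {
  m <- nrow(E); n <- ncol(E)
  raw <- matrix(0, m, n)
  gain2 <- 1 + noise$signal_dependent_coeff^2
  for (j in seq_len(m)) {
    sd_t <- sqrt(gain2 * E[j, ]^2 + baseline_abs^2)
    raw[j, ] <- sd_t * bandlimited_carrier(n, fs)
  }
  f <- noise$crosstalk_fraction
  if (f > 0) {
    M <- diag(1 - f, m) + matrix(f / (m - 1), m, m) -
      diag(f / (m - 1), m)
    raw <- M %*% raw
  }
  raw
}

# ---- operations -----------------------------------------------------------

#' Generate one participant's facial-expression task
#'
#' Simulates the six-trial expression task (one expression per trial,
#' `n_repetitions` neutral/expression cycles per trial). Per repetition a
#' smoothed trapezoidal synergy activation (0.5 s rise/fall) is scaled by
#' the expression's activation map entry and log-normal trial-to-trial
#' jitter; muscle envelopes are `Ws_true %*% c(t)`; the raw-like sEMG is
#' an amplitude-modulated 20-450 Hz Gaussian carrier plus
#' signal-dependent and baseline noise and crosstalk. Keypoint
#' displacements are the SMSM forward equilibria of the noise-free
#' normalised envelopes, multiplied by the coupling matrix, sampled at the
#' video rate, plus Gaussian tracking noise.
#'
#' @param config A [generator_config()].
#' @param participant Participant index (1-based).
#' @return A list with elements `emg` (list of 6 raw [emg_recording]s),
#'   `keypoints` (list of 6 [keypoint_trajectories]), `structure` (list of
#'   6 [trial_structure]s) and `truth` (ground-truth sidecar: `Ws_true`,
#'   per-trial activation envelopes `C_true` and muscle envelopes
#'   `envelopes`, per-muscle MVC amplitudes `mvc_amp`, SMSM parameters,
#'   coupling and amplitude scale).
#' @export
generate_expression_task <- function(config, participant) {
  stopifnot(inherits(config, "generator_config"))
  if (participant < 1L || participant > config$n_participants)
    stop("participant index out of range")
  truth <- participant_truth(config, participant)
  fs <- config$fs_emg
  structures <- vector("list", 6L)
  C_true <- vector("list", 6L)
  E_true <- vector("list", 6L)
  for (trial in 1:6) {
    structures[[trial]] <- expression_trial_structure(config, trial,
                                                      FACE_EXPRESSIONS[trial])
    C_true[[trial]] <- trial_activation(config, structures[[trial]], truth, trial, fs)
    E_true[[trial]] <- truth$amp * (truth$Ws %*% C_true[[trial]])
  }
  mvc_amp <- apply(do.call(cbind, E_true), 1L, max)
  names(mvc_amp) <- FACE_MUSCLES
  baseline_abs <- config$noise$baseline_sd * mean(mvc_amp)

  emg <- vector("list", 6L)
  kps <- vector("list", 6L)
  for (trial in 1:6) {
    emg[[trial]] <- with_seed(derive_seed(gen_seed(config, participant, "carrier"), trial),
      emg_recording(synthesize_raw(E_true[[trial]], fs, config$noise, baseline_abs),
                    fs = fs, stage = "raw"))
    # keypoints: SMSM forward on normalised noise-free envelopes at video rate
    U <- sweep(E_true[[trial]], 1L, mvc_amp, "/")
    idx <- video_tick_index(ncol(U), fs, config$fs_video)
    Uv <- U[, idx, drop = FALSE]
    D <- config$coupling_true %*% smsm_forward(config$smsm_params_true, Uv)
    if (config$noise$keypoint_noise_sd > 0)
      D <- D + with_seed(derive_seed(gen_seed(config, participant, "keypoint"), trial),
                         matrix(stats::rnorm(length(D),
                                             sd = config$noise$keypoint_noise_sd),
                                nrow(D), ncol(D)))
    kps[[trial]] <- keypoint_trajectories(D, fs = config$fs_video)
  }
  list(emg = emg, keypoints = kps, structure = structures,
       truth = list(Ws_true = truth$Ws, C_true = C_true, envelopes = E_true,
                    mvc_amp = mvc_amp, amp = truth$amp,
                    smsm_params = config$smsm_params_true,
                    coupling = config$coupling_true))
}

#' Generate one participant's MVC task
#'
#' Five 40 s trials of five 4 s neutral / 4 s action cycles. Each action
#' drives a designated muscle subset at that participant's maximum
#' expression-task envelope amplitude, so that MVC normalisation maps the
#' expression task into [0, 1]. Action-to-muscle mapping: (1) eyebrow
#' elevation IF+OF, (2) eyebrow furrowing and nose elevation CS+LLSAN,
#' (3) mouth-corner elevation ZM, (4) mouth-corner depression DAO,
#' (5) chin wrinkling Me.
#'
#' @inheritParams generate_expression_task
#' @return A list with `emg` (list of 5 raw [emg_recording]s),
#'   `structure` (list of 5 [trial_structure]s) and `truth` (programmed
#'   per-muscle maxima `mvc_amp`).
#' @export
generate_mvc_task <- function(config, participant) {
  stopifnot(inherits(config, "generator_config"))
  if (participant < 1L || participant > config$n_participants)
    stop("participant index out of range")
  truth <- participant_truth(config, participant)
  # reproduce the expression task's realized per-muscle maxima without
  # synthesizing its signals: trapezoid peak = plateau amplitude
  amap <- config$expression_activation_map
  mvc_amp <- rep(0, 7L)
  for (trial in 1:6) {
    for (r in seq_len(config$n_repetitions)) {
      cvec <- amap[FACE_EXPRESSIONS[trial], ] * truth$jitter[trial, r, ]
      mvc_amp <- pmax(mvc_amp, truth$amp * as.vector(truth$Ws %*% cvec))
    }
  }
  names(mvc_amp) <- FACE_MUSCLES
  baseline_abs <- config$noise$baseline_sd * mean(mvc_amp)
  actions <- list(c("IF", "OF"), c("CS", "LLSAN"), "ZM", "DAO", "Me")
  fs <- config$fs_emg
  emg <- vector("list", 5L)
  structures <- vector("list", 5L)
  for (trial in 1:5) {
    segs <- list(); t0 <- 0
    for (r in 1:5) {
      segs[[length(segs) + 1L]] <- data.frame(trial = trial, repetition = r,
                                              label = "neutral",
                                              start_s = t0, end_s = t0 + 4)
      segs[[length(segs) + 1L]] <- data.frame(trial = trial, repetition = r,
                                              label = paste0("action", trial),
                                              start_s = t0 + 4, end_s = t0 + 8)
      t0 <- t0 + 8
    }
    st <- trial_structure(do.call(rbind, segs))
    structures[[trial]] <- st
    n <- round(max(st$end_s) * fs)
    E <- matrix(0, 7L, n, dimnames = list(FACE_MUSCLES, NULL))
    for (i in which(st$label != "neutral")) {
      i0 <- round(st$start_s[i] * fs) + 1L
      i1 <- round(st$end_s[i] * fs)
      tz <- trapezoid(i1 - i0 + 1L, fs, config$ramp)
      for (mus in actions[[trial]])
        E[mus, i0:i1] <- mvc_amp[mus] * tz
    }
    emg[[trial]] <- with_seed(
      derive_seed(gen_seed(config, participant, "mvc_carrier"), trial),
      emg_recording(synthesize_raw(E, fs, config$noise, baseline_abs),
                    fs = fs, stage = "raw"))
  }
  list(emg = emg, structure = structures, truth = list(mvc_amp = mvc_amp))
}
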