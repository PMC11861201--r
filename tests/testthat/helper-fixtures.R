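# Shared fixtures, built lazily and cached for the whole run.

.fixtures <- new.env(parent = emptyenv())

# small study: 1 participant, 2 repetitions per trial (fast but exercises
# the whole generation + preprocessing path)
small_config <- function(seed = 42, ...) {
  generator_config(seed = seed, n_participants = 1, n_repetitions = 2, ...)
}

zero_noise <- list(baseline_sd = 0, signal_dependent_coeff = 0,
                   crosstalk_fraction = 0, keypoint_noise_sd = 0)

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

small_prep <- function() cached("small_prep", prepare_participant(small_config(), 1))

small_task <- function() cached("small_task",
                                generate_expression_task(small_config(), 1))

# independent scalar reimplementation of the spring equilibria, used as
# an oracle against the vectorised forward map
oracle_forward <- function(p, U) {
  D <- matrix(0, 5, ncol(U))
  single <- function(sp, KH, u) (sp[1] + sp[2] * u) * (sp[3] + sp[4] * u) /
    (KH + sp[1] + sp[2] * u)
  dbl <- function(d, KH, u1, u2) {
    num <- den <- 0
    uu <- c(u1, u2)
    for (i in 1:2) {
      s <- d$k0[i] + d$k1[i] * uu[i]
      num <- num + d$a[i] * s * (d$l0[i] + d$l1[i] * uu[i])
      den <- den + d$a[i] * d$lambda[i] * s
    }
    num / (p$KH + den)
  }
  for (t in seq_len(ncol(U))) {
    D[1, t] <- dbl(p$doubles$inner_eyebrow, p$KH, U[1, t], U[3, t])
    D[2, t] <- single(p$singles$outer_eyebrow, p$KH, U[2, t])
    D[3, t] <- single(p$singles$nose, p$KH, U[4, t])
    D[4, t] <- dbl(p$doubles$mouth_corner, p$KH, U[5, t], U[6, t])
    D[5, t] <- single(p$singles$chin, p$KH, U[7, t])
  }
  D
}

# trial structure covering one labelled block, for feature tests
one_segment_structure <- function(label, dur, fs) {
  trial_structure(data.frame(trial = 1, repetition = 1, label = label,
                             start_s = 0, end_s = dur))
}
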