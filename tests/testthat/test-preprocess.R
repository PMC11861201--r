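make_rec <- function(x, fs = 1024, stage = "raw") {
  emg_recording(matrix(x, 7, length(x), byrow = TRUE), fs = fs, stage = stage)
}

test_that("band-pass keeps 100 Hz, rejects 5 Hz, and rectifies", {
  fs <- 1024
  t <- (0:(20 * fs - 1)) / fs
  mid <- 5000:15000
  rec100 <- make_rec(sin(2 * pi * 100 * t))
  out <- bandpass_rectify(rec100)
  expect_gte(max(out$samples[1, mid]), 0.95)
  rec5 <- make_rec(sin(2 * pi * 5 * t))
  out5 <- bandpass_rectify(rec5)
  expect_lte(max(out5$samples[1, mid]), 0.2)
  expect_true(all(out$samples >= 0))
  # zero in, zero out
  z <- bandpass_rectify(make_rec(rep(0, 2048)))
  expect_true(all(z$samples == 0))
  # too-low sampling rate for the 450 Hz edge
  expect_error(bandpass_rectify(make_rec(rep(0, 2048), fs = 800)), "450")
})

test_that("MVC profile is the smoothed per-channel maximum", {
  const <- emg_recording(matrix(2.5, 7, 4096), fs = 1024, stage = "rectified")
  prof <- compute_mvc(const)
  expect_equal(as.numeric(prof), rep(2.5, 7), tolerance = 1e-6)
  # doubling one channel doubles only that channel's value
  x <- matrix(abs(sin(2 * pi * 3 * (0:8191) / 1024)), 7, 8192, byrow = TRUE)
  x2 <- x; x2[4, ] <- 2 * x2[4, ]
  p1 <- compute_mvc(emg_recording(x, 1024, "rectified"))
  p2 <- compute_mvc(emg_recording(x2, 1024, "rectified"))
  expect_equal(p2[[4]], 2 * p1[[4]], tolerance = 1e-12)
  expect_equal(as.numeric(p2[-4]), as.numeric(p1[-4]), tolerance = 1e-12)
  # dead channel
  dead <- matrix(1, 7, 2048); dead[2, ] <- 0
  expect_error(compute_mvc(emg_recording(dead, 1024, "rectified")), "dead")
})

test_that("MVC profile from the synthetic task tracks the programmed maxima", {
  cfg <- small_config(noise = zero_noise)
  mvc_task <- generate_mvc_task(cfg, 1)
  prof <- compute_mvc(lapply(mvc_task$emg, bandpass_rectify))
  # the rectified, 2 Hz-smoothed carrier has mean sqrt(2/pi) x amplitude
  # and a few percent of residual ripple, so the smoothed maximum sits
  # slightly above that mean level, uniformly across channels
  ratio <- as.numeric(prof) / (mvc_task$truth$mvc_amp * sqrt(2 / pi))
  expect_true(all(ratio >= 1 & ratio <= 1.3))
  expect_lt(diff(range(ratio)) / mean(ratio), 0.1)
})

test_that("normalization and enveloping behave as designed", {
  # a rectified channel equal to its MVC value gives an envelope of ~1
  rec <- emg_recording(matrix(3, 7, 8192), fs = 1024, stage = "rectified")
  mvc <- structure(rep(3, 7), class = "mvc_profile", names = FACE_MUSCLES)
  env <- normalize_and_envelope(rec, mvc)
  expect_equal(unname(env$samples[1, 4096]), 1, tolerance = 1e-6)
  expect_equal(env$stage, "envelope")
  # zero input stays zero
  z <- normalize_and_envelope(emg_recording(matrix(0, 7, 2048), 1024, "rectified"), mvc)
  expect_true(all(z$samples == 0))
  # step reaches >= 0.9 of MVC within 0.5 s
  step <- matrix(rep(c(rep(0, 2048), rep(3, 4096)), each = 1), 7, 6144, byrow = TRUE)
  env2 <- normalize_and_envelope(emg_recording(step, 1024, "rectified"), mvc)
  expect_gte(env2$samples[1, 2048 + 512], 0.9)
  # channel-count mismatch
  expect_error(normalize_and_envelope(rec, structure(rep(1, 5), class = "mvc_profile")),
               "channels")
})

test_that("video downsampling picks one sample per 40 ms tick", {
  env <- emg_recording(matrix(seq_len(1024), 7, 1024, byrow = TRUE) * 1.0,
                       fs = 1024, stage = "envelope")
  down <- downsample_to_video(env)
  expect_equal(ncol(down$samples), 25L)
  expect_equal(down$fs, 25)
  # constant stays constant
  cst <- downsample_to_video(emg_recording(matrix(2, 7, 2048), 1024, "envelope"))
  expect_true(all(cst$samples == 2))
  # a 36 s segment yields 900 samples
  env36 <- emg_recording(matrix(1, 7, 36 * 1024), fs = 1024, stage = "envelope")
  expect_equal(ncol(downsample_to_video(env36)$samples), 900L)
  expect_error(downsample_to_video(env36, fs_out = 2000), "exceeds")
})

test_that("transition trimming removes the margins and keeps the books straight", {
  task <- small_task()
  cfg <- small_config()
  env <- emg_recording(task$truth$envelopes[[1]], fs = cfg$fs_emg,
                       stage = "envelope")
  st <- task$structure[[1]]
  res <- trim_transitions(env, st, margin = 1)
  # 5 s expression segments retain 3 s
  ex <- res$structure[res$structure$label != "neutral", ]
  expect_equal(ex$end_s - ex$start_s, rep(3, nrow(ex)))
  # margin 0 returns the input unchanged
  same <- trim_transitions(env, st, margin = 0)
  expect_identical(same$data$samples, env$samples)
  # bookkeeping: retained = total - 2 * margin * n_transitions
  n_trans <- nrow(st) - 1L
  retained <- sum(res$structure$end_s - res$structure$start_s)
  expect_equal(retained, sum(st$end_s - st$start_s) - 2 * n_trans, tolerance = 1e-9)
  # interior segment shorter than 2 * margin is an error
  bad <- trial_structure(data.frame(trial = 1, repetition = 1,
                                    label = c("neutral", "anger", "neutral"),
                                    start_s = c(0, 3, 4.5), end_s = c(3, 4.5, 8)))
  sig <- emg_recording(matrix(0, 7, 8 * 1024), 1024, "envelope")
  expect_error(trim_transitions(sig, bad, margin = 1), "anger")
})

test_that("reordered trials contain every expression once and partition the data", {
  prep <- small_prep()
  n_rep <- small_config()$n_repetitions
  expect_length(prep$reordered, n_rep)
  seen <- list()
  for (r in seq_len(n_rep)) {
    st <- prep$reordered[[r]]$structure
    ex <- st[st$label != "neutral", ]
    expect_setequal(ex$label, FACE_EXPRESSIONS)
    seen[[r]] <- paste(ex$trial, ex$repetition)
  }
  # union over reordered trials = all trial x repetition pairs exactly once
  expect_setequal(unlist(seen),
                  as.vector(outer(1:6, seq_len(n_rep), paste)))
  expect_equal(anyDuplicated(unlist(seen)), 0L)
  # deterministic given the seed
  trials <- lapply(1:6, function(tr) {
    env <- normalize_and_envelope(bandpass_rectify(small_task()$emg[[tr]]), prep$mvc)
    tt <- trim_transitions(env, small_task()$structure[[tr]])
    list(emg = tt$data, structure = tt$structure)
  })
  r1 <- reorder_trials(trials, seed = 5)
  r2 <- reorder_trials(trials, seed = 5)
  expect_identical(r1[[1]]$structure, r2[[1]]$structure)
  expect_identical(r1[[2]]$emg$samples, r2[[2]]$emg$samples)
})

test_that("the preprocessed envelope tracks the generator ground truth", {
  prep <- small_prep()
  task <- small_task()
  cfg <- small_config()
  env <- normalize_and_envelope(bandpass_rectify(task$emg[[1]]), prep$mvc)
  truth <- task$truth$envelopes[[1]] / task$truth$mvc_amp
  for (m in 1:7) {
    if (stats::sd(truth[m, ]) > 0)
      expect_gt(stats::cor(env$samples[m, ], truth[m, ]), 0.99)
  }
})
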