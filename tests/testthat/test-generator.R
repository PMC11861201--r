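test_that("generation is deterministic given config and seed", {
  cfg <- small_config()
  a <- generate_expression_task(cfg, 1)
  b <- generate_expression_task(cfg, 1)
  expect_identical(a$emg[[1]]$samples, b$emg[[1]]$samples)
  expect_identical(a$keypoints[[3]]$displacements, b$keypoints[[3]]$displacements)
  m1 <- generate_mvc_task(cfg, 1)
  m2 <- generate_mvc_task(cfg, 1)
  expect_identical(m1$emg[[2]]$samples, m2$emg[[2]]$samples)
})

test_that("zero noise gives silent neutral segments and equilibrium keypoints", {
  cfg <- small_config(noise = zero_noise)
  task <- generate_expression_task(cfg, 1)
  st <- task$structure[[1]]
  times <- (seq_len(ncol(task$emg[[1]]$samples)) - 1) / cfg$fs_emg
  labs <- facemotor:::segment_labels_at(st, times)
  expect_true(all(task$emg[[1]]$samples[, labs == "neutral"] == 0))
  # keypoints on neutral equal the zero-activation equilibrium (zero here,
  # since all rest offsets l0 are 0)
  kt <- (seq_len(ncol(task$keypoints[[1]]$displacements)) - 1) / cfg$fs_video
  klabs <- facemotor:::segment_labels_at(st, kt)
  neutral_kp <- task$keypoints[[1]]$displacements[, klabs == "neutral"]
  eq0 <- smsm_forward(cfg$smsm_params_true, matrix(0, 7, 1))
  expect_equal(max(abs(neutral_kp - as.numeric(eq0))), 0)
})

test_that("MVC task has the documented trial timing and dominates the expression task", {
  cfg <- small_config(noise = zero_noise)
  mvc <- generate_mvc_task(cfg, 1)
  expect_length(mvc$emg, 5L)
  # 40 s at 1024 Hz
  expect_equal(ncol(mvc$emg[[1]]$samples), 40960L)
  task <- generate_expression_task(cfg, 1)
  expect_equal(mvc$truth$mvc_amp, task$truth$mvc_amp, tolerance = 1e-12)
  # per-muscle MVC envelope max >= expression-task envelope max
  expr_max <- apply(do.call(cbind, task$truth$envelopes), 1, max)
  expect_true(all(mvc$truth$mvc_amp >= expr_max - 1e-12))
  # neutral sub-segments silent at zero noise
  st <- mvc$structure[[1]]
  times <- (seq_len(40960L) - 1) / cfg$fs_emg
  labs <- facemotor:::segment_labels_at(st, times)
  expect_true(all(mvc$emg[[1]]$samples[, labs == "neutral"] == 0))
})

test_that("each expression is repeated n_repetitions times per participant", {
  task <- small_task()
  for (tr in 1:6) {
    st <- task$structure[[tr]]
    ex <- st[st$label != "neutral", ]
    expect_equal(nrow(ex), small_config()$n_repetitions)
    expect_equal(unique(ex$label), FACE_EXPRESSIONS[tr])
  }
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(expression_duration = 0), "positive")
  expect_error(generator_config(noise = list(baseline_sd = -1,
                                             signal_dependent_coeff = 0,
                                             crosstalk_fraction = 0,
                                             keypoint_noise_sd = 0)), "baseline_sd")
  W <- default_synergy_matrix(); W[1, 1] <- -0.1
  expect_error(generator_config(synergy_matrix_true = W), "non-negative")
  amap <- default_activation_map(); amap["neutral", 1] <- 0.2
  expect_error(generator_config(expression_activation_map = amap), "zero")
  expect_error(generate_expression_task(small_config(), 3), "out of range")
})

test_that("classification gets harder, never easier, as baseline noise grows", {
  # separability dial: window-level accuracy non-increasing across three
  # baseline noise levels (tiny study: 1 participant, 2 repetitions)
  accs <- vapply(c(0.02, 1, 4), function(bsd) {
    cfg <- generator_config(seed = 7, n_participants = 1, n_repetitions = 3,
                            noise = list(baseline_sd = bsd,
                                         signal_dependent_coeff = 0.1,
                                         crosstalk_fraction = 0.05,
                                         keypoint_noise_sd = 2e-4))
    prep <- prepare_participant(cfg, 1)
    tabs <- lapply(prep$reordered, function(tr)
      sliding_features(tr$emg, tr$structure))
    clf <- train_classifier(facemotor:::bind_feature_tables(tabs[1:2]),
                            cv_folds = 0, seed = 1)
    evaluate_classifier(clf, facemotor:::bind_feature_tables(tabs[3]))$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) <= 1e-9))
})
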