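# End-to-end experiment runners on synthetic data: generation ->
# preprocessing -> synergy extraction -> classification (FER analysis)
# and -> keypoint model fitting/comparison (displacement analysis).
# A single master seed fans out to named sub-seeds (generation, NMF
# restarts, split, forest, Adam) so stages are independently
# reproducible.

#' Generate and preprocess one participant
#'
#' Runs the full preprocessing path for one simulated participant: MVC
#' task rectification and MVC profile extraction; expression-task
#' band-pass + rectification, MVC normalisation and 2 Hz enveloping;
#' 1 s transition trimming; trial reordering. Produces the reordered
#' trials both at the sEMG rate (for synergy extraction and
#' classification features) and at the video rate (for the keypoint
#' models), with keypoints trimmed and reordered identically.
#'
#' @param config A [generator_config()].
#' @param participant Participant index.
#' @param margin Transition trim margin in seconds (default 1).
#' @return List: `reordered` (reordered trials with `emg` envelope at
#'   `fs_emg`, `keypoints`, `structure`), `reordered_video` (same trials
#'   with `emg` downsampled to the video rate), `mvc`, `truth`.
#' @export
prepare_participant <- function(config, participant, margin = 1) {
  mvc_task <- generate_mvc_task(config, participant)
  mvc <- compute_mvc(lapply(mvc_task$emg, bandpass_rectify))
  task <- generate_expression_task(config, participant)
  trials_full <- vector("list", 6L)
  trials_video <- vector("list", 6L)
  for (tr in 1:6) {
    env <- normalize_and_envelope(bandpass_rectify(task$emg[[tr]]), mvc)
    trimmed <- trim_transitions(env, task$structure[[tr]], margin)
    kp <- trim_transitions(task$keypoints[[tr]], task$structure[[tr]], margin)
    trials_full[[tr]] <- list(emg = trimmed$data, keypoints = kp$data,
                              structure = trimmed$structure)
    env25 <- downsample_to_video(env, config$fs_video)
    tr25 <- trim_transitions(env25, task$structure[[tr]], margin)
    trials_video[[tr]] <- list(emg = tr25$data, keypoints = kp$data,
                               structure = tr25$structure)
  }
  reorder_seed <- derive_seed(config$seed, participant, 9L)
  list(reordered = reorder_trials(trials_full, seed = reorder_seed),
       reordered_video = reorder_trials(trials_video, seed = reorder_seed),
       mvc = mvc, truth = task$truth)
}

#' Run the facial-expression-recognition experiment
#'
#' For every participant: extract muscle synergies from the reordered
#' envelopes (rank chosen by the VAF threshold rule on the video-rate
#' envelopes), project the activations at the full sEMG rate, compute
#' sliding-window features in synergy mode and sEMG mode, then pool a
#' 10/2 reordered-trial split across participants, train one random
#' forest per mode and evaluate on the held-out windows.
#'
#' @param config A [generator_config()].
#' @param prepared Optional list of [prepare_participant()] outputs (one
#'   per participant) to reuse across experiments.
#' @param synergy_threshold VAF threshold in percent (default 90).
#' @param n_restarts NMF restarts (default 10).
#' @param window,step Feature window and step in samples (defaults 125
#'   and 40 ms).
#' @param n_trees,cv_folds Random-forest size and training-CV folds.
#' @param n_train Training trials per participant (default 10).
#' @param seed Master seed (defaults to the generator seed).
#' @return List: `reports` (`synergy` and `semg` [classifier_report]s),
#'   `ranks`, `vaf_curves`, `decompositions`, `split` assignment,
#'   `cv_accuracy` per mode, `manifest`.
#' @export
run_fer_experiment <- function(config, prepared = NULL,
                               synergy_threshold = 90, n_restarts = 10L,
                               window = 125L, step = NULL,
                               n_trees = 100L, cv_folds = 5L,
                               n_train = 10L, seed = config$seed) {
  np <- config$n_participants
  feats_syn <- vector("list", np)
  feats_emg <- vector("list", np)
  ranks <- integer(np)
  vaf_curves <- vector("list", np)
  decomps <- vector("list", np)
  for (p in seq_len(np)) {
    prep <- if (is.null(prepared)) prepare_participant(config, p) else prepared[[p]]
    # synergy extraction on the video-rate envelopes (the 2 Hz envelope is
    # band-limited far below the video Nyquist, so this loses nothing)
    U25 <- do.call(cbind, lapply(prep$reordered_video, function(tr) tr$emg$samples))
    sel <- select_rank(U25, threshold = synergy_threshold,
                       n_restarts = n_restarts,
                       seed = derive_seed(seed, 11L, p))
    ranks[p] <- sel$rank
    vaf_curves[[p]] <- sel$vaf_curve
    decomps[[p]] <- sel$decomposition
    feats_syn[[p]] <- lapply(prep$reordered, function(tr) {
      C <- project_activations(sel$decomposition$Ws, tr$emg$samples)
      sliding_features(C, tr$structure, fs = tr$emg$fs, window = window,
                       step = step)
    })
    feats_emg[[p]] <- lapply(prep$reordered, function(tr)
      sliding_features(tr$emg, tr$structure, window = window, step = step))
  }
  split_seed <- derive_seed(seed, 12L)
  reports <- list(); cv_acc <- list()
  splits <- NULL
  for (mode in c("synergy", "semg")) {
    tabs <- if (mode == "synergy") feats_syn else feats_emg
    sp <- split_train_test(tabs, n_train = n_train, seed = split_seed)
    splits <- sp$assignment
    train <- bind_feature_tables(sp$train)
    test <- bind_feature_tables(sp$test)
    clf <- train_classifier(train, n_trees = n_trees, cv_folds = cv_folds,
                            seed = derive_seed(seed, 13L, match(mode, c("synergy", "semg"))))
    reports[[mode]] <- evaluate_classifier(clf, test)
    cv_acc[[mode]] <- clf$cv_accuracy
  }
  list(reports = reports, ranks = ranks, vaf_curves = vaf_curves,
       decompositions = decomps, split = splits, cv_accuracy = cv_acc,
       manifest = experiment_manifest(config, seed))
}

#' Run the keypoint displacement estimation experiment
#'
#' Per participant, fits the requested displacement models on the same
#' 10/2 reordered-trial split used by the recognition experiment
#' (video-rate activations and displacements, k-fold CV with best-fold
#' selection), evaluates them on the held-out trials, and compares the
#' models across participants with one-way ANOVA plus Tukey HSD on both
#' metrics.
#'
#' @param config A [generator_config()].
#' @param prepared Optional list of [prepare_participant()] outputs.
#' @param models Model kinds to fit (default all three).
#' @param epochs,folds,lr Training protocol passed to
#'   [fit_keypoint_model()].
#' @param n_train Training trials per participant (default 10).
#' @param seed Master seed (defaults to the generator seed).
#' @return List: `metrics` (data.frame participant x model with
#'   `mean_r2`, `mean_nrmse`), `comparison` (ANOVA + Tukey for each
#'   metric; NULL with fewer than 2 models), `fits`, `manifest`.
#' @export
run_keypoint_experiment <- function(config, prepared = NULL,
                                    models = c("smsm", "lrm", "smsm_lrm"),
                                    epochs = 18000L, folds = 5L, lr = 1e-3,
                                    n_train = 10L, seed = config$seed) {
  np <- config$n_participants
  split_seed <- derive_seed(seed, 12L)
  rows <- list(); fits <- list()
  for (p in seq_len(np)) {
    prep <- if (is.null(prepared)) prepare_participant(config, p) else prepared[[p]]
    trials <- prep$reordered_video
    n_trials <- length(trials)
    idx <- with_seed(derive_seed(split_seed, 202L, p), sample.int(n_trials))
    train_ids <- idx[seq_len(n_train)]
    test_ids <- setdiff(idx, train_ids)
    U <- lapply(trials, function(tr) tr$emg$samples)
    Y <- lapply(trials, function(tr) tr$keypoints$displacements)
    U_test <- do.call(cbind, U[test_ids])
    Y_test <- do.call(cbind, Y[test_ids])
    fits[[p]] <- list()
    for (kind in models) {
      fit <- fit_keypoint_model(kind, U[train_ids], Y[train_ids],
                                epochs = epochs, folds = folds, lr = lr,
                                seed = derive_seed(seed, 14L, p,
                                                   match(kind, c("smsm", "lrm", "smsm_lrm"))))
      met <- regression_metrics(Y_test, predict(fit, U_test))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, model = kind,
        mean_r2 = met$mean_r2, mean_nrmse = met$mean_nrmse)
      fits[[p]][[kind]] <- fit
    }
  }
  metrics <- do.call(rbind, rows)
  comparison <- NULL
  if (length(models) >= 2L && np >= 2L) {
    comparison <- list(
      nrmse = compare_models(data.frame(model = metrics$model,
                                        value = metrics$mean_nrmse)),
      r2 = compare_models(data.frame(model = metrics$model,
                                     value = metrics$mean_r2)))
  }
  list(metrics = metrics, comparison = comparison, fits = fits,
       manifest = experiment_manifest(config, seed))
}

experiment_manifest <- function(config, seed) {
  cfg <- unclass(config)
  cfg$smsm_params_true <- unclass(cfg$smsm_params_true)
  list(seed = seed,
       config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
       package_version = as.character(utils::packageVersion("facemotor")),
       timestamp = format(Sys.time(), tz = "UTC"))
}
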