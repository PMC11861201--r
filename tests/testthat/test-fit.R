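# smooth synthetic activation trials on [0, 1]
activation_trials <- function(n_trials, T = 200, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_trials), function(i) {
    t <- seq_len(T) / T
    U <- sapply(1:7, function(m)
      pmax(0, runif(1, 0.3, 1) * sin(2 * pi * runif(1, 0.5, 2) * t +
                                       runif(1, 0, 2 * pi))))
    t(U)
  })
}

# R-side replica of the training objective (forward + denominator hinge
# penalty), used as an independent check of the compiled loss
r_loss <- function(kind, th, U, Y, KH = 100, pen_weight = 1e4, den_min = 1) {
  T <- ncol(U)
  if (kind == "lrm") {
    P <- matrix(th, 5, 7, byrow = TRUE) %*% U
    return(mean((P - Y)^2))
  }
  p <- facemotor:::params_from_theta(th[1:36], KH)
  D <- oracle_forward(p, U)
  pen <- 0
  for (nm in c("inner_eyebrow", "mouth_corner")) {
    d <- p$doubles[[nm]]
    rows <- if (nm == "inner_eyebrow") c(1, 3) else c(5, 6)
    den <- KH + d$a[1] * d$lambda[1] * (d$k0[1] + d$k1[1] * U[rows[1], ]) +
      d$a[2] * d$lambda[2] * (d$k0[2] + d$k1[2] * U[rows[2], ])
    pen <- pen + pen_weight * sum(pmax(0, den_min - den)^2) / T
  }
  P <- if (kind == "smsm_lrm") matrix(th[37:61], 5, 5, byrow = TRUE) %*% D else D
  mean((P - Y)^2) + pen
}

test_that("the compiled objective matches an independent R computation", {
  set.seed(2)
  U <- matrix(runif(7 * 80), 7)
  Y <- matrix(rnorm(5 * 80, sd = 0.01), 5)
  for (kind in c("smsm", "smsm_lrm", "lrm")) {
    th <- facemotor:::init_theta(kind, 3, 100)
    th <- th + rnorm(length(th), sd = 0.3)
    code <- match(kind, c("smsm", "smsm_lrm", "lrm")) - 1L
    res <- facemotor:::adam_fit_cpp(U, Y, code, th, 100, 1L, 1e-3,
                                    0.9, 0.999, 1e4, 1)
    expect_equal(res$loss_curve[1], r_loss(kind, th, U, Y), tolerance = 1e-10)
  }
  # with the hinge penalty active (den_min far above any denominator)
  th <- facemotor:::init_theta("smsm", 4, 100)
  res <- facemotor:::adam_fit_cpp(U, Y, 0L, th, 100, 1L, 1e-3,
                                  0.9, 0.999, 1e4, 150)
  expect_equal(res$loss_curve[1],
               r_loss("smsm", th, U, Y, den_min = 150), tolerance = 1e-10)
})

test_that("closed-form linear regression recovers exact linear data", {
  set.seed(6)
  W_true <- matrix(rnorm(35, sd = 0.02), 5, 7)
  U <- activation_trials(6, T = 150, seed = 2)
  Y <- lapply(U, function(u) W_true %*% u)
  fit <- fit_keypoint_model("lrm", U, Y, folds = 3, seed = 1)
  expect_lt(max(abs(coef(fit) - W_true)), 1e-6)
  pred <- predict(fit, U[[1]])
  expect_lt(max(abs(pred - Y[[1]])), 1e-8)
})

test_that("the spring model refits its own forward map (predictive self-consistency)", {
  p_true <- default_smsm_parameters()
  U <- activation_trials(7, T = 250, seed = 3)
  Y <- lapply(U, function(u) smsm_forward(p_true, u))
  fit <- fit_keypoint_model("smsm", U[1:6], Y[1:6], epochs = 6000, folds = 3,
                            seed = 1)
  met <- regression_metrics(Y[[7]], predict(fit, U[[7]]))
  expect_lte(met$mean_nrmse, 0.02)
})

test_that("the hybrid model recovers coupled displacements at zero noise", {
  p_true <- default_smsm_parameters()
  K <- default_coupling_matrix()
  for (sd in 1:3) {
    U <- activation_trials(7, T = 250, seed = sd + 10)
    Y <- lapply(U, function(u) K %*% smsm_forward(p_true, u))
    fit <- fit_keypoint_model("smsm_lrm", U[1:6], Y[1:6], epochs = 6000,
                              folds = 3, seed = sd)
    met <- regression_metrics(Y[[7]], predict(fit, U[[7]]))
    expect_lte(met$mean_nrmse, 0.02)
  }
})

test_that("the Adam path on the convex linear objective is monotone", {
  set.seed(8)
  W_true <- matrix(rnorm(35, sd = 0.02), 5, 7)
  U <- matrix(runif(7 * 400), 7)
  Y <- W_true %*% U + matrix(rnorm(5 * 400, sd = 1e-4), 5)
  fit <- fit_keypoint_model("lrm", list(U), Y_trials = list(Y), epochs = 4000,
                            folds = 1, seed = 1, lrm_optimizer = "adam")
  lc <- fit$loss_curve
  span <- 500
  idx <- seq_len(length(lc) - span)
  # monotone descent up to optimizer chatter at the converged noise floor
  expect_true(all(lc[idx + span] - lc[idx] <= 1e-3 * lc[1]))
  expect_lt(lc[length(lc)], 1e-2 * lc[1])
})

test_that("regression metrics match hand arithmetic and are scale free", {
  truth <- matrix(rep(c(0, 1, 2), 5), 5, 3, byrow = TRUE)
  pred <- matrix(rep(c(0, 1, 3), 5), 5, 3, byrow = TRUE)
  met <- regression_metrics(truth, pred)
  expect_equal(met$mean_nrmse, 0.28868, tolerance = 1e-4)
  expect_equal(unname(met$nrmse[1]), sqrt(1 / 3) / 2, tolerance = 1e-12)
  expect_equal(unname(met$r2[1]), 100 * (1 - 1 / 2), tolerance = 1e-12)
  perfect <- regression_metrics(truth, truth)
  expect_equal(perfect$mean_r2, 100)
  expect_equal(perfect$mean_nrmse, 0)
  mean_pred <- regression_metrics(truth, matrix(1, 5, 3))
  expect_equal(mean_pred$mean_r2, 0)
  # rescaling both truth and prediction leaves both metrics unchanged
  set.seed(4)
  A <- matrix(rnorm(5 * 50), 5); B <- A + matrix(rnorm(5 * 50, sd = 0.1), 5)
  m1 <- regression_metrics(A, B)
  m2 <- regression_metrics(37 * A, 37 * B)
  expect_equal(m1$mean_nrmse, m2$mean_nrmse, tolerance = 1e-12)
  expect_equal(m1$mean_r2, m2$mean_r2, tolerance = 1e-12)
  expect_error(regression_metrics(matrix(1, 5, 3), matrix(1, 5, 3)), "range")
})

test_that("model comparison reproduces textbook one-way ANOVA", {
  # identical group distributions: F = 0, all Tukey p = 1
  same <- data.frame(model = rep(c("a", "b", "c"), each = 3),
                     value = rep(c(1, 2, 3), 3))
  cmp <- compare_models(same)
  expect_equal(cmp$F, 0, tolerance = 1e-12)
  expect_equal(cmp$p, 1, tolerance = 1e-12)
  expect_true(all(cmp$tukey$p.adj > 0.999))
  # well-separated group 1 vs identical groups 2 and 3
  eps <- c(-1e-6, 0, 1e-6)
  sep <- data.frame(model = rep(c("m1", "m2", "m3"), each = 3),
                    value = c(0 + eps, 1 + eps, 1 + eps))
  cmp2 <- compare_models(sep)
  expect_lt(cmp2$p, 1e-6)
  tk <- cmp2$tukey
  expect_lt(tk$p.adj[tk$pair == "m2-m1"], 0.001)
  expect_lt(tk$p.adj[tk$pair == "m3-m1"], 0.001)
  expect_gt(tk$p.adj[tk$pair == "m3-m2"], 0.9)
  # brute-force F on a random 3 x 10 fixture
  set.seed(12)
  vals <- rnorm(30)
  grp <- rep(c("x", "y", "z"), each = 10)
  cmp3 <- compare_models(data.frame(model = grp, value = vals))
  gm <- tapply(vals, grp, mean); gv <- tapply(vals, grp, function(v) sum((v - mean(v))^2))
  ssb <- sum(10 * (gm - mean(vals))^2); ssw <- sum(gv)
  F_oracle <- (ssb / 2) / (ssw / 27)
  expect_equal(cmp3$F, F_oracle, tolerance = 1e-10)
  expect_error(compare_models(data.frame(model = "a", value = 1:3)), "two models")
})

test_that("fit_keypoint_model validates its inputs and exposes methods", {
  U <- activation_trials(3, T = 50, seed = 1)
  Y <- lapply(U, function(u) smsm_forward(default_smsm_parameters(), u))
  expect_error(fit_keypoint_model("smsm", U, Y, folds = 5), "fewer trials")
  expect_error(fit_keypoint_model("smsm", U, Y[1:2], folds = 2), "same length")
  fit <- fit_keypoint_model("lrm", U, Y, folds = 3, seed = 1)
  expect_s3_class(fit, "keypoint_fit")
  expect_output(print(fit), "LRM")
  expect_equal(dim(coef(fit)), c(5L, 7L))
  r <- residuals(fit, U[[2]], Y[[2]])
  expect_equal(dim(r), dim(Y[[2]]))
  expect_equal(fit$best_fold, which.min(fit$cv$val_mse))
})
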