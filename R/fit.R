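# Fitting the keypoint displacement estimators (SMSM, LRM, SMSM-LRM).
# The spring parameters are optimised by full-batch Adam with stiffness
# positivity enforced through a soft-plus reparameterisation and the
# skin stiffness KH held fixed; the LRM admits an exact least-squares
# solution (with an Adam path available for parity). Model selection
# uses k-fold cross-validation over training trials: the fold whose
# model attains the lowest validation MSE is kept.

inv_softplus <- function(k) log(expm1(k))

# theta layout must mirror src/adam_fit.cpp
SING_ORDER <- c("outer_eyebrow", "nose", "chin")
DBL_ORDER <- c("inner_eyebrow", "mouth_corner")

theta_from_params <- function(p) {
  th <- numeric(0)
  for (nm in SING_ORDER) {
    sp <- p$singles[[nm]]
    th <- c(th, inv_softplus(sp[["k0"]]), inv_softplus(sp[["k1"]]),
            sp[["l0"]], sp[["l1"]])
  }
  for (nm in DBL_ORDER) {
    d <- p$doubles[[nm]]
    th <- c(th,
            inv_softplus(d$k0[1]), inv_softplus(d$k1[1]), d$l0[1], d$l1[1],
            inv_softplus(d$k0[2]), inv_softplus(d$k1[2]), d$l0[2], d$l1[2],
            d$a[1], d$a[2], d$lambda[1], d$lambda[2])
  }
  th
}

params_from_theta <- function(th, KH = 100) {
  softplus <- function(x) ifelse(x > 0, x, 0) + log1p(exp(-abs(x)))
  singles <- list()
  for (i in seq_along(SING_ORDER)) {
    b <- 4 * (i - 1)
    singles[[SING_ORDER[i]]] <- c(softplus(th[b + 1]), softplus(th[b + 2]),
                                  th[b + 3], th[b + 4])
  }
  doubles <- list()
  for (i in seq_along(DBL_ORDER)) {
    b <- 12 + 12 * (i - 1)
    doubles[[DBL_ORDER[i]]] <- list(
      k0 = softplus(c(th[b + 1], th[b + 5])),
      k1 = softplus(c(th[b + 2], th[b + 6])),
      l0 = c(th[b + 3], th[b + 7]),
      l1 = c(th[b + 4], th[b + 8]),
      a = c(th[b + 9], th[b + 10]),
      lambda = c(th[b + 11], th[b + 12]))
  }
  smsm_parameters(KH = KH, singles = singles, doubles = doubles)
}

# seeded initial parameter vector; lambda signs follow the anatomical
# agonist/antagonist convention of the wiring (first member elevates /
# pulls positive, second opposes)
init_theta <- function(kind, seed, KH) {
  with_seed(seed, {
    th <- numeric(0)
    if (kind %in% c("smsm", "smsm_lrm")) {
      for (i in 1:3)
        th <- c(th, inv_softplus(10), inv_softplus(20), 0,
                stats::rnorm(1, 0, 0.01))
      for (i in 1:2)
        th <- c(th, inv_softplus(10), inv_softplus(20), 0, stats::rnorm(1, 0, 0.01),
                inv_softplus(10), inv_softplus(20), 0, stats::rnorm(1, 0, 0.01),
                1, 1, 1, -1)
    }
    if (kind == "smsm_lrm")
      th <- c(th, as.vector(t(diag(5) + matrix(stats::rnorm(25, 0, 0.01), 5, 5))))
    if (kind == "lrm")
      th <- c(th, stats::rnorm(35, 0, 0.01))
    th
  })
}

as_activation_matrix <- function(x) {
  if (inherits(x, "emg_recording")) x$samples
  else if (inherits(x, "keypoint_trajectories")) x$displacements
  else as.matrix(x)
}

lrm_closed_form <- function(U, Y) {
  G <- tcrossprod(U)
  W <- Y %*% t(U) %*% solve(G + diag(1e-12 * max(diag(G)), nrow(G)))
  rownames(W) <- FACE_KEYPOINTS
  colnames(W) <- FACE_MUSCLES
  W
}

fit_one <- function(kind, U, Y, epochs, lr, seed, KH, pen_weight, den_min,
                    optimizer) {
  if (kind == "lrm" && optimizer == "closed_form") {
    W <- lrm_closed_form(U, Y)
    return(list(theta = NULL, W = W, params = NULL, loss_curve = numeric(0)))
  }
  th0 <- init_theta(kind, seed, KH)
  kind_code <- match(kind, c("smsm", "smsm_lrm", "lrm")) - 1L
  res <- adam_fit_cpp(U, Y, kind_code, th0, KH, as.integer(epochs), lr,
                      0.9, 0.999, pen_weight, den_min)
  th <- res$theta
  out <- list(theta = th, loss_curve = res$loss_curve, W = NULL, params = NULL)
  if (kind == "lrm") {
    out$W <- matrix(th, 5L, 7L, byrow = TRUE,
                    dimnames = list(FACE_KEYPOINTS, FACE_MUSCLES))
  } else {
    out$params <- params_from_theta(th[1:36], KH)
    if (kind == "smsm_lrm")
      out$W <- matrix(th[37:61], 5L, 5L, byrow = TRUE,
                      dimnames = list(FACE_KEYPOINTS, FACE_KEYPOINTS))
  }
  out
}

predict_fit <- function(kind, fit, U, KH) {
  switch(kind,
         smsm = smsm_forward(fit$params, U),
         lrm = lrm_predict(fit$W, U),
         smsm_lrm = hybrid_predict(fit$params, fit$W, U))
}

#' Fit a keypoint displacement model from muscle activations
#'
#' Fits one of the three displacement estimators — the per-point
#' skin-musculoskeletal spring model (`"smsm"`), the multivariate linear
#' regression model (`"lrm"`) or their hybrid (`"smsm_lrm"`, a 5 x 5
#' linear recombination of the spring-model outputs) — to aligned 25 Hz
#' activation/displacement training trials.
#'
#' Spring parameters (and the hybrid weight matrix) are optimised jointly
#' over all five keypoints by full-batch Adam minimising the mean squared
#' error, with `k0`, `k1` kept positive through a soft-plus
#' reparameterisation and `KH` fixed. A hinge penalty keeps the
#' double-system equilibrium denominator away from zero. The LRM is
#' solved in closed form by default (`lrm_optimizer = "closed_form"`),
#' with the Adam path available for parity. Model selection is k-fold
#' cross-validation over trials: each fold's model is trained on the
#' remaining folds and scored on the held-out fold; the model with the
#' lowest validation MSE is returned.
#'
#' @param kind `"smsm"`, `"lrm"` or `"smsm_lrm"`.
#' @param U_trials List of 7 x T activation matrices (or downsampled
#'   [emg_recording]s), one per training trial.
#' @param Y_trials List of matching 5 x T displacement matrices (or
#'   [keypoint_trajectories]).
#' @param epochs Adam epochs (default 18000).
#' @param folds Cross-validation folds (default 5).
#' @param lr Adam step size (default 1e-3).
#' @param seed Integer seed (fold assignment and initialisation).
#' @param KH Fixed skin stiffness (default 100 N/m).
#' @param pen_weight,den_min Denominator hinge-penalty weight and bound.
#' @param lrm_optimizer `"closed_form"` or `"adam"` (LRM only).
#' @return An object of class `keypoint_fit` with methods `print`,
#'   `summary`, `coef`, `predict`, `residuals` and `plot`.
#' @export
fit_keypoint_model <- function(kind = c("smsm", "lrm", "smsm_lrm"),
                               U_trials, Y_trials,
                               epochs = 18000L, folds = 5L, lr = 1e-3,
                               seed = 1L, KH = 100,
                               pen_weight = 1e4, den_min = 0.01 * KH,
                               lrm_optimizer = c("closed_form", "adam")) {
  kind <- match.arg(kind)
  lrm_optimizer <- match.arg(lrm_optimizer)
  U_trials <- lapply(U_trials, as_activation_matrix)
  Y_trials <- lapply(Y_trials, as_activation_matrix)
  if (length(U_trials) != length(Y_trials))
    stop("U_trials and Y_trials must have the same length")
  n_trials <- length(U_trials)
  if (n_trials < folds) stop("fewer trials (", n_trials, ") than folds (", folds, ")")
  for (i in seq_len(n_trials))
    if (ncol(U_trials[[i]]) != ncol(Y_trials[[i]]))
      stop("trial ", i, ": activation and displacement lengths differ")

  fold_of <- with_seed(derive_seed(seed, 404L),
                       sample(rep_len(seq_len(folds), n_trials)))
  cv <- data.frame(fold = seq_len(folds), val_mse = NA_real_)
  fits <- vector("list", folds)
  for (f in seq_len(folds)) {
    # folds = 1: fit and validate on everything (no held-out fold)
    tr_sel <- if (folds == 1L) rep(TRUE, n_trials) else fold_of != f
    U_tr <- do.call(cbind, U_trials[tr_sel])
    Y_tr <- do.call(cbind, Y_trials[tr_sel])
    U_va <- do.call(cbind, U_trials[fold_of == f])
    Y_va <- do.call(cbind, Y_trials[fold_of == f])
    fits[[f]] <- fit_one(kind, U_tr, Y_tr, epochs, lr,
                         derive_seed(seed, 405L, f), KH, pen_weight, den_min,
                         lrm_optimizer)
    pred <- predict_fit(kind, fits[[f]], U_va, KH)
    cv$val_mse[f] <- mean((pred - Y_va)^2)
  }
  best <- which.min(cv$val_mse)
  fit <- fits[[best]]
  structure(list(kind = kind, params = fit$params, W = fit$W,
                 cv = cv, best_fold = best, fold_of = fold_of,
                 loss_curve = fit$loss_curve, epochs = epochs, lr = lr,
                 KH = KH, seed = seed, n_trials = n_trials,
                 call = match.call()),
            class = "keypoint_fit")
}

#' @export
print.keypoint_fit <- function(x, ...) {
  lab <- c(smsm = "SMSM", lrm = "LRM", smsm_lrm = "SMSM-LRM")[x$kind]
  cat(sprintf("<keypoint_fit> %s, %d training trials, %d-fold CV (best fold %d)\n",
              lab, x$n_trials, nrow(x$cv), x$best_fold))
  cat(sprintf("  validation MSE (best fold): %.4g\n", min(x$cv$val_mse)))
  invisible(x)
}

#' @export
summary.keypoint_fit <- function(object, ...) {
  print(object)
  cat("  per-fold validation MSE:\n")
  print(object$cv, row.names = FALSE)
  if (!is.null(object$params)) print(object$params)
  if (!is.null(object$W)) {
    cat("  weight matrix:\n")
    print(round(object$W, 4))
  }
  invisible(object)
}

#' @export
coef.keypoint_fit <- function(object, ...) {
  switch(object$kind,
         smsm = object$params,
         lrm = object$W,
         smsm_lrm = list(params = object$params, W = object$W))
}

#' @export
predict.keypoint_fit <- function(object, U, ...) {
  U <- as_activation_matrix(U)
  predict_fit(object$kind, object, U, object$KH)
}

#' @export
residuals.keypoint_fit <- function(object, U, Y, ...) {
  as_activation_matrix(Y) - predict(object, U)
}

#' @export
plot.keypoint_fit <- function(x, ...) {
  if (length(x$loss_curve) == 0) {
    warning("no loss curve (closed-form fit)")
    return(invisible(x))
  }
  graphics::plot(seq_along(x$loss_curve), x$loss_curve, type = "l", log = "y",
                 xlab = "epoch", ylab = "training MSE",
                 main = paste("Training loss,", x$kind), ...)
  invisible(x)
}

#' Regression metrics for displacement estimates
#'
#' Per-keypoint coefficient of determination (0-100 scale) and RMSE
#' normalised by the max-min range of the true data, plus their means
#' across keypoints.
#'
#' @param Y_true,Y_pred 5 x T displacement matrices of equal shape.
#' @return List: `r2` (per keypoint, percent), `nrmse` (per keypoint),
#'   `mean_r2`, `mean_nrmse`.
#' @export
regression_metrics <- function(Y_true, Y_pred) {
  Y_true <- as_activation_matrix(Y_true)
  Y_pred <- as_activation_matrix(Y_pred)
  if (!all(dim(Y_true) == dim(Y_pred))) stop("shapes differ")
  k <- nrow(Y_true)
  r2 <- nrmse <- numeric(k)
  for (i in seq_len(k)) {
    y <- Y_true[i, ]; p <- Y_pred[i, ]
    rng <- diff(range(y))
    if (rng <= 0) stop("zero range in true data for keypoint ", i)
    ss_res <- sum((y - p)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2[i] <- 100 * (1 - ss_res / ss_tot)
    nrmse[i] <- sqrt(mean((y - p)^2)) / rng
  }
  names(r2) <- names(nrmse) <- rownames(Y_true)
  list(r2 = r2, nrmse = nrmse, mean_r2 = mean(r2), mean_nrmse = mean(nrmse))
}

#' Compare model performance across participants
#'
#' One-way ANOVA of a performance metric across model groups followed by
#' Tukey's honestly-significant-difference post-hoc test on all pairs.
#'
#' @param metrics A data.frame with columns `model` and `value` (one row
#'   per participant x model).
#' @return List: `F` statistic, `p` value, `anova` (the aov fit) and
#'   `tukey` (data.frame of pairwise differences and adjusted p values).
#' @export
compare_models <- function(metrics) {
  stopifnot(all(c("model", "value") %in% names(metrics)))
  metrics$model <- factor(metrics$model)
  if (nlevels(metrics$model) < 2L) stop("need at least two models")
  if (any(table(metrics$model) < 2L)) stop("need at least two samples per model")
  fit <- stats::aov(value ~ model, data = metrics)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$model
  list(F = tab[1L, "F value"], p = tab[1L, "Pr(>F)"], anova = fit,
       tukey = data.frame(pair = rownames(tk), as.data.frame(tk),
                          row.names = NULL))
}
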