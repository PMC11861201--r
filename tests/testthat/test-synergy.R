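test_that("VAF follows the Frobenius ratio", {
  U <- matrix(c(2, 1), 2, 1)
  WC <- matrix(c(1, 1), 2, 1)
  expect_equal(compute_vaf(U, WC, matrix(1)), 80)
  expect_equal(compute_vaf(U, U, matrix(1)), 100)
  expect_equal(compute_vaf(U, 0 * U, matrix(1)), 0)
  expect_error(compute_vaf(0 * U, U, matrix(1)), "zero")
  # scale invariance: VAF unchanged under U -> a U
  set.seed(1)
  U2 <- matrix(rexp(7 * 40), 7)
  f <- fit_nmf(U2, 2, n_restarts = 3, seed = 1)
  expect_equal(compute_vaf(3.7 * U2, f$Ws, 3.7 * f$C),
               compute_vaf(U2, f$Ws, f$C), tolerance = 1e-10)
})

test_that("rank-1 factorisation of the 2x2 identity matches the brute-force optimum", {
  # oracle: grid search over unit direction angles for rank-1 nonneg factors
  ang <- seq(0, pi / 2, length.out = 721)
  best <- Inf
  I2 <- diag(2)
  for (a in ang) for (b in ang) {
    w <- c(cos(a), sin(a)); h <- c(cos(b), sin(b))
    # optimal scale for || I - s w h' ||_F
    s <- sum(I2 * outer(w, h)) / sum(outer(w, h)^2)
    best <- min(best, sum((I2 - s * outer(w, h))^2))
  }
  vaf_oracle <- 100 * (1 - best / 2)
  expect_equal(vaf_oracle, 50, tolerance = 0.01)
  f <- fit_nmf(I2, 1, n_restarts = 10, seed = 1, max_iter = 2000, tol = 1e-15)
  expect_equal(f$vaf_percent, vaf_oracle, tolerance = 0.1)
})

test_that("exact low-rank data is factorised to solver precision", {
  W <- default_synergy_matrix()
  set.seed(3)
  C <- matrix(rexp(3 * 400), 3)
  U <- W %*% C
  f <- fit_nmf(U, 3, n_restarts = 5, seed = 1, max_iter = 4000, tol = 1e-15)
  expect_lt(sqrt(sum((U - f$Ws %*% f$C)^2) / sum(U^2)), 1e-6)
  expect_gte(f$vaf_percent, 99.9)
  # decomposition invariants
  expect_true(all(f$Ws >= 0) && all(f$C >= 0))
  expect_equal(colSums(f$Ws^2), rep(1, 3), ignore_attr = TRUE, tolerance = 1e-9)
  # full rank explains essentially everything
  f7 <- fit_nmf(U + 0.01 * mean(U), 7, n_restarts = 3, seed = 1)
  expect_gte(f7$vaf_percent, 99)
})

test_that("the VAF curve is monotone and the threshold rule picks its knee", {
  prep <- small_prep()
  U25 <- do.call(cbind, lapply(prep$reordered_video, function(t) t$emg$samples))
  sel <- select_rank(U25, n_restarts = 5, seed = 2)
  expect_equal(sel$rank, 3L)
  expect_gte(sel$vaf_curve[3], 90)
  expect_true(all(diff(sel$vaf_curve) > -0.5))
  expect_equal(select_rank(U25, threshold = 1e-12, n_restarts = 2, seed = 2,
                           max_rank = 2)$rank, 1L)
  # restart stability at the true rank
  f <- fit_nmf(U25, 3, n_restarts = 10, seed = 4)
  spread <- diff(range(f$restart_losses)) / mean(f$restart_losses)
  expect_lt(spread, 0.01)
})

test_that("synergy matching maximises and reports cosine similarity", {
  W <- default_synergy_matrix()
  same <- match_and_similarity(W, W[, c(2, 3, 1)])
  expect_equal(same$pairing, c(3L, 1L, 2L))
  expect_equal(same$cosine, rep(1, 3), tolerance = 1e-12)
  A <- diag(7)[, 1:3]; B <- diag(7)[, 5:7]
  expect_equal(match_and_similarity(A, B)$cosine, rep(0, 3))
  a <- matrix(c(1, 1, 0, 0, 0, 0, 0) / sqrt(2), ncol = 1)
  b <- matrix(c(1, 0, 0, 0, 0, 0, 0), ncol = 1)
  expect_equal(match_and_similarity(a, b)$cosine, 0.7071, tolerance = 1e-4)
  expect_error(match_and_similarity(A, diag(7)[, 1:2]), "rank")
})

test_that("3-D hulls of known polytopes have the known volumes", {
  simplex <- rbind(diag(3), c(0, 0, 0))
  h <- facemotor:::convex_hull_3d(simplex)
  expect_equal(h$volume, 1 / 6, tolerance = 1e-12)
  expect_false(h$degenerate)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  set.seed(1)
  inside <- matrix(runif(60), ncol = 3)
  expect_equal(facemotor:::convex_hull_3d(rbind(cube, inside))$volume, 1,
               tolerance = 1e-9)
  octa <- rbind(diag(3), -diag(3))
  expect_equal(facemotor:::convex_hull_3d(octa)$volume, 4 / 3, tolerance = 1e-9)
  # degenerate inputs
  expect_true(facemotor:::convex_hull_3d(matrix(1, 5, 3))$degenerate)
  coplanar <- cbind(matrix(runif(20), 10), 0.5)
  expect_true(facemotor:::convex_hull_3d(coplanar)$degenerate)
  expect_equal(facemotor:::convex_hull_3d(coplanar)$volume, 0)
})

test_that("activation clusters separate neutral from expressions", {
  prep <- small_prep()
  U25 <- do.call(cbind, lapply(prep$reordered_video, function(t) t$emg$samples))
  f <- fit_nmf(U25, 3, n_restarts = 5, seed = 1)
  # single-trial clustering; identical points give a degenerate zero hull
  st <- prep$reordered_video[[1]]$structure
  n1 <- ncol(prep$reordered_video[[1]]$emg$samples)
  cl <- activation_clusters(f$C[, seq_len(n1)], st, fs = 25)
  expect_setequal(names(cl), c("neutral", FACE_EXPRESSIONS))
  cn <- sqrt(sum(cl$neutral$centroid^2))
  for (ex in FACE_EXPRESSIONS)
    expect_lt(cn, sqrt(sum(cl[[ex]]$centroid^2)))
  same <- activation_clusters(matrix(0.3, 3, 100),
                              one_segment_structure("anger", 4, 25), fs = 25)
  expect_true(same$anger$degenerate)
  expect_equal(same$anger$hull_volume, 0)
  expect_equal(same$anger$centroid, rep(0.3, 3), ignore_attr = TRUE)
})

test_that("rank selection and synergy recovery hold across generator seeds", {
  for (sd in 1:3) {
    cfg <- small_config(seed = sd)
    prep <- prepare_participant(cfg, 1)
    U25 <- do.call(cbind, lapply(prep$reordered_video, function(t) t$emg$samples))
    sel <- select_rank(U25, n_restarts = 5, seed = sd)
    expect_equal(sel$rank, 3L)
    sim <- match_and_similarity(sel$decomposition$Ws, prep$truth$Ws_true)
    expect_true(all(sim$cosine >= 0.9))
  }
})
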