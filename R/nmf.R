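# Non-negative matrix factorisation U ~ Ws C by hierarchical alternating
# least squares (column-wise coordinate descent on the Frobenius
# objective), best-of-restarts. Rank is selected by the smallest number
# of synergies whose variance accounted for reaches a threshold.

nmf_hals_once <- function(U, s, max_iter, tol) {
  m <- nrow(U); n <- ncol(U)
  scale0 <- sqrt(mean(U) / s)
  W0 <- matrix(stats::runif(m * s), m, s) * scale0
  C0 <- matrix(stats::runif(s * n), s, n) * scale0
  nmf_hals_cpp(U, W0, C0, as.integer(max_iter), tol, TRUE)
}

#' Fit a muscle-synergy factorisation of fixed rank
#'
#' Factorises a non-negative envelope matrix `U` (muscles x time) as
#' `Ws %*% C` with `s` synergies, minimising the Frobenius norm of the
#' residual by HALS coordinate descent over multiple seeded random
#' restarts; the best restart is kept. Synergy columns are normalised to
#' unit Euclidean norm (with `C` rescaled compensatingly) and ordered by
#' descending activation energy.
#'
#' @param U Non-negative muscles x time matrix.
#' @param s Number of synergies (1 to number of muscles).
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed; restart r uses a seed derived from it.
#' @param max_iter,tol HALS iteration cap and relative loss-change tolerance (tighten for exact-factorisation studies).
#' @return An object of class `synergy_decomposition`: `Ws`, `C`,
#'   `vaf_percent`, `rank`, `restart_losses`.
#' @export
fit_nmf <- function(U, s, n_restarts = 10L, seed = 1L,
                    max_iter = 300L, tol = 1e-7) {
  U <- as.matrix(U)
  if (any(U < 0)) stop("U must be non-negative")
  if (sum(U^2) == 0) stop("U is all zero")
  if (s < 1L || s > nrow(U)) stop("rank s must be in 1..", nrow(U))
  best <- NULL
  losses <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(derive_seed(seed, 101L, r),
                     nmf_hals_once(U, s, max_iter, tol))
    losses[r] <- fit$loss
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  W <- best$W; C <- best$C
  nrm <- sqrt(colSums(W^2))
  nz <- nrm > 0
  W[, nz] <- sweep(W[, nz, drop = FALSE], 2L, nrm[nz], "/")
  C[nz, ] <- sweep(C[nz, , drop = FALSE], 1L, nrm[nz], "*")
  ord <- order(rowSums(C^2), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]; C <- C[ord, , drop = FALSE]
  rownames(W) <- rownames(U)
  colnames(W) <- rownames(C) <- paste0("syn", seq_len(s))
  structure(list(Ws = W, C = C, vaf_percent = compute_vaf(U, W, C),
                 rank = as.integer(s), restart_losses = losses),
            class = "synergy_decomposition")
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat(sprintf("<synergy_decomposition> rank %d, VAF %.2f%%, %d restarts\n",
              x$rank, x$vaf_percent, length(x$restart_losses)))
  print(round(x$Ws, 3))
  invisible(x)
}

#' Variance accounted for by a factorisation
#'
#' `VAF = 100 (1 - ||U - Ws C||_F^2 / ||U||_F^2)`, the global Frobenius
#' form dominant in the muscle-synergy literature.
#'
#' @param U Data matrix; `Ws`, `C` conformable factors.
#' @return Percentage (at most 100; can be negative for a factorisation
#'   worse than the zero model).
#' @export
compute_vaf <- function(U, Ws, C) {
  U <- as.matrix(U)
  tot <- sum(U^2)
  if (tot == 0) stop("||U||_F is zero; VAF undefined")
  100 * (1 - sum((U - Ws %*% C)^2) / tot)
}

#' Select the number of synergies by the VAF threshold rule
#'
#' Fits ranks 1..`max_rank` and returns the smallest rank whose VAF
#' reaches `threshold` (a 90% threshold is the common criterion in
#' synergy analysis), together with the whole VAF curve and the selected
#' decomposition. If no rank reaches the threshold the number of muscles
#' is returned with `threshold_met = FALSE`.
#'
#' @param U Non-negative muscles x time matrix.
#' @param threshold VAF threshold in percent (default 90).
#' @param n_restarts,seed,max_iter,tol Passed to [fit_nmf()].
#' @param max_rank Largest rank tried (default `nrow(U)`).
#' @return List with `rank`, `vaf_curve` (named numeric), `decomposition`
#'   (the fit at the selected rank) and `threshold_met`.
#' @export
select_rank <- function(U, threshold = 90, n_restarts = 10L, seed = 1L,
                        max_iter = 300L, tol = 1e-7, max_rank = nrow(U)) {
  if (threshold <= 0) threshold <- .Machine$double.eps
  if (threshold > 100) stop("threshold must be in (0, 100]")
  vaf <- rep(NA_real_, max_rank)
  fits <- vector("list", max_rank)
  chosen <- NA_integer_
  for (s in seq_len(max_rank)) {
    fits[[s]] <- fit_nmf(U, s, n_restarts = n_restarts, seed = derive_seed(seed, s),
                         max_iter = max_iter, tol = tol)
    vaf[s] <- fits[[s]]$vaf_percent
    if (is.na(chosen) && vaf[s] >= threshold) chosen <- s
  }
  met <- !is.na(chosen)
  if (!met) {
    warning("no rank reached the VAF threshold; returning the full rank")
    chosen <- max_rank
  }
  names(vaf) <- seq_len(max_rank)
  list(rank = chosen, vaf_curve = vaf, decomposition = fits[[chosen]],
       threshold_met = met)
}

#' Project envelopes onto fixed synergies (non-negative least squares)
#'
#' Computes non-negative activation coefficients `C` minimising
#' `||U - Ws C||_F` for a fixed synergy matrix, by the same HALS row
#' updates used in [fit_nmf()]. Used to evaluate activations at the full
#' sEMG rate after extracting synergies from downsampled envelopes.
#'
#' @param Ws Muscles x s synergy matrix.
#' @param U Non-negative muscles x time matrix.
#' @param max_iter,tol Iteration cap and relative loss tolerance.
#' @return s x time activation matrix.
#' @export
project_activations <- function(Ws, U, max_iter = 200L, tol = 1e-10) {
  Ws <- as.matrix(Ws); U <- as.matrix(U)
  C0 <- crossprod(Ws, U)
  C0[C0 < 0] <- 0  # warm start from clipped unconstrained projection
  res <- nmf_hals_cpp(U, Ws, C0, as.integer(max_iter), tol, FALSE)
  C <- res$C
  rownames(C) <- colnames(Ws)
  C
}
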