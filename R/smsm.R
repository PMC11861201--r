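# Skin-musculoskeletal spring-equilibrium model (SMSM).
#
# Each facial keypoint is in force equilibrium between a linear skin
# spring of stiffness KH and one or two muscle springs with
# activation-dependent stiffness (k0 + k1 u) and rest length (l0 + l1 u).
# Single-muscle systems: outer eyebrow <- OF, nose <- LLSAN, chin <- Me.
# Double-muscle systems: inner eyebrow <- {IF, CS}, mouth corner <- {ZM, DAO},
# with per-muscle projection coefficients a_i and geometry factors lambda_i.

SMSM_SINGLE_WIRING <- c(outer_eyebrow = "OF", nose = "LLSAN", chin = "Me")
SMSM_DOUBLE_WIRING <- list(inner_eyebrow = c("IF", "CS"),
                           mouth_corner = c("ZM", "DAO"))

#' SMSM parameter set
#'
#' Spring parameters for the five keypoint systems. `singles` is a named
#' list (outer_eyebrow, nose, chin) of numeric vectors `c(k0, k1, l0,
#' l1)`; `doubles` is a named list (inner_eyebrow, mouth_corner) of lists
#' with per-muscle vectors `k0, k1, l0, l1` (length 2, first/second
#' member muscle) plus `a` and `lambda` (length 2).
#'
#' Units: KH, k0 in N/m; k1 in N/m per unit activation; l0, l1 in
#' displacement units (and per unit activation). Activations are
#' dimensionless fractions of MVC.
#'
#' @param KH Skin stiffness (default 100 N/m, held fixed).
#' @param singles,doubles See description.
#' @return An object of class `smsm_parameters`.
#' @export
smsm_parameters <- function(KH = 100, singles, doubles) {
  stopifnot(KH > 0)
  if (!setequal(names(singles), names(SMSM_SINGLE_WIRING)))
    stop("singles must be named: ", paste(names(SMSM_SINGLE_WIRING), collapse = ", "))
  if (!setequal(names(doubles), names(SMSM_DOUBLE_WIRING)))
    stop("doubles must be named: ", paste(names(SMSM_DOUBLE_WIRING), collapse = ", "))
  for (nm in names(singles)) {
    p <- singles[[nm]]
    if (length(p) != 4L) stop("single system '", nm, "' needs c(k0, k1, l0, l1)")
    if (p[1L] <= 0 || p[2L] < 0) stop("single system '", nm, "': k0 > 0, k1 >= 0 required")
    names(singles[[nm]]) <- c("k0", "k1", "l0", "l1")
  }
  for (nm in names(doubles)) {
    p <- doubles[[nm]]
    for (f in c("k0", "k1", "l0", "l1", "a", "lambda"))
      if (length(p[[f]]) != 2L) stop("double system '", nm, "': field '", f,
                                     "' must have length 2")
    if (any(p$k0 <= 0) || any(p$k1 < 0))
      stop("double system '", nm, "': k0 > 0, k1 >= 0 required")
  }
  structure(list(KH = KH, singles = singles, doubles = doubles),
            class = "smsm_parameters")
}

#' @export
print.smsm_parameters <- function(x, ...) {
  cat("<smsm_parameters> KH =", x$KH, "N/m\n")
  for (nm in names(x$singles))
    cat(sprintf("  %-13s (%s):  k0=%.3g k1=%.3g l0=%.3g l1=%.3g\n", nm,
                SMSM_SINGLE_WIRING[[nm]], x$singles[[nm]][1], x$singles[[nm]][2],
                x$singles[[nm]][3], x$singles[[nm]][4]))
  for (nm in names(x$doubles)) {
    p <- x$doubles[[nm]]
    mus <- SMSM_DOUBLE_WIRING[[nm]]
    for (i in 1:2)
      cat(sprintf("  %-13s (%s): k0=%.3g k1=%.3g l0=%.3g l1=%.3g a=%.3g lambda=%.3g\n",
                  nm, mus[i], p$k0[i], p$k1[i], p$l0[i], p$l1[i], p$a[i], p$lambda[i]))
  }
  invisible(x)
}

#' Default ground-truth SMSM parameters for the synthetic generator
#'
#' Stiffnesses of order 10 N/m (intrinsic) plus 20 N/m per unit
#' activation against the fixed 100 N/m skin spring; rest offsets l0 = 0
#' so the neutral pose has zero displacement; activation-dependent rest
#' length changes of a few hundredths of a displacement unit, with
#' antagonist muscles (CS, DAO) acting with opposite sign.
#'
#' @return An `smsm_parameters` object.
#' @export
default_smsm_parameters <- function() {
  smsm_parameters(
    KH = 100,
    singles = list(outer_eyebrow = c(10, 20, 0, 0.030),
                   nose          = c(10, 20, 0, 0.025),
                   chin          = c(10, 20, 0, 0.020)),
    doubles = list(
      inner_eyebrow = list(k0 = c(10, 10), k1 = c(20, 20), l0 = c(0, 0),
                           l1 = c(0.030, -0.020), a = c(1, 1),
                           lambda = c(1, -1)),
      mouth_corner  = list(k0 = c(10, 10), k1 = c(20, 20), l0 = c(0, 0),
                           l1 = c(0.030, -0.020), a = c(1, 1),
                           lambda = c(1, -1))))
}

.check_denominator <- function(den, KH) {
  if (any(den < 1e-6 * KH))
    stop("SMSM equilibrium denominator below bound (", signif(min(den), 4),
         " < 1e-6 * KH)")
  den
}

#' Single-muscle spring-equilibrium displacement
#'
#' `dl = (k0 + k1 u) (l0 + l1 u) / (KH + k0 + k1 u)`, vectorised over `u`.
#'
#' @param k0,k1,l0,l1 Muscle spring parameters.
#' @param KH Skin stiffness.
#' @param u Activation(s) in `[0, ~1]`.
#' @return Displacement(s), same length as `u`.
#' @export
smsm_single_displacement <- function(k0, k1, l0, l1, KH, u) {
  den <- .check_denominator(KH + k0 + k1 * u, KH)
  (k0 + k1 * u) * (l0 + l1 * u) / den
}

#' Double-muscle spring-equilibrium displacement
#'
#' `dl = sum_i a_i (k0_i + k1_i u_i)(l0_i + l1_i u_i) /
#'      (KH + sum_i a_i lambda_i (k0_i + k1_i u_i))` over the two member
#' muscles, vectorised over time.
#'
#' @param p List with fields `k0, k1, l0, l1, a, lambda`, each length 2.
#' @param KH Skin stiffness.
#' @param u_pair Activations: length-2 vector or 2 x T matrix.
#' @return Displacement(s).
#' @export
smsm_double_displacement <- function(p, KH, u_pair) {
  U <- if (is.matrix(u_pair)) u_pair else matrix(u_pair, nrow = 2L)
  num <- 0; den <- KH
  for (i in 1:2) {
    s <- p$k0[i] + p$k1[i] * U[i, ]
    num <- num + p$a[i] * s * (p$l0[i] + p$l1[i] * U[i, ])
    den <- den + p$a[i] * p$lambda[i] * s
  }
  .check_denominator(den, KH)
  out <- num / den
  if (!is.matrix(u_pair)) out else as.numeric(out)
}

#' SMSM forward map: muscle activations to keypoint displacements
#'
#' Applies the single- or double-muscle equilibrium per keypoint per time
#' step, with the fixed anatomical wiring (OF to outer eyebrow, LLSAN to
#' nose, Me to chin, ZM+DAO to mouth corner, IF+CS to inner eyebrow).
#'
#' @param p An [smsm_parameters()] object.
#' @param U 7 x T activation matrix with rows in canonical muscle order
#'   (rownames used when present).
#' @return 5 x T displacement matrix in canonical keypoint order.
#' @export
smsm_forward <- function(p, U) {
  stopifnot(inherits(p, "smsm_parameters"))
  if (!is.matrix(U)) U <- matrix(U, ncol = 1L)
  if (nrow(U) != 7L) stop("U must have 7 rows (muscles)")
  if (!is.null(rownames(U)) && !identical(rownames(U), FACE_MUSCLES))
    U <- U[FACE_MUSCLES, , drop = FALSE]
  D <- matrix(0, 5L, ncol(U), dimnames = list(FACE_KEYPOINTS, NULL))
  for (nm in names(SMSM_SINGLE_WIRING)) {
    sp <- p$singles[[nm]]
    D[nm, ] <- smsm_single_displacement(sp["k0"], sp["k1"], sp["l0"], sp["l1"],
                                        p$KH, U[match(SMSM_SINGLE_WIRING[[nm]],
                                                      FACE_MUSCLES), ])
  }
  for (nm in names(SMSM_DOUBLE_WIRING)) {
    rows <- match(SMSM_DOUBLE_WIRING[[nm]], FACE_MUSCLES)
    D[nm, ] <- smsm_double_displacement(p$doubles[[nm]], p$KH,
                                        U[rows, , drop = FALSE])
  }
  D
}

#' Linear regression model prediction
#'
#' `dL = W_LRM U`: a 5 x 7 weight matrix applied to the seven muscle
#' activations.
#'
#' @param W_LRM 5 x 7 weight matrix.
#' @param U 7 x T activation matrix.
#' @return 5 x T displacement matrix.
#' @export
lrm_predict <- function(W_LRM, U) {
  W_LRM <- as.matrix(W_LRM)
  if (!is.matrix(U)) U <- matrix(U, ncol = 1L)
  if (nrow(W_LRM) != 5L || ncol(W_LRM) != 7L) stop("W_LRM must be 5 x 7")
  if (nrow(U) != 7L) stop("U must have 7 rows")
  out <- W_LRM %*% U
  rownames(out) <- FACE_KEYPOINTS
  out
}

#' Hybrid SMSM-LRM prediction
#'
#' `dL = W smsm_forward(p, U)`: a 5 x 5 coupling matrix applied to the
#' per-point spring-equilibrium displacements, capturing skin
#' connectivity between keypoints that the local systems ignore.
#'
#' @param p An [smsm_parameters()] object.
#' @param W_hybrid 5 x 5 coupling matrix.
#' @param U 7 x T activation matrix.
#' @return 5 x T displacement matrix.
#' @export
hybrid_predict <- function(p, W_hybrid, U) {
  W_hybrid <- as.matrix(W_hybrid)
  if (nrow(W_hybrid) != 5L || ncol(W_hybrid) != 5L) stop("W_hybrid must be 5 x 5")
  out <- W_hybrid %*% smsm_forward(p, U)
  rownames(out) <- FACE_KEYPOINTS
  out
}
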