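# Cross-dataset synergy matching and per-expression activation-cluster
# summaries (centroid + 3-D convex hull) in synergy space.

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_permutations(n - 1L))
    for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
  out
}

#' Match synergies across decompositions and score their similarity
#'
#' Finds the one-to-one pairing of synergy columns between two
#' decompositions that maximises the total cosine similarity (exhaustive
#' search over permutations; ranks are at most 7 so this is exact), and
#' returns the pairing with the per-pair cosines.
#'
#' @param A,B `synergy_decomposition` objects (or plain synergy matrices)
#'   with equal muscle counts and equal rank.
#' @return List with `pairing` (column of B matched to each column of A)
#'   and `cosine` (per-pair cosine similarity).
#' @export
match_and_similarity <- function(A, B) {
  Wa <- if (inherits(A, "synergy_decomposition")) A$Ws else as.matrix(A)
  Wb <- if (inherits(B, "synergy_decomposition")) B$Ws else as.matrix(B)
  if (nrow(Wa) != nrow(Wb)) stop("muscle counts differ")
  if (ncol(Wa) != ncol(Wb)) stop("ranks differ (", ncol(Wa), " vs ", ncol(Wb), ")")
  s <- ncol(Wa)
  na <- sqrt(colSums(Wa^2)); nb <- sqrt(colSums(Wb^2))
  S <- crossprod(Wa, Wb) / outer(na, nb)  # cosine matrix
  S[!is.finite(S)] <- 0
  best <- NULL; best_total <- -Inf
  for (perm in all_permutations(s)) {
    tot <- sum(S[cbind(seq_len(s), perm)])
    if (tot > best_total) { best_total <- tot; best <- unlist(perm) }
  }
  list(pairing = best, cosine = S[cbind(seq_len(s), best)])
}

# ---- 3-D convex hull (incremental) ---------------------------------------

# Returns list(vertices = row indices of hull vertices, faces = integer
# matrix of triangles, volume, degenerate). Coplanar/collinear input is
# degenerate with volume 0.
convex_hull_3d <- function(P) {
  P <- as.matrix(P)
  stopifnot(ncol(P) == 3L)
  P <- P[!duplicated(round(P, 12L)), , drop = FALSE]
  n <- nrow(P)
  scale <- max(apply(P, 2L, function(x) diff(range(x))), 0)
  eps <- max(1e-12, 1e-9 * scale)
  degenerate <- function() list(points = P, vertices = seq_len(n), faces = NULL,
                                volume = 0, degenerate = TRUE)
  if (n < 4L || scale == 0) return(degenerate())

  # seed tetrahedron
  i1 <- which.min(P[, 1L])
  d1 <- rowSums(sweep(P, 2L, P[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] < eps^2) return(degenerate())
  e1 <- P[i2, ] - P[i1, ]
  crossv <- function(a, b) c(a[2]*b[3] - a[3]*b[2], a[3]*b[1] - a[1]*b[3],
                             a[1]*b[2] - a[2]*b[1])
  d2 <- apply(P, 1L, function(q) sum(crossv(e1, q - P[i1, ])^2))
  i3 <- which.max(d2)
  if (d2[i3] < (eps * sqrt(sum(e1^2)))^2) return(degenerate())
  nrm <- crossv(e1, P[i3, ] - P[i1, ])
  d3 <- abs(as.numeric(P %*% nrm) - sum(nrm * P[i1, ]))
  i4 <- which.max(d3)
  if (d3[i4] < eps * sqrt(sum(nrm^2))) return(degenerate())

  interior <- colMeans(P[c(i1, i2, i3, i4), ])
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    nn <- crossv(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
    if (sum(nn * (interior - P[f[1], ])) > 0) f[c(1L, 3L, 2L)] else f
  }
  faces <- lapply(faces, orient)
  face_normal <- function(f) crossv(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])

  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- vapply(faces, function(f) {
      nn <- face_normal(f)
      sum(nn * (P[p, ] - P[f[1], ])) > eps * sqrt(sum(nn^2))
    }, logical(1L))
    if (!any(vis)) next
    vis_faces <- faces[vis]
    keep_faces <- faces[!vis]
    # horizon: edges of visible faces appearing exactly once among them
    edges <- do.call(rbind, lapply(vis_faces, function(f)
      rbind(sort(c(f[1], f[2])), sort(c(f[2], f[3])), sort(c(f[1], f[3])))))
    key <- paste(edges[, 1L], edges[, 2L])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    new_faces <- lapply(seq_len(nrow(horizon)), function(i)
      orient(c(horizon[i, 1L], horizon[i, 2L], p)))
    faces <- c(keep_faces, new_faces)
  }
  fmat <- do.call(rbind, faces)
  vol <- 0
  for (i in seq_len(nrow(fmat))) {
    f <- fmat[i, ]
    vol <- vol + det(rbind(P[f[1], ] - interior, P[f[2], ] - interior,
                           P[f[3], ] - interior)) / 6
  }
  list(points = P, vertices = sort(unique(as.vector(fmat))), faces = fmat,
       volume = abs(vol), degenerate = FALSE)
}

#' Per-expression activation clusters in synergy space
#'
#' For each label in the trial structure, collects the synergy activation
#' points (columns of `C` falling inside that label's segments) and
#' summarises them by their centroid and the 3-D convex hull containing
#' them (vertex set and volume). Fewer than four non-coplanar points give
#' a degenerate hull with volume 0.
#'
#' @param C 3 x T synergy activation matrix (rank must be 3), or a
#'   `synergy_decomposition` of rank 3.
#' @param structure [trial_structure()] labelling the T samples.
#' @param fs Sampling rate of `C` in Hz.
#' @return Named list per label: `centroid`, `n_points`, `hull_volume`,
#'   `hull_vertices` (points in synergy space), `degenerate`.
#' @export
activation_clusters <- function(C, structure, fs) {
  if (inherits(C, "synergy_decomposition")) C <- C$C
  C <- as.matrix(C)
  if (nrow(C) != 3L) stop("activation clusters require rank 3 (3-D synergy space)")
  times <- (seq_len(ncol(C)) - 1) / fs
  labs <- segment_labels_at(structure, times)
  out <- list()
  for (lab in unique(stats::na.omit(labs))) {
    pts <- t(C[, which(labs == lab), drop = FALSE])
    hull <- convex_hull_3d(pts)
    out[[lab]] <- list(centroid = colMeans(pts), n_points = nrow(pts),
                       hull_volume = hull$volume,
                       hull_vertices = hull$points[hull$vertices, , drop = FALSE],
                       degenerate = hull$degenerate)
  }
  out
}
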