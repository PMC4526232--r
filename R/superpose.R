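# Least-squares superposition of trajectory frames (Kabsch), vectorised over
# frames: the 3x3 cross-covariances for all frames come from nine matrix-vector
# products; only the tiny 3x3 SVD runs per frame.

#' Superpose trajectory frames onto a reference
#'
#' Weighted least-squares fit of every frame onto `ref`, computed on the
#' `fit_idx` atoms and applied to the whole frame. When `ref` is NULL the
#' frames are fitted to their own mean structure (two refinement passes).
#'
#' @param x frames matrix (rows = frames, columns = 3N flat coordinates)
#' @param ref reference coordinates: length-3N vector or N x 3 matrix, or NULL
#' @param fit_idx atom indices (1..N) of the fit group; default all atoms
#' @param weights per-fit-atom weights (e.g. masses); default uniform
#' @return the superposed frames matrix
#' @export
superpose_frames <- function(x, ref = NULL, fit_idx = NULL, weights = NULL) {
  N <- ncol(x) / 3
  if (is.null(fit_idx)) fit_idx <- seq_len(N)
  if (is.null(weights)) weights <- rep(1, length(fit_idx))
  if (is.null(ref)) {
    ref <- colMeans(x)
    x <- superpose_frames(x, ref, fit_idx, weights)
    ref <- colMeans(x)
    return(superpose_frames(x, ref, fit_idx, weights))
  }
  if (is.matrix(ref) && ncol(ref) == 3) ref <- as.vector(t(ref))
  cols <- .xyz_cols(fit_idx)
  w <- weights / sum(weights)
  refm <- matrix(ref[cols], ncol = 3, byrow = TRUE)
  refc <- colSums(refm * w)
  refm <- sweep(refm, 2, refc)

  nf <- nrow(x)
  sel <- x[, cols, drop = FALSE]
  xs <- sel[, seq(1, ncol(sel), 3), drop = FALSE]
  ys <- sel[, seq(2, ncol(sel), 3), drop = FALSE]
  zs <- sel[, seq(3, ncol(sel), 3), drop = FALSE]
  cx <- as.vector(xs %*% w); cy <- as.vector(ys %*% w); cz <- as.vector(zs %*% w)
  xs <- xs - cx; ys <- ys - cy; zs <- zs - cz
  # C[f, a, b] = sum_i w_i frame[f, i, a] ref[i, b]
  C <- array(0, c(nf, 3, 3))
  for (b in 1:3) {
    rb <- refm[, b] * w
    C[, 1, b] <- xs %*% rb
    C[, 2, b] <- ys %*% rb
    C[, 3, b] <- zs %*% rb
  }
  out <- matrix(0, nf, ncol(x))
  xcols <- seq(1, ncol(x), 3)
  fx <- x[, xcols, drop = FALSE] - cx
  fy <- x[, xcols + 1, drop = FALSE] - cy
  fz <- x[, xcols + 2, drop = FALSE] - cz
  for (f in seq_len(nf)) {
    sv <- svd(C[f, , ])
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # maps frame coords onto ref
    rot <- cbind(fx[f, ], fy[f, ], fz[f, ]) %*% t(R)
    out[f, xcols] <- rot[, 1] + refc[1]
    out[f, xcols + 1] <- rot[, 2] + refc[2]
    out[f, xcols + 2] <- rot[, 3] + refc[3]
  }
  out
}

# RMSD between one flat frame and a flat reference over given atom indices
.rmsd_flat <- function(frame, ref, atom_idx) {
  cols <- .xyz_cols(atom_idx)
  sqrt(mean((frame[cols] - ref[cols])^2) * 3)
}

# orthonormal basis of the 6 rigid-body directions (mass-weighted convention)
.rigid_basis <- function(ref_xyz, masses) {
  N <- nrow(ref_xyz)
  sm <- sqrt(masses)
  xc <- sweep(ref_xyz, 2, colSums(ref_xyz * masses) / sum(masses))
  B <- matrix(0, 3 * N, 6)
  for (a in 1:3) B[seq(a, 3 * N, by = 3), a] <- sm
  for (a in 1:3) {
    w <- diag(3)[a, ]
    rot <- cbind(w[2] * xc[, 3] - w[3] * xc[, 2],
                 w[3] * xc[, 1] - w[1] * xc[, 3],
                 w[1] * xc[, 2] - w[2] * xc[, 1])
    B[, 3 + a] <- as.vector(t(rot)) * rep(sm, each = 3)
  }
  qr.Q(qr(B))
}
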