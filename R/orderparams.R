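# NMR-style order parameters: methyl-axis S^2 from second moments of the
# axis unit vector, and residue dihedral order parameters from circular
# moments.

#' Squared generalized order parameter of an axis-vector series
#'
#' S^2 of a unit-vector time series from its Cartesian second moments:
#' \deqn{S^2 = \frac{3}{2}\left[\langle x^2\rangle^2 + \langle y^2\rangle^2 +
#'   \langle z^2\rangle^2 + 2\langle xy\rangle^2 + 2\langle xz\rangle^2 +
#'   2\langle yz\rangle^2\right] - \frac{1}{2}}
#' 1 for a rigid axis, 0 for isotropic disorder. When `window_frames` is
#' given the series is cut into non-overlapping windows, S^2 computed per
#' window and averaged (the windowed convention of methyl-axis analyses).
#'
#' @param v n x 3 matrix of axis vectors (normalised internally)
#' @param window_frames frames per window, or NULL for the whole series
#' @return list with `s2` (mean over windows) and `per_window`
#' @export
s2_from_vectors <- function(v, window_frames = NULL) {
  v <- as.matrix(v)
  stopifnot(ncol(v) == 3)
  v <- v / sqrt(rowSums(v^2))
  one <- function(m) {
    x <- m[, 1]; y <- m[, 2]; z <- m[, 3]
    1.5 * (mean(x^2)^2 + mean(y^2)^2 + mean(z^2)^2 +
             2 * mean(x * y)^2 + 2 * mean(x * z)^2 + 2 * mean(y * z)^2) - 0.5
  }
  if (is.null(window_frames) || window_frames >= nrow(v)) {
    s <- one(v)
    return(list(s2 = s, per_window = s))
  }
  nw <- nrow(v) %/% window_frames
  if (nw < 1) stop("window longer than the series")
  pw <- vapply(seq_len(nw), function(w) {
    one(v[((w - 1) * window_frames + 1):(w * window_frames), , drop = FALSE])
  }, numeric(1))
  list(s2 = mean(pw), per_window = pw)
}

#' Methyl-axis order parameters of an ensemble
#'
#' Computes S^2 for every axis vector defined in the topology (for 4-point
#' synthetic residues, the CA -> side-chain-centroid pseudo-axis). Frames are
#' superposed to remove global rotation, each replica is cut into windows of
#' `window_ps` (default 3 ns), S^2 computed per window and averaged over
#' windows and replicas.
#'
#' @param ens a `traj_ensemble`
#' @param topology the matching `topology` (defaults to the ensemble's); must
#'   define `axes`
#' @param window_ps window length in ps
#' @param superpose superpose frames first (default TRUE)
#' @return class `op_profile`: data.frame with `label`, `s2`; per-window
#'   values in `attr(, "per_window")`
#' @export
methyl_axis_s2 <- function(ens, topology = NULL, window_ps = 3000,
                           superpose = TRUE) {
  if (is.null(topology)) topology <- ens$topology
  ax <- topology$axes
  if (is.null(ax) || !nrow(ax)) {
    stop("topology defines no axis vectors (needs a 4-point model or explicit axes)")
  }
  if (window_ps <= 0) stop("window_ps must be positive")
  wf <- max(1L, as.integer(round(window_ps / ens$dt_ps)))
  nfr <- vapply(ens$replicas, nrow, integer(1))
  if (any(wf > nfr)) {
    stop("window (", wf, " frames) longer than a replica (", min(nfr), " frames)")
  }
  serial <- topology$atoms$serial
  i_from <- match(ax$from, serial)
  i_to <- match(ax$to, serial)
  vals <- matrix(NA_real_, nrow(ax), length(ens$replicas))
  pw <- vector("list", nrow(ax))
  for (r in seq_along(ens$replicas)) {
    xyz <- ens$replicas[[r]]
    if (superpose) xyz <- superpose_frames(xyz, weights = topology$atoms$mass)
    for (a in seq_len(nrow(ax))) {
      v <- xyz[, .xyz_cols(i_to[a]), drop = FALSE] -
        xyz[, .xyz_cols(i_from[a]), drop = FALSE]
      res <- s2_from_vectors(v, wf)
      vals[a, r] <- res$s2
      pw[[a]] <- c(pw[[a]], res$per_window)
    }
  }
  out <- data.frame(label = ax$label, s2 = rowMeans(vals),
                    stringsAsFactors = FALSE)
  attr(out, "per_window") <- pw
  attr(out, "window_ps") <- wf * ens$dt_ps
  attr(out, "state") <- ens$state
  attr(out, "kind") <- "methyl_axis"
  class(out) <- c("op_profile", "data.frame")
  out
}

#' Circular order parameter of an angle series
#'
#' S = <cos x>^2 + <sin x>^2: 1 for a frozen angle, 0 for a uniformly
#' circular one. For a von Mises distribution with concentration kappa,
#' S = (I1(kappa)/I0(kappa))^2.
#'
#' @param x angles in radians
#' @return scalar in [0, 1]
#' @export
circular_order_parameter <- function(x) {
  mean(cos(x))^2 + mean(sin(x))^2
}

#' Dihedral angles over trajectory frames
#'
#' Standard atan2 torsion angle of an atom quadruple, vectorised over frames.
#'
#' @param xyz frames matrix (rows = frames, 3N columns)
#' @param quad integer vector of 4 atom indices (1..N)
#' @return angle per frame, radians in (-pi, pi]
#' @export
dihedral_angles <- function(xyz, quad) {
  p <- lapply(quad, function(a) xyz[, .xyz_cols(a), drop = FALSE])
  b1 <- p[[2]] - p[[1]]
  b2 <- p[[3]] - p[[2]]
  b3 <- p[[4]] - p[[3]]
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
              n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
              n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1])
  b2n <- sqrt(rowSums(b2^2))
  atan2(rowSums(m1 * n2) / b2n, rowSums(n1 * n2))
}

#' Residue dihedral order parameters
#'
#' For every dihedral defined in the topology, S = <cos chi>^2 + <sin chi>^2
#' over the concatenated ensemble (internal coordinates: no superposition
#' needed); the per-residue value is the mean over that residue's dihedrals.
#'
#' @param ens a `traj_ensemble`
#' @param topology the matching `topology` (defaults to the ensemble's); must
#'   define `dihedrals`
#' @param dihedrals optional data.frame overriding the topology definitions
#'   (columns `label`, `residue`, `a1`..`a4`, atom serials)
#' @return class `op_profile`: data.frame with `label` (residue), `s`;
#'   per-dihedral values in `attr(, "per_dihedral")`
#' @export
dihedral_order_parameters <- function(ens, topology = NULL, dihedrals = NULL) {
  if (is.null(topology)) topology <- ens$topology
  if (is.null(dihedrals)) dihedrals <- topology$dihedrals
  if (is.null(dihedrals) || !nrow(dihedrals)) {
    stop("topology defines no dihedrals (needs a 4-point model or explicit quadruples)")
  }
  serial <- topology$atoms$serial
  xyz <- do.call(rbind, ens$replicas)
  svals <- numeric(nrow(dihedrals))
  ok <- rep(TRUE, nrow(dihedrals))
  for (d in seq_len(nrow(dihedrals))) {
    quad <- match(c(dihedrals$a1[d], dihedrals$a2[d], dihedrals$a3[d],
                    dihedrals$a4[d]), serial)
    if (anyNA(quad)) {
      warning("skipping dihedral ", dihedrals$label[d],
              ": unresolvable atoms (chain break?)")
      ok[d] <- FALSE
      next
    }
    chi <- dihedral_angles(xyz, quad)
    svals[d] <- circular_order_parameter(chi)
  }
  dres <- dihedrals$residue[ok]
  sv <- svals[ok]
  agg <- tapply(sv, dres, mean)
  out <- data.frame(label = names(agg), s = as.numeric(agg),
                    stringsAsFactors = FALSE)
  per <- data.frame(label = dihedrals$label[ok], residue = dres, s = sv,
                    stringsAsFactors = FALSE)
  attr(out, "per_dihedral") <- per
  attr(out, "state") <- ens$state
  attr(out, "kind") <- "dihedral"
  class(out) <- c("op_profile", "data.frame")
  out
}

#' Order-parameter difference between two states
#'
#' Delta = S_before - S_after, so a positive difference means a flexibility
#' gain after the event (e.g. ligand binding) and a negative one a loss.
#'
#' @param before,after `op_profile` objects over the same vectors/residues
#' @return data.frame with `label`, `delta`
#' @export
order_parameter_difference <- function(before, after) {
  stopifnot(inherits(before, "op_profile"), inherits(after, "op_profile"))
  if (!identical(attr(before, "kind"), attr(after, "kind"))) {
    stop("profiles of different kinds: ", attr(before, "kind"), " vs ",
         attr(after, "kind"))
  }
  if (!setequal(before$label, after$label)) {
    stop("profiles cover different vectors/residues")
  }
  col <- if ("s2" %in% names(before)) "s2" else "s"
  i <- match(before$label, after$label)
  data.frame(label = before$label,
             delta = before[[col]] - after[[col]][i],
             stringsAsFactors = FALSE)
}
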