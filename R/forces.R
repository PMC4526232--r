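# Exact pairwise and atomic forces of the spring potential on sampled frames.

#' Per-frame pairwise force vectors from a model
#'
#' Evaluates the exact spring force on every bonded pair at every frame:
#' F_ij = k (r - r0) \\hat{d} is the force on atom i from atom j (attractive
#' when the spring is stretched). Pairs are stored once with i < j;
#' antisymmetry F_ji = -F_ij is implicit. Ligand springs are included, so
#' ligand-node forces are attributed to the ligand pseudo-residue downstream.
#'
#' @param model a `toy_model`
#' @param ens a `traj_ensemble` generated from the same model
#' @return an object of class `pair_force_set`: per replica an array
#'   (frames x pairs x 3) in kJ mol^-1 nm^-1
#' @export
pairwise_forces_from_model <- function(model, ens) {
  .check_traj_matches(model, ens)
  sp <- model$springs
  replicas <- lapply(ens$replicas, function(xyz) {
    nf <- nrow(xyz)
    out <- array(0, dim = c(nf, nrow(sp), 3))
    for (e in seq_len(nrow(sp))) {
      ii <- (3 * sp$i[e] - 2):(3 * sp$i[e])
      jj <- (3 * sp$j[e] - 2):(3 * sp$j[e])
      d <- xyz[, jj, drop = FALSE] - xyz[, ii, drop = FALSE]
      r <- sqrt(rowSums(d^2))
      out[, e, ] <- d * (sp$k[e] * (r - sp$r0[e]) / r)
    }
    out
  })
  structure(list(pairs = sp[, c("i", "j")], topology = ens$topology,
                 replicas = replicas, state = ens$state, dt_ps = ens$dt_ps),
            class = "pair_force_set")
}

#' @export
print.pair_force_set <- function(x, ...) {
  cat("pair_force_set [", x$state, "]: ", length(x$replicas), " replica(s), ",
      nrow(x$pairs), " atom pairs\n", sep = "")
  invisible(x)
}

.check_traj_matches <- function(model, ens) {
  if (!inherits(ens, "traj_ensemble")) stop("ens must be a traj_ensemble")
  if (ncol(ens$replicas[[1]]) != 3 * nrow(model$xyz)) {
    stop("topology mismatch: ensemble has ", ncol(ens$replicas[[1]]) / 3,
         " atoms, model has ", nrow(model$xyz))
  }
  invisible(TRUE)
}

#' Per-frame total atomic forces from a model
#'
#' Sums the exact spring forces acting on each atom at every frame; the input
#' of the force-covariance entropy estimator.
#'
#' @param model a `toy_model`
#' @param ens a `traj_ensemble` generated from the same model
#' @return class `atomic_forces`: list of (frames x 3N) matrices, one per
#'   replica, with the model reference coordinates attached
#' @export
atomic_forces_from_model <- function(model, ens) {
  .check_traj_matches(model, ens)
  sp <- model$springs
  replicas <- lapply(ens$replicas, function(xyz) {
    nf <- nrow(xyz)
    F <- matrix(0, nf, ncol(xyz))
    for (e in seq_len(nrow(sp))) {
      ii <- (3 * sp$i[e] - 2):(3 * sp$i[e])
      jj <- (3 * sp$j[e] - 2):(3 * sp$j[e])
      d <- xyz[, jj, drop = FALSE] - xyz[, ii, drop = FALSE]
      r <- sqrt(rowSums(d^2))
      Fij <- d * (sp$k[e] * (r - sp$r0[e]) / r)
      F[, ii] <- F[, ii] + Fij
      F[, jj] <- F[, jj] - Fij
    }
    F
  })
  structure(list(replicas = replicas, topology = ens$topology,
                 reference = model$xyz, state = ens$state),
            class = "atomic_forces")
}

#' Total atomic forces by summation of a pairwise force set
#'
#' @param pfs a `pair_force_set`
#' @param reference optional N x 3 reference coordinates to attach (needed for
#'   rigid-body projection in the entropy estimator)
#' @return class `atomic_forces`
#' @export
atomic_forces <- function(pfs, reference = NULL) {
  stopifnot(inherits(pfs, "pair_force_set"))
  N <- n_atoms(pfs$topology)
  replicas <- lapply(pfs$replicas, function(arr) {
    nf <- dim(arr)[1]
    F <- matrix(0, nf, 3 * N)
    for (e in seq_len(nrow(pfs$pairs))) {
      ii <- (3 * pfs$pairs$i[e] - 2):(3 * pfs$pairs$i[e])
      jj <- (3 * pfs$pairs$j[e] - 2):(3 * pfs$pairs$j[e])
      F[, ii] <- F[, ii] + arr[, e, ]
      F[, jj] <- F[, jj] - arr[, e, ]
    }
    F
  })
  structure(list(replicas = replicas, topology = pfs$topology,
                 reference = reference, state = pfs$state),
            class = "atomic_forces")
}
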