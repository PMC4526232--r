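# Configurational entropy from coordinate covariance (quasi-harmonic, QH) or
# force covariance (FC). Both assume a harmonic system and differ only in how
# mode frequencies are extracted:
#   QH: eigenvalues lambda of the mass-weighted coordinate covariance give
#       omega = sqrt(kB T / lambda)
#   FC: eigenvalues mu of the mass-weighted force covariance (f_i / sqrt(m_i))
#       give omega = sqrt(mu / (kB T))
# Each retained mode contributes the quantum harmonic-oscillator entropy.

.entropy_result <- function(estimator, omega, temperature, selection,
                            n_frames, replica_stats = NULL) {
  per_mode <- qho_entropy(omega, temperature)
  S <- sum(per_mode)
  structure(list(estimator = estimator, omega = omega, per_mode = per_mode,
                 S_kJ_mol_K = S,
                 minus_TS_kcal = -temperature * S / .KCAL,
                 temperature = temperature, selection = selection,
                 n_modes = length(omega), n_frames = n_frames,
                 replica_stats = replica_stats),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat("entropy_result [", x$estimator, "] selection=", x$selection,
      " T=", x$temperature, "K\n", sep = "")
  cat("  ", x$n_modes, " modes, S = ", signif(x$S_kJ_mol_K, 6),
      " kJ/mol/K, -TS = ", signif(x$minus_TS_kcal, 6), " kcal/mol\n", sep = "")
  invisible(x)
}

# pooled covariance from a list of observation matrices, keeping per-replica
# sufficient statistics (n, column sums, crossproducts) for bootstrapping
.cov_stats <- function(mats) {
  stats <- lapply(mats, function(m) list(n = nrow(m), s = colSums(m),
                                         cp = crossprod(m)))
  list(stats = stats, cov = .combine_cov(stats))
}

.combine_cov <- function(stats) {
  n <- sum(vapply(stats, `[[`, numeric(1), "n"))
  s <- Reduce(`+`, lapply(stats, `[[`, "s"))
  cp <- Reduce(`+`, lapply(stats, `[[`, "cp"))
  mu <- s / n
  (cp - n * tcrossprod(mu)) / (n - 1)
}

# QH frequencies from a (mass-weighted) covariance matrix
.qh_omega <- function(cov, temperature, null_tol = 1e-9) {
  lam <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  keep <- lam >= null_tol * max(lam)
  if (sum(!keep) > 6) {
    warning("coordinate covariance is singular beyond rigid-body rank ",
            "deficiency (", sum(!keep), " null modes dropped)")
  }
  sort(sqrt(.kB * temperature / lam[keep]))
}

# FC frequencies from a (mass-weighted) force covariance matrix
.fc_omega <- function(cov, temperature, null_tol = 1e-10) {
  mu <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  keep <- mu >= null_tol * max(mu)
  if (!any(keep)) stop("force covariance has no modes above the numerical floor")
  if (sum(!keep) > 6) {
    warning(sum(!keep), " zero-variance force modes dropped")
  }
  sort(sqrt(mu[keep] / (.kB * temperature)))
}

#' Quasi-harmonic configurational entropy of an ensemble
#'
#' Frames are superposed onto the mean structure of the analysis selection
#' (the fit group is the selection itself), coordinates are mass-weighted and
#' the covariance matrix eigen-decomposed; each retained mode of frequency
#' omega = sqrt(kB T / lambda) contributes the quantum harmonic-oscillator
#' entropy. Rigid-body modes appear as near-zero-variance directions after
#' superposition and are dropped.
#'
#' @param ens a `traj_ensemble`
#' @param selection "full", "mainchain", "calpha", "protein" or atom serials
#' @param temperature temperature in K
#' @param superpose superpose frames before the covariance (default TRUE)
#' @return an `entropy_result` with per-replica statistics for bootstrapping
#' @export
quasi_harmonic_entropy <- function(ens, selection = "full", temperature = 300,
                                   superpose = TRUE) {
  sel_label <- if (is.character(selection)) selection else "custom"
  idx <- .select_atoms(ens$topology, selection)
  masses <- ens$topology$atoms$mass[idx]
  ndof <- 3 * length(idx)
  if (n_frames(ens) < 3 * length(idx)) {
    warning("fewer frames (", n_frames(ens), ") than 3 x selection size (",
            3 * length(idx), "); entropy will be underconverged")
  }
  mats <- lapply(ens$replicas, function(xyz) xyz[, .xyz_cols(idx), drop = FALSE])
  if (superpose) {
    all <- do.call(rbind, mats)
    all <- superpose_frames(all, ref = NULL, weights = masses)
    nfr <- vapply(mats, nrow, integer(1))
    mats <- split.data.frame(all, rep(seq_along(mats), nfr))
    mats <- lapply(mats, as.matrix)
  }
  sw <- rep(sqrt(masses), each = 3)
  mats <- lapply(mats, function(m) sweep(m, 2, sw, "*"))
  cs <- .cov_stats(mats)
  omega <- .qh_omega(cs$cov, temperature)
  .entropy_result("QH", omega, temperature, sel_label,
                  n_frames = n_frames(ens), replica_stats = cs$stats)
}

#' Force-covariance configurational entropy
#'
#' Mode frequencies from the covariance of mass-weighted atomic forces
#' (f_i / sqrt(m_i)): omega = sqrt(mu / (kB T)). For a harmonic oscillator
#' <f^2>/m = omega^2 kB T, so the estimator is exact in the harmonic limit and
#' needs no superposition (the force-covariance spectrum is invariant under
#' rigid rotation of all frames). When the selection covers the whole system
#' and reference coordinates are available, forces are first projected off the
#' six rigid-body directions (translational components vanish identically by
#' Newton's third law; rotational ones only to first order); remaining
#' zero-variance modes are dropped at a relative floor of 1e-10.
#'
#' @param forces an `atomic_forces` object (or list of frames x 3N matrices)
#' @param topology the matching `topology` (defaults to the one in `forces`)
#' @param selection "full", "mainchain", "calpha", "protein" or atom serials
#' @param temperature temperature in K
#' @param project_rigid project out rigid-body force components (default: TRUE
#'   when the selection is the full system and a reference is available)
#' @return an `entropy_result` with per-replica statistics for bootstrapping
#' @export
force_covariance_entropy <- function(forces, topology = NULL,
                                     selection = "full", temperature = 300,
                                     project_rigid = NULL) {
  if (is.list(forces) && !inherits(forces, "atomic_forces")) {
    forces <- structure(list(replicas = forces, topology = topology,
                             reference = NULL, state = NA), class = "atomic_forces")
  }
  if (is.null(topology)) topology <- forces$topology
  sel_label <- if (is.character(selection)) selection else "custom"
  idx <- .select_atoms(topology, selection)
  masses <- topology$atoms$mass[idx]
  full <- length(idx) == n_atoms(topology)
  if (is.null(project_rigid)) {
    project_rigid <- full && !is.null(forces$reference)
  }
  sw <- rep(sqrt(masses), each = 3)
  mats <- lapply(forces$replicas, function(F) {
    sweep(F[, .xyz_cols(idx), drop = FALSE], 2, sw, "/")
  })
  if (project_rigid) {
    if (is.null(forces$reference)) stop("rigid projection needs reference coordinates")
    Q <- .rigid_basis(forces$reference[idx, , drop = FALSE], masses)
    mats <- lapply(mats, function(m) m - (m %*% Q) %*% t(Q))
  }
  cs <- .cov_stats(mats)
  omega <- .fc_omega(cs$cov, temperature)
  nf <- sum(vapply(mats, nrow, integer(1)))
  .entropy_result("FC", omega, temperature, sel_label, n_frames = nf,
                  replica_stats = cs$stats)
}

#' Entropy estimators on raw sample matrices
#'
#' Low-level interface for arbitrary-dimensional harmonic(-ish) systems:
#' each row of `x` (coordinates) or `f` (forces) is one observation, each
#' column one degree of freedom with mass `masses`. No superposition or
#' rigid-body handling is applied. Useful for closed-form oracles
#' (one-dimensional oscillators, quartic toys).
#'
#' @param x observation matrix of coordinates (QH), or NULL
#' @param f observation matrix of forces (FC), or NULL
#' @param masses mass per degree of freedom, amu (recycled)
#' @param temperature temperature in K
#' @return an `entropy_result`
#' @export
entropy_from_samples <- function(x = NULL, f = NULL, masses,
                                 temperature = 300) {
  if (is.null(x) == is.null(f)) stop("supply exactly one of x (QH) or f (FC)")
  if (!is.null(x)) {
    x <- as.matrix(x)
    m <- rep_len(masses, ncol(x))
    cov <- stats::cov(sweep(x, 2, sqrt(m), "*"))
    omega <- sort(sqrt(.kB * temperature / eigen(cov, symmetric = TRUE,
                                                 only.values = TRUE)$values))
    .entropy_result("QH", omega, temperature, "samples", nrow(x))
  } else {
    f <- as.matrix(f)
    m <- rep_len(masses, ncol(f))
    cov <- stats::cov(sweep(f, 2, sqrt(m), "/"))
    omega <- sort(sqrt(eigen(cov, symmetric = TRUE,
                             only.values = TRUE)$values / (.kB * temperature)))
    .entropy_result("FC", omega, temperature, "samples", nrow(f))
  }
}

#' Entropic contribution -T dS between two states
#'
#' Reports -T (S_B - S_A) in kcal/mol, the entropic contribution of the
#' A -> B change (e.g. a ligand-binding event) to the free energy. Positive
#' values are entropic penalties. Both results must come from the same
#' estimator and atom selection. If both carry per-replica statistics and at
#' least two replicas, a bootstrap over replicas yields an uncertainty band.
#'
#' @param a,b `entropy_result` objects for states A and B
#' @param temperature temperature in K for the -T dS report
#' @param n_boot bootstrap resamples over replicas (0 = point estimate only)
#' @param seed seed for the bootstrap
#' @return list with `minus_TdS_kcal`, and with `se`, `ci95`, `boot` when
#'   bootstrapped
#' @export
entropy_difference <- function(a, b, temperature = 300, n_boot = 200,
                               seed = 1L) {
  stopifnot(inherits(a, "entropy_result"), inherits(b, "entropy_result"))
  if (!identical(a$estimator, b$estimator) && !any(c(a$estimator, b$estimator) == "analytic")) {
    stop("estimator mismatch: ", a$estimator, " vs ", b$estimator)
  }
  if (!identical(a$selection, b$selection)) {
    stop("selection mismatch: ", a$selection, " vs ", b$selection)
  }
  point <- -temperature * (b$S_kJ_mol_K - a$S_kJ_mol_K) / .KCAL
  out <- list(minus_TdS_kcal = point, estimator = a$estimator,
              temperature = temperature)
  can_boot <- n_boot > 0 && !is.null(a$replica_stats) &&
    !is.null(b$replica_stats) && length(a$replica_stats) >= 2 &&
    length(b$replica_stats) >= 2
  if (can_boot) {
    set.seed(as.integer(seed))
    omega_of <- function(stats, est) {
      cov <- .combine_cov(stats)
      if (est == "QH") .qh_omega(cov, temperature) else .fc_omega(cov, temperature)
    }
    boots <- vapply(seq_len(n_boot), function(i) {
      sa <- a$replica_stats[sample(length(a$replica_stats), replace = TRUE)]
      sb <- b$replica_stats[sample(length(b$replica_stats), replace = TRUE)]
      Sa <- sum(qho_entropy(omega_of(sa, a$estimator), temperature))
      Sb <- sum(qho_entropy(omega_of(sb, b$estimator), temperature))
      -temperature * (Sb - Sa) / .KCAL
    }, numeric(1))
    out$se <- stats::sd(boots)
    out$ci95 <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    out$boot <- boots
  }
  class(out) <- "entropy_difference"
  out
}

#' @export
print.entropy_difference <- function(x, ...) {
  cat("-T dS [", x$estimator, "] = ", signif(x$minus_TdS_kcal, 5),
      " kcal/mol at T = ", x$temperature, " K\n", sep = "")
  if (!is.null(x$ci95)) {
    cat("  bootstrap 95% CI: [", signif(x$ci95[1], 5), ", ",
        signif(x$ci95[2], 5), "]\n", sep = "")
  }
  invisible(x)
}
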