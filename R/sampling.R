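# Ensemble sampling from the model's harmonic covariance.

#' Specify a sampling ensemble
#'
#' @param n_replicas number of independent replicas (>= 1); the convention of
#'   averaging over nine independent runs per state is the default
#' @param n_frames frames per replica (>= 2)
#' @param temperature temperature in K (> 0)
#' @param sampler "gaussian" (frames i.i.d. from the exact harmonic
#'   covariance kB*T*H^+) or "langevin" (overdamped Ornstein-Uhlenbeck
#'   dynamics per mode; same stationary covariance, time-correlated)
#' @param seed master integer seed; each replica derives its own stream
#' @param dt_ps frame spacing, ps
#' @param friction Langevin friction, amu/ps (mode correlation time is
#'   friction / mode stiffness)
#' @return an object of class `ensemble_spec`
#' @export
ensemble_spec <- function(n_replicas = 9L, n_frames = 1000L, temperature = 300,
                          sampler = c("gaussian", "langevin"), seed = 1L,
                          dt_ps = 20, friction = 2e4) {
  sampler <- match.arg(sampler)
  if (n_replicas < 1) stop("n_replicas must be >= 1")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(n_replicas = as.integer(n_replicas),
                 n_frames = as.integer(n_frames), temperature = temperature,
                 sampler = sampler, seed = as.integer(seed), dt_ps = dt_ps,
                 friction = friction),
            class = "ensemble_spec")
}

#' Per-replica seed stream
#'
#' Deterministic integer seed for replica `r` under master seed `seed`;
#' independent of how many replicas are requested, so adding replicas never
#' changes the frames of existing ones.
#'
#' @param seed master seed
#' @param r replica index (1-based)
#' @return integer seed
#' @export
replica_seed <- function(seed, r) {
  as.integer((abs(as.numeric(seed)) %% 99991) * 20011 + r * 104729) %% 2000000011L
}

#' Sample a trajectory ensemble from a model
#'
#' Draws frames about the model's equilibrium coordinates with covariance
#' kB*T*H^+ (pseudo-inverse of the spring Hessian, rigid-body modes excluded).
#' The Gaussian sampler draws frames independently, which makes the model's
#' analytic entropy the exact entropy of the sampled distribution; the
#' Langevin sampler evolves each mode as an exact-discretisation
#' Ornstein-Uhlenbeck process with correlation time friction/lambda_k, for
#' analyses that need time correlation (order-parameter windows).
#'
#' @param model a connected `toy_model`
#' @param spec an `ensemble_spec`
#' @param state state label carried through downstream tables ("apo", "cap1",
#'   "cap2", ...)
#' @return an object of class `traj_ensemble`
#' @export
sample_ensemble <- function(model, spec, state = "apo") {
  stopifnot(inherits(model, "toy_model"), inherits(spec, "ensemble_spec"))
  .check_connected(model)
  H <- enm_hessian(model)
  eH <- eigen(H, symmetric = TRUE)
  tol <- 1e-9 * max(eH$values)
  keep <- which(eH$values >= tol)
  V <- eH$vectors[, keep, drop = FALSE]
  lam <- eH$values[keep]
  sd_mode <- sqrt(.kB * spec$temperature / lam)
  x0 <- as.vector(t(model$xyz))
  seeds <- vapply(seq_len(spec$n_replicas), function(r) replica_seed(spec$seed, r),
                  integer(1))
  replicas <- vector("list", spec$n_replicas)
  for (r in seq_len(spec$n_replicas)) {
    set.seed(seeds[r])
    nf <- spec$n_frames
    if (spec$sampler == "gaussian") {
      Z <- matrix(stats::rnorm(nf * length(keep)), nf)
    } else {
      tau <- spec$friction / lam
      phi <- exp(-spec$dt_ps / tau)
      Z <- matrix(0, nf, length(keep))
      Z[1, ] <- stats::rnorm(length(keep))
      innov_sd <- sqrt(1 - phi^2)
      for (t in 2:nf) {
        Z[t, ] <- phi * Z[t - 1, ] + innov_sd * stats::rnorm(length(keep))
      }
    }
    dx <- Z %*% (t(V) * sd_mode)
    replicas[[r]] <- sweep(dx, 2, x0, "+")
  }
  structure(list(state = state, topology = model$topology, replicas = replicas,
                 dt_ps = spec$dt_ps, temperature = spec$temperature,
                 sampler = spec$sampler, seeds = seeds),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  nf <- vapply(x$replicas, nrow, integer(1))
  cat("traj_ensemble [", x$state, "]: ", length(x$replicas), " replica(s) x ",
      paste(unique(nf), collapse = "/"), " frames, ",
      ncol(x$replicas[[1]]) / 3, " atoms, dt ", x$dt_ps, " ps\n", sep = "")
  invisible(x)
}

#' Total frame count of an ensemble
#' @param ens a `traj_ensemble`
#' @return integer
#' @export
n_frames <- function(ens) sum(vapply(ens$replicas, nrow, integer(1)))

# all frames of an ensemble as one matrix (rows = frames)
.ens_frames <- function(ens, atom_idx = NULL) {
  x <- do.call(rbind, ens$replicas)
  if (!is.null(atom_idx)) x <- x[, .xyz_cols(atom_idx), drop = FALSE]
  x
}

#' Generate axis-vector series with a prescribed order parameter
#'
#' Wobble-in-cone series: unit vectors uniform over the spherical cap of
#' semi-angle theta0 chosen so that the cone-model order parameter
#' S = cos(theta0) (1 + cos(theta0)) / 2 satisfies S^2 = `s2_target`. Applying
#' the methyl-axis S^2 estimator to the output recovers `s2_target` up to
#' sampling noise. `s2_target = 0` samples the full sphere (isotropic);
#' `s2_target = 1` returns a constant vector.
#'
#' @param s2_target target squared order parameter in [0, 1]
#' @param n_frames number of vectors
#' @param seed integer seed
#' @return an `n_frames` x 3 matrix of unit vectors
#' @export
generate_axis_vectors <- function(s2_target, n_frames, seed = 1L) {
  if (s2_target < 0 || s2_target > 1) stop("s2_target must be in [0, 1]")
  set.seed(as.integer(seed))
  n <- as.integer(n_frames)
  if (s2_target == 1) {
    return(matrix(rep(c(0, 0, 1), each = n), n, 3))
  }
  ct0 <- if (s2_target == 0) -1 else (-1 + sqrt(1 + 8 * sqrt(s2_target))) / 2
  ct <- stats::runif(n, ct0, 1)
  ph <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - ct^2))
  cbind(st * cos(ph), st * sin(ph), ct)
}
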