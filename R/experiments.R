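# Validation experiments packaged as functions: each one generates its own
# synthetic ground truth, runs the estimator or detector under test, and
# reports the measured error. They double as the reproducibility entry points
# for the package's headline numbers.

#' Entropy-estimator recovery on a known harmonic dimer
#'
#' Samples a Gaussian ensemble from the exact covariance of an
#' elastic-network dimer and measures the relative error of the
#' quasi-harmonic and force-covariance entropy estimates against the model's
#' analytic mode-spectrum entropy.
#'
#' @param n_res_per_protomer dimer size (default 20)
#' @param n_frames frames to sample (default 1e5)
#' @param temperature temperature, K
#' @param seed integer seed
#' @return list with `S_analytic`, `S_qh`, `S_fc` (kJ/mol/K) and relative
#'   errors `rel_err_qh`, `rel_err_fc`
#' @export
entropy_recovery_experiment <- function(n_res_per_protomer = 20,
                                        n_frames = 1e5, temperature = 300,
                                        seed = 1L) {
  m <- build_enm_dimer(n_res_per_protomer, seed = seed)
  s_true <- analytic_entropy(m, temperature)$S_kJ_mol_K
  ens <- sample_ensemble(m, ensemble_spec(1, n_frames, temperature,
                                          seed = seed))
  qh <- quasi_harmonic_entropy(ens, temperature = temperature)
  fc <- force_covariance_entropy(atomic_forces_from_model(m, ens),
                                 temperature = temperature)
  list(S_analytic = s_true, S_qh = qh$S_kJ_mol_K, S_fc = fc$S_kJ_mol_K,
       rel_err_qh = (qh$S_kJ_mol_K - s_true) / s_true,
       rel_err_fc = (fc$S_kJ_mol_K - s_true) / s_true,
       n_frames = n_frames)
}

#' Estimator bias on a two-state quartic-perturbed oscillator
#'
#' One-dimensional double well V = k2/2 x^2 + eps x^4 (k2 < 0), sampled
#' exactly from its classical Boltzmann distribution by inverse-CDF; the
#' reference entropy is the exact quantum value from a dense finite-difference
#' diagonalisation of the 1-D Hamiltonian. In this multi-well regime the
#' coordinate covariance conflates inter-well spread with softness, so the
#' force-based estimate deviates less.
#'
#' @param k2 harmonic coefficient, kJ/mol/nm^2 (negative for a double well)
#' @param eps quartic coefficient, kJ/mol/nm^4
#' @param mass particle mass, amu
#' @param temperature temperature, K
#' @param n_samples Boltzmann samples
#' @param seed integer seed
#' @return list with `S_exact`, `S_qh`, `S_fc` and absolute errors
#' @export
anharmonic_bias_experiment <- function(k2 = -2500, eps = 20000, mass = 110,
                                       temperature = 300, n_samples = 2e5,
                                       seed = 1L) {
  Vfun <- function(x) 0.5 * k2 * x^2 + eps * x^4
  L <- 1.5 * sqrt(max(abs(k2), 500) / (2 * eps)) + 4 * sqrt(.kB * temperature / 500)
  # exact quantum reference
  npts <- 3000
  xg <- seq(-L, L, length.out = npts)
  h <- xg[2] - xg[1]
  V <- Vfun(xg) - min(Vfun(xg))
  co <- .hbar^2 / (2 * mass * h^2)
  H <- diag(V + 2 * co)
  idx <- seq_len(npts - 1)
  H[cbind(idx, idx + 1)] <- -co
  H[cbind(idx + 1, idx)] <- -co
  E <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)[1:300]
  b <- 1 / (.kB * temperature)
  w <- exp(-b * (E - E[1]))
  S_exact <- .kB * log(sum(w)) + sum(w * (E - E[1])) / sum(w) / temperature
  # exact classical sampling
  fine <- seq(-L, L, length.out = 200001)
  p <- exp(-b * (Vfun(fine) - min(Vfun(fine))))
  cdf <- cumsum(p); cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  set.seed(as.integer(seed))
  xs <- stats::approx(cdf[keep], fine[keep], stats::runif(n_samples),
                      rule = 2)$y
  fs <- -(k2 * xs + 4 * eps * xs^3)
  S_qh <- entropy_from_samples(x = matrix(xs), masses = mass,
                               temperature = temperature)$S_kJ_mol_K
  S_fc <- entropy_from_samples(f = matrix(fs), masses = mass,
                               temperature = temperature)$S_kJ_mol_K
  list(S_exact = S_exact, S_qh = S_qh, S_fc = S_fc,
       abs_err_qh = abs(S_qh - S_exact), abs_err_fc = abs(S_fc - S_exact))
}

# analytic mean |F| per spring from the exact ENM covariance: the force on a
# spring is ~ k times the longitudinal extension, a zero-mean Gaussian, so
# E|F| = k sqrt(2 v / pi) with v the extension variance
.predicted_mean_force <- function(model, temperature) {
  H <- enm_hessian(model)
  e <- eigen(H, symmetric = TRUE)
  tol <- 1e-9 * max(e$values)
  keep <- e$values >= tol
  Vv <- e$vectors[, keep, drop = FALSE]
  Cv <- (Vv %*% (t(Vv) / e$values[keep])) * .kB * temperature
  sp <- model$springs
  vapply(seq_len(nrow(sp)), function(eg) {
    i <- sp$i[eg]; j <- sp$j[eg]
    d <- model$xyz[j, ] - model$xyz[i, ]
    u <- d / sqrt(sum(d^2))
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    v <- as.numeric(t(u) %*% (Cv[jj, jj] + Cv[ii, ii] - Cv[ii, jj] -
                                Cv[jj, ii]) %*% u)
    sp$k[eg] * sqrt(2 * v / pi)
  }, numeric(1))
}

#' Planted-pathway recovery experiment
#'
#' Builds a C2 dimer, plants a contact-following inter-protomer chain of
#' springs whose stiffness differs by `dk` between two states, samples both
#' states, runs the full force-difference network analysis and scores how
#' well the largest connected component recovers the planted chain. The
#' detection cutoff is set a priori to half the smallest pathway edge's
#' predicted force change (from the exact model covariances), i.e. midway
#' between background and signal.
#'
#' @param n_res_per_protomer dimer size
#' @param dk pathway stiffness delta, kJ/mol/nm^2
#' @param n_replicas,n_frames sampling effort per state
#' @param temperature temperature, K
#' @param seed integer seed (drives geometry jitter and sampling)
#' @param from,to pathway end residues (defaults: the innermost residue of
#'   each protomer, so the chain must cross the interface)
#' @return list with `recovery` and `contamination` fractions, `cutoff_pN`,
#'   `n_pathway_edges`, `signal_to_background`
#' @export
pathway_recovery_experiment <- function(n_res_per_protomer = 20, dk = 400,
                                        n_replicas = 3, n_frames = 1000,
                                        temperature = 300, seed = 1L,
                                        from = NULL, to = NULL) {
  n <- n_res_per_protomer
  base <- build_enm_dimer(n, seed = seed)
  if (is.null(from)) from <- 1              # innermost residue of A
  if (is.null(to)) to <- n + 1              # its C2 partner in B
  chain <- pathway_chain(base, from, to)
  base <- plant_pathway(base, data.frame(u = chain$u, v = chain$v, dk = dk))
  pert <- perturb_pathway(base)

  pred_base <- .predicted_mean_force(base, temperature)
  pred_pert <- .predicted_mean_force(pert, temperature)
  idx_path <- base$pathway_edges$spring
  d_pred <- abs(pred_pert - pred_base) * .PN_PER_KJ_MOL_NM
  cutoff <- 0.5 * min(d_pred[idx_path])
  background <- max(d_pred[-idx_path])
  s2b <- min(d_pred[idx_path]) / max(background, 1e-12)

  run_state <- function(model, sd_offset, state) {
    spec <- ensemble_spec(n_replicas, n_frames, temperature,
                          seed = replica_seed(seed, sd_offset))
    ens <- sample_ensemble(model, spec, state = state)
    average_table(residue_pair_forces(pairwise_forces_from_model(model, ens)))
  }
  tab_a <- run_state(base, 1, "base")
  tab_b <- run_state(pert, 2, "perturbed")
  d <- force_difference(tab_a, tab_b)
  nw <- threshold_network(d, cutoff, keep = "largest")

  lab <- unique(residue_labels(base$topology))
  path_keys <- paste(lab[pmin(chain$u, chain$v)], lab[pmax(chain$u, chain$v)])
  got_keys <- paste(nw$edges$label_u, nw$edges$label_v)
  recovery <- mean(path_keys %in% got_keys)
  contamination <- if (length(got_keys)) mean(!got_keys %in% path_keys) else 0
  list(recovery = recovery, contamination = contamination,
       cutoff_pN = cutoff, n_pathway_edges = length(path_keys),
       signal_to_background = s2b)
}

#' Protomer-stress convergence experiment
#'
#' Samples a symmetric apo dimer with several replicas and returns the
#' replica-subset convergence curve of the mean absolute protomer stress
#' difference, plus the per-protomer stress totals (which must agree within
#' sampling error for a C2 dimer).
#'
#' @param n_res_per_protomer dimer size
#' @param n_replicas,n_frames sampling effort
#' @param temperature temperature, K
#' @param seed integer seed
#' @return list with `curve` (data.frame), `stress_A`, `stress_B`,
#'   `asymmetry` (relative protomer stress difference)
#' @export
stress_convergence_experiment <- function(n_res_per_protomer = 12,
                                          n_replicas = 9, n_frames = 300,
                                          temperature = 300, seed = 1L) {
  m <- build_enm_dimer(n_res_per_protomer, seed = seed)
  ens <- sample_ensemble(m, ensemble_spec(n_replicas, n_frames, temperature,
                                          seed = seed))
  tab <- average_table(residue_pair_forces(pairwise_forces_from_model(m, ens)))
  st <- punctual_stress(tab)
  sA <- sum(st$stress_pN[st$chain == "A"])
  sB <- sum(st$stress_pN[st$chain == "B"])
  list(curve = convergence_curve(tab, seed = seed),
       stress_A = sA, stress_B = sB,
       asymmetry = abs(sA - sB) / ((sA + sB) / 2))
}
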