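# Entropy estimators: closed-form oracles, scaling laws, invariances,
# additivity, anharmonic behaviour and bootstrapped differences.

test_that("QH recovers the 1-D oscillator closed form within 1%", {
  k <- 500; m <- 110; temperature <- 300
  set.seed(31)
  x <- rnorm(1e5, sd = sqrt(kB_ * temperature / k))
  s <- entropy_from_samples(x = matrix(x), masses = m,
                            temperature = temperature)
  s_exact <- qho_entropy(sqrt(k / m), temperature)
  expect_lt(abs(s$S_kJ_mol_K - s_exact) / s_exact, 0.01)
})

test_that("FC recovers omega = sqrt(k/m) from forces within 1%", {
  k <- 500; m <- 110; temperature <- 300
  set.seed(37)
  x <- rnorm(1e5, sd = sqrt(kB_ * temperature / k))
  f <- -k * x
  s <- entropy_from_samples(f = matrix(f), masses = m,
                            temperature = temperature)
  expect_lt(abs(s$omega - sqrt(k / m)) / sqrt(k / m), 0.01)
})

test_that("doubling masses halves frequencies with the closed-form entropy gain", {
  k <- 500; m <- 110; temperature <- 300
  set.seed(41)
  x <- matrix(rnorm(5e4, sd = sqrt(kB_ * temperature / k)))
  s1 <- entropy_from_samples(x = x, masses = m, temperature = temperature)
  s2 <- entropy_from_samples(x = x, masses = 4 * m, temperature = temperature)
  expect_equal(s2$omega, s1$omega / 2, tolerance = 1e-12)
  gain_exact <- qho_entropy(sqrt(k / m) / 2, temperature) -
    qho_entropy(sqrt(k / m), temperature)
  expect_equal(s2$S_kJ_mol_K - s1$S_kJ_mol_K, gain_exact, tolerance = 0.01 * gain_exact)
})

test_that("QH and FC agree with the analytic model entropy on a harmonic
           ensemble and with each other within 2%", {
  m <- build_enm_dimer(12, seed = 43)
  temperature <- 300
  ens <- sample_ensemble(m, ensemble_spec(2, 5000, temperature, seed = 47))
  s_true <- analytic_entropy(m, temperature)$S_kJ_mol_K
  qh <- quasi_harmonic_entropy(ens, temperature = temperature)
  fc <- force_covariance_entropy(atomic_forces_from_model(m, ens),
                                 temperature = temperature)
  expect_lt(abs(qh$S_kJ_mol_K - s_true) / s_true, 0.02)
  expect_lt(abs(fc$S_kJ_mol_K - s_true) / s_true, 0.02)
  expect_lt(abs(fc$S_kJ_mol_K - qh$S_kJ_mol_K) / s_true, 0.02)
})

test_that("the FC spectrum is invariant under rigid rotation of all frames", {
  m <- build_enm_dimer(8, seed = 53)
  ens <- sample_ensemble(m, ensemble_spec(1, 800, seed = 59))
  af <- atomic_forces_from_model(m, ens)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rot_flat <- function(mat) {
    out <- mat
    for (a in seq_len(ncol(mat) / 3)) {
      cols <- (3 * a - 2):(3 * a)
      out[, cols] <- mat[, cols] %*% t(R)
    }
    out
  }
  af_rot <- af
  af_rot$replicas <- lapply(af$replicas, rot_flat)
  af_rot$reference <- af$reference %*% t(R)
  s1 <- force_covariance_entropy(af)
  s2 <- force_covariance_entropy(af_rot)
  expect_equal(s2$S_kJ_mol_K, s1$S_kJ_mol_K, tolerance = 1e-8)
})

test_that("entropy is additive over independent subsystems", {
  m <- build_enm_dimer(8, seed = 61)
  s1 <- analytic_entropy(m)
  # duplicate the model as two non-interacting copies: spectrum doubles
  m2 <- m
  n <- nrow(m$xyz)
  m2$xyz <- rbind(m$xyz, m$xyz + 50)  # far apart, no shared springs
  sp <- m$springs
  sp2 <- sp; sp2$i <- sp2$i + n; sp2$j <- sp2$j + n
  m2$springs <- rbind(sp, sp2)
  a2 <- m$topology$atoms
  a2b <- a2; a2b$serial <- a2b$serial + n; a2b$chain <- "C"
  suppressWarnings({
    m2$topology <- topology(rbind(a2, a2b))
    s2 <- analytic_entropy(m2)
  })
  # the doubled system has 12 rigid modes (two free bodies); analytic_entropy
  # drops them by tolerance and warns
  expect_equal(s2$S_kJ_mol_K, 2 * s1$S_kJ_mol_K, tolerance = 1e-8)
})

test_that("estimator error shrinks with sample size on harmonic ensembles", {
  m <- build_enm_dimer(6, seed = 67)
  s_true <- analytic_entropy(m)$S_kJ_mol_K
  errs <- vapply(c(200, 2000, 20000), function(n) {
    ens <- sample_ensemble(m, ensemble_spec(1, n, seed = 71))
    qh <- quasi_harmonic_entropy(ens, superpose = FALSE)
    abs(qh$S_kJ_mol_K - s_true)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("FC deviates less than QH on a two-state quartic-perturbed toy", {
  # double well V = -|k2|/2 x^2 + eps x^4 with a ~7.8 kBT barrier: the
  # coordinate covariance conflates inter-well spread with softness, the
  # force covariance reflects the local curvature
  k2 <- -2500; eps <- 20000; m <- 110; temperature <- 300
  Vfun <- function(x) 0.5 * k2 * x^2 + eps * x^4
  s_true <- schrodinger_entropy(function(x) Vfun(x) - min(Vfun(x)),
                                m, temperature, L = 0.8)
  xs <- boltzmann_sample_1d(Vfun, temperature, L = 0.8, n = 2e5, seed = 73)
  fs <- -(k2 * xs + 4 * eps * xs^3)
  s_qh <- entropy_from_samples(x = matrix(xs), masses = m,
                               temperature = temperature)$S_kJ_mol_K
  s_fc <- entropy_from_samples(f = matrix(fs), masses = m,
                               temperature = temperature)$S_kJ_mol_K
  expect_lt(abs(s_fc - s_true), abs(s_qh - s_true))
})

test_that("entropy differences: zero for identical states, positive penalty
           for added springs, analytic recovery within the bootstrap CI", {
  m <- build_enm_dimer(10, seed = 79,
                       pathway_spec = data.frame(u = c(4, 6), v = c(14, 16),
                                                 dk = 400))
  holo <- perturb_pathway(m)
  temperature <- 300
  ens_a <- sample_ensemble(m, ensemble_spec(3, 1500, seed = 83), state = "apo")
  ens_b <- sample_ensemble(holo, ensemble_spec(3, 1500, seed = 89),
                           state = "holo")
  qa <- quasi_harmonic_entropy(ens_a, temperature = temperature)
  qb <- quasi_harmonic_entropy(ens_b, temperature = temperature)
  expect_equal(entropy_difference(qa, qa, n_boot = 0)$minus_TdS_kcal, 0)
  d <- entropy_difference(qa, qb, temperature = temperature, n_boot = 100,
                          seed = 3)
  d_true <- entropy_difference(analytic_entropy(m, temperature),
                               analytic_entropy(holo, temperature),
                               n_boot = 0)$minus_TdS_kcal
  expect_gt(d_true, 0)
  half_width <- (d$ci95[2] - d$ci95[1]) / 2
  expect_lt(abs(d$minus_TdS_kcal - d_true), max(3 * half_width, 0.05 * abs(d_true)))
  # estimator/selection mismatches are rejected
  fa <- force_covariance_entropy(atomic_forces_from_model(m, ens_a),
                                 temperature = temperature)
  expect_error(entropy_difference(fa, qb), "estimator mismatch")
  qm <- quasi_harmonic_entropy(ens_a, selection = "calpha",
                               temperature = temperature)
  expect_error(entropy_difference(qm, qb), "selection mismatch")
})
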