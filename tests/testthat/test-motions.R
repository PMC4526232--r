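# Collective-motion machinery: PCA spectra, reconstruction, projections,
# motion matrices, RMSF/B-factor conversion and local RMSD semantics.

test_that("PCA of a single-axis displacement puts >99% variance on mode 1", {
  set.seed(151)
  n_at <- 6
  base <- matrix(rnorm(3 * n_at), n_at, 3)
  dirv <- rnorm(3 * n_at); dirv <- dirv / sqrt(sum(dirv^2))
  amp <- rnorm(200)
  frames <- t(vapply(amp, function(a) as.vector(t(base)) + a * dirv,
                     numeric(3 * n_at)))
  eig <- pca_ensemble(frames, superpose = FALSE)
  expect_gt(eig$values[1] / sum(eig$values), 0.99)
  expect_equal(abs(sum(eig$vectors[, 1] * dirv)), 1, tolerance = 1e-6)
})

test_that("eigenvectors are orthonormal and eigenvalues sorted", {
  m <- build_enm_dimer(7, seed = 157)
  ens <- sample_ensemble(m, ensemble_spec(1, 300, seed = 163))
  eig <- pca_ensemble(ens, selection = "full")
  G <- crossprod(eig$vectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_true(all(diff(eig$values) <= 1e-12))
})

test_that("PCA sampling recovers a known 2-D covariance within 3 SE", {
  set.seed(167)
  n <- 20000
  sds <- c(0.3, 0.1)
  x <- cbind(rnorm(n, sd = sds[1]), rnorm(n, sd = sds[2]), rnorm(n, sd = 0.02))
  eig <- pca_ensemble(x, superpose = FALSE)
  for (k in 1:2) {
    se <- sds[k]^2 * sqrt(2 / n)
    expect_lt(abs(eig$values[k] - sds[k]^2), 3 * se)
  }
})

test_that("projecting then reconstructing with all modes is lossless", {
  m <- build_enm_dimer(6, seed = 173)
  ens <- sample_ensemble(m, ensemble_spec(1, 500, seed = 179))
  eig <- pca_ensemble(ens, selection = "full")
  mat <- superpose_frames(do.call(rbind, ens$replicas))
  cent <- sweep(mat, 2, colMeans(mat))
  scores <- cent %*% eig$vectors
  recon <- scores %*% t(eig$vectors)
  expect_lt(max(abs(recon - cent)), 1e-8)
})

test_that("projection semantics: mean maps to 0, mean + c v1 maps to c", {
  m <- build_enm_dimer(6, seed = 181)
  ens <- sample_ensemble(m, ensemble_spec(1, 200, seed = 191))
  eig <- pca_ensemble(ens, selection = "full")
  p0 <- project_structures(matrix(eig$mean, 1), eig, 1, superpose = FALSE)
  expect_equal(p0, 0, tolerance = 1e-10)
  cc <- 0.37
  p1 <- project_structures(matrix(eig$mean + cc * eig$vectors[, 1], 1), eig, 1,
                           superpose = FALSE)
  expect_equal(p1, cc, tolerance = 1e-10)
})

test_that("a two-state ensemble separates bimodally along mode 1", {
  m <- build_enm_dimer(6, seed = 193)
  x0 <- as.vector(t(m$xyz))
  shift <- rep(0, length(x0))
  shift[seq(3, length(x0), 3)] <- 0.4  # state B displaced in z on some atoms
  shift[seq(3, length(x0), 3)][1:6] <- 0
  set.seed(197)
  frames <- rbind(
    matrix(rep(x0, 300), 300, byrow = TRUE) + rnorm(300 * length(x0), sd = 0.02),
    matrix(rep(x0 + shift, 300), 300, byrow = TRUE) + rnorm(300 * length(x0), sd = 0.02))
  eig <- pca_ensemble(frames, superpose = FALSE)
  pr <- project_frames(frames, eig, 1, superpose = FALSE)
  lab <- rep(c(1, 2), each = 300)
  gap <- abs(mean(pr[lab == 1]) - mean(pr[lab == 2]))
  spread <- max(sd(pr[lab == 1]), sd(pr[lab == 2]))
  expect_gt(gap, 5 * spread)
})

test_that("motion matrices: zero for identical or rigidly moved inputs,
           hand-computed stretch case, correlations at the poles", {
  a <- matrix(rnorm(24), 8, 3)
  expect_equal(max(abs(motion_matrix(a, a))), 0)
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- a %*% R + matrix(rep(c(3, -1, 2), each = 8), 8)
  expect_lt(max(abs(motion_matrix(moved, a))), 1e-10)

  # 3-residue stretch along x, hand-computed distance changes
  pa <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  pb <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0))
  M <- motion_matrix(pa, pb)
  expect_equal(M[1, 2], 1 - 1.5)
  expect_equal(M[1, 3], 2 - 3)
  expect_equal(M[2, 3], 1 - 1.5)
  expect_equal(M[2, 1], M[1, 2])
  expect_equal(diag(M), rep(0, 3))

  neg <- structure(-unclass(M), class = class(M))
  expect_equal(motion_correlation(M, M), 1)
  expect_equal(motion_correlation(M, neg), -1)
  # independent random matrices decorrelate
  set.seed(199)
  rs <- replicate(20, {
    m1 <- motion_matrix(matrix(rnorm(150), 50), matrix(rnorm(150), 50))
    m2 <- motion_matrix(matrix(rnorm(150), 50), matrix(rnorm(150), 50))
    motion_correlation(m1, m2)
  })
  expect_lt(median(abs(rs)), 0.1)
  z <- structure(matrix(0, 3, 3), class = c("motion_matrix", "matrix"))
  expect_warning(expect_true(is.na(motion_correlation(z, z))), "zero-variance")
})

test_that("RMSF/B-factor closed form and the covariance oracle", {
  # 1 Angstrom RMSF corresponds to B = 8 pi^2 / 3 = 26.32 A^2
  expect_equal(8 * pi^2 / 3, 26.3189, tolerance = 1e-4)
  m <- build_enm_dimer(8, seed = 211)
  ens <- sample_ensemble(m, ensemble_spec(2, 3000, seed = 223))
  rb <- rmsf_bfactor(ens, selection = "calpha", superpose = FALSE)
  expect_equal(rb$bfactor_A2, (8 * pi^2 / 3) * rb$rmsf_A^2, tolerance = 1e-10)
  # frozen ensemble: RMSF 0
  frozen <- ens
  frozen$replicas <- list(ens$replicas[[1]][rep(1, 5), ])
  expect_equal(max(rmsf_bfactor(frozen, superpose = FALSE)$rmsf_A), 0)
  # analytic per-node variance from the pseudo-inverse Hessian
  H <- enm_hessian(m)
  e <- eigen(H, symmetric = TRUE)
  keep <- e$values > 1e-9 * max(e$values)
  Cv <- (e$vectors[, keep] %*% (t(e$vectors[, keep]) / e$values[keep])) *
    kB_ * 300
  msf_true <- vapply(seq_len(nrow(m$xyz)), function(a) {
    sum(diag(Cv[(3 * a - 2):(3 * a), (3 * a - 2):(3 * a)]))
  }, numeric(1))
  rmsf_true <- 10 * sqrt(msf_true)
  n_eff <- 6000
  se <- rmsf_true * sqrt(1 / (2 * n_eff)) * 3
  expect_true(all(abs(rb$rmsf_A - rmsf_true) < pmax(se, 0.05 * rmsf_true)))
  expect_error(rmsf_bfactor(ens, bfactors = 1:3), "length")
})

test_that("local RMSD: zero for the reference, rigid co-motion invisible,
           planted flip bimodal", {
  m <- build_enm_dimer(8, seed = 227)
  x0 <- as.vector(t(m$xyz))
  still <- structure(list(state = "ref", topology = m$topology,
                          replicas = list(matrix(rep(x0, 4), 4, byrow = TRUE)),
                          dt_ps = 1, temperature = 300, sampler = "none",
                          seeds = 0), class = "traj_ensemble")
  lr <- local_rmsd(still, "A:4", m$xyz)
  expect_lt(max(lr), 1e-8)

  # rigid global rotation of every frame: local RMSD stays ~0
  th <- 0.5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rotfr <- t(vapply(1:4, function(i) as.vector(t(m$xyz %*% R)), numeric(length(x0))))
  rot <- still; rot$replicas <- list(rotfr)
  expect_lt(max(local_rmsd(rot, "A:4", m$xyz)), 1e-8)

  # flip: displace the target atom in half the frames
  lab <- residue_labels(m$topology)
  tgt_atom <- which(lab == "A:4")[1]
  fr <- matrix(rep(x0, 40), 40, byrow = TRUE)
  fr[21:40, 3 * tgt_atom - 2] <- fr[21:40, 3 * tgt_atom - 2] + 0.3
  flip <- still; flip$replicas <- list(fr)
  lrf <- local_rmsd(flip, "A:4", m$xyz)
  expect_lt(max(lrf[1:20]), 0.5)
  expect_gt(min(lrf[21:40]), 1.0)  # ~3 A displacement, diluted by residue size
  expect_error(local_rmsd(still, "A:4", m$xyz, fit_cutoff_nm = 0.01),
               "no neighbour")
})
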