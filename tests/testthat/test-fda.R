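# Force distribution analysis: residue-pair semantics, averaging
# conventions, differences, networks, stress and convergence.

test_that("vector-sum-then-norm semantics: opposing atom forces cancel", {
  top <- four_atom_topology()
  pairs <- data.frame(i = c(1L, 2L), j = c(3L, 4L))
  f <- rbind(c(0, 0, 2), c(0, 0, -2))  # two records, opposite z forces
  pfs <- manual_pair_force_set(pairs, list(f), top)
  rp <- residue_pair_forces(pfs)
  expect_equal(nrow(rp$pairs), 1)
  expect_equal(as.numeric(rp$replicas[[1]]), 0)

  # a single record of magnitude |f| gives exactly |f|
  pfs1 <- manual_pair_force_set(data.frame(i = 1L, j = 3L),
                                list(matrix(c(0, 0, 1.5), 1)), top)
  rp1 <- residue_pair_forces(pfs1)
  expect_equal(as.numeric(rp1$replicas[[1]]), 1.5)
})

test_that("residue-pair forces match the brute-force triple loop", {
  m <- build_enm_dimer(5, seed = 9, nodes_per_residue = 4)  # 10 res, 40 atoms
  ens <- sample_ensemble(m, ensemble_spec(1, 7, seed = 2))
  pfs <- pairwise_forces_from_model(m, ens)
  rp <- residue_pair_forces(pfs)
  oracle <- brute_residue_pair_forces(pfs, m$topology)
  key <- paste(rp$pairs$label_u, rp$pairs$label_v)
  expect_setequal(key, names(oracle))
  for (k in names(oracle)) {
    expect_equal(rp$replicas[[1]][, match(k, key)], oracle[[k]],
                 tolerance = 1e-12)
  }
})

test_that("Newton's third law holds for every stored record", {
  m <- build_enm_dimer(6, seed = 3)
  ens <- sample_ensemble(m, ensemble_spec(1, 5, seed = 4))
  pfs <- pairwise_forces_from_model(m, ens)
  # stored once with i < j; the reverse force is the negation by construction,
  # so the total internal force must vanish frame by frame
  af <- atomic_forces(pfs)
  tot <- sapply(1:3, function(a) {
    rowSums(af$replicas[[1]][, seq(a, ncol(af$replicas[[1]]), 3)])
  })
  expect_lt(max(abs(tot)), 1e-9)
})

test_that("forces vanish at the equilibrium geometry", {
  m <- build_enm_dimer(6, seed = 3)
  ens <- structure(list(state = "eq", topology = m$topology,
                        replicas = list(matrix(rep(as.vector(t(m$xyz)), 2), 2,
                                               byrow = TRUE)),
                        dt_ps = 1, temperature = 300, sampler = "none",
                        seeds = 0), class = "traj_ensemble")
  pfs <- pairwise_forces_from_model(m, ens)
  expect_lt(max(abs(pfs$replicas[[1]])), 1e-12)
})

test_that("time-mean |F| of a thermal pair follows the half-normal law", {
  k <- 400; temperature <- 300
  m <- two_node_model(k = k)
  ens <- sample_ensemble(m, ensemble_spec(1, 1e5, temperature, seed = 21))
  pfs <- pairwise_forces_from_model(m, ens)
  fmag <- sqrt(rowSums(pfs$replicas[[1]][, 1, ]^2))
  mean_expect <- sqrt(2 * k * kB_ * temperature / pi)
  se <- sd(fmag) / sqrt(length(fmag))
  expect_lt(abs(mean(fmag) - mean_expect), 3 * se)
  # and the residue-pair time average is strictly positive at equilibrium
  tab <- average_table(residue_pair_forces(pfs))
  expect_gt(tab$mean_pN, 0)
})

test_that("replica averaging is unweighted", {
  top <- four_atom_topology()
  pairs <- data.frame(i = 1L, j = 3L)
  mk <- function(vals) {
    arr <- array(0, dim = c(length(vals), 1, 3))
    arr[, 1, 3] <- vals
    arr
  }
  pfs <- structure(list(pairs = pairs, topology = top,
                        replicas = list(mk(rep(1, 4)), mk(rep(3, 10))),
                        state = "x", dt_ps = 1), class = "pair_force_set")
  tab <- average_table(residue_pair_forces(pfs))
  expect_equal(tab$mean_pN, 2 * PN_, tolerance = 1e-12)
})

test_that("force differences subtract, default to zero, and antisymmetrise", {
  m <- build_enm_dimer(6, seed = 13)
  ens <- sample_ensemble(m, ensemble_spec(2, 20, seed = 5))
  tab <- average_table(residue_pair_forces(pairwise_forces_from_model(m, ens)))
  d0 <- force_difference(tab, tab)
  expect_true(all(d0$delta_pN == 0))
  # drop one pair from A; its delta must equal +mean in B
  tab_a <- tab[-1, ]
  attributes(tab_a) <- attributes(tab)[setdiff(names(attributes(tab)), c("row.names", "names"))]
  attr(tab_a, "row.names") <- seq_len(nrow(tab) - 1)
  names(tab_a) <- names(tab)
  class(tab_a) <- class(tab)
  dd <- force_difference(tab_a, tab)
  key <- paste(dd$label_u, dd$label_v)
  k1 <- paste(tab$label_u[1], tab$label_v[1])
  expect_equal(dd$delta_pN[match(k1, key)], tab$mean_pN[1])
  d_ab <- force_difference(tab_a, tab)
  d_ba <- force_difference(tab, tab_a)
  expect_equal(d_ab$delta_pN, -d_ba$delta_pN[match(paste(d_ab$label_u, d_ab$label_v),
                                                   paste(d_ba$label_u, d_ba$label_v))])
})

test_that("thresholded networks match a planted chain and brute-force components", {
  # hand-built delta table: a 3-edge chain at 60 pN over background < 40 pN
  res <- c("A:1", "A:2", "A:3", "A:4", "B:1", "B:2")
  d <- data.frame(label_u = c("A:1", "A:2", "A:3", "A:4", "B:1"),
                  label_v = c("A:2", "A:3", "A:4", "B:1", "B:2"),
                  delta_pN = c(60, -60, 60, 30, 20))
  attr(d, "residues") <- res
  class(d) <- c("force_delta", "data.frame")
  nw <- threshold_network(d, 50)
  expect_equal(nrow(nw$edges), 3)
  expect_setequal(nw$components[[1]], c("A:1", "A:2", "A:3", "A:4"))
  # empty beyond the maximum
  expect_equal(nrow(threshold_network(d, 100)$edges), 0)
  # all components vs union-find oracle
  nw_all <- threshold_network(d, 25, keep = "all")
  oracle <- brute_components(d$label_u[abs(d$delta_pN) >= 25],
                             d$label_v[abs(d$delta_pN) >= 25])
  got <- lapply(nw_all$components, sort)
  want <- lapply(oracle, function(x) sort(unname(x)))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
})

test_that("edge sets are nested across cutoffs (50 pN within 40 pN)", {
  m <- build_enm_dimer(8, seed = 17)
  e1 <- sample_ensemble(m, ensemble_spec(2, 40, seed = 6), state = "a")
  e2 <- sample_ensemble(m, ensemble_spec(2, 40, seed = 7), state = "b")
  t1 <- average_table(residue_pair_forces(pairwise_forces_from_model(m, e1)))
  t2 <- average_table(residue_pair_forces(pairwise_forces_from_model(m, e2)))
  d <- force_difference(t1, t2)
  # rescale so both presets are populated, keeping the spirit of 40/50 pN
  d$delta_pN <- d$delta_pN * (55 / max(abs(d$delta_pN)))
  n50 <- threshold_network(d, 50, keep = "all")
  n40 <- threshold_network(d, 40, keep = "all")
  key50 <- paste(n50$edges$label_u, n50$edges$label_v)
  key40 <- paste(n40$edges$label_u, n40$edges$label_v)
  expect_true(all(key50 %in% key40))
})

test_that("punctual stress is the row sum of the pair table", {
  top <- four_atom_topology()
  pairs <- data.frame(i = c(1L, 2L), j = c(3L, 4L))
  f <- rbind(c(0, 0, 3), c(4, 0, 0))
  pfs <- manual_pair_force_set(pairs, list(f), top)
  tab <- average_table(residue_pair_forces(pfs))
  st <- punctual_stress(tab)
  # single pair: both residues carry the same stress
  expect_equal(st$stress_pN[st$label == "A:1"], st$stress_pN[st$label == "A:2"])
  # double-counting identity over a larger random table
  m <- build_enm_dimer(7, seed = 19)
  ens <- sample_ensemble(m, ensemble_spec(1, 15, seed = 8))
  tb <- average_table(residue_pair_forces(pairwise_forces_from_model(m, ens)))
  sp <- punctual_stress(tb)
  expect_equal(sum(sp$stress_pN), 2 * sum(tb$mean_pN), tolerance = 1e-12)
})

test_that("star-topology centre accumulates the arm means", {
  atoms <- data.frame(serial = 1:4, name = "CA", resno = 1:4, resname = "ALA",
                      chain = "A", mass = 12, het = FALSE)
  top <- topology(atoms)
  pairs <- data.frame(i = c(1L, 1L, 1L), j = c(2L, 3L, 4L))
  f <- rbind(c(0, 0, 1), c(0, 2, 0), c(3, 0, 0))
  pfs <- manual_pair_force_set(pairs, list(f), top)
  st <- punctual_stress(average_table(residue_pair_forces(pfs)))
  expect_equal(st$stress_pN[st$label == "A:1"], (1 + 2 + 3) * PN_,
               tolerance = 1e-12)
})

test_that("convergence curve: identical replicas give a flat zero; k = 1 is
           the mean per-replica protomer difference", {
  m <- build_enm_dimer(6, seed = 23)
  ens <- sample_ensemble(m, ensemble_spec(4, 25, seed = 9))
  tab <- average_table(residue_pair_forces(pairwise_forces_from_model(m, ens)))
  # clone one replica into all slots -> all subsets identical -> zero spread
  rm <- attr(tab, "replica_means")
  rm_flat <- rm
  for (r in seq_len(ncol(rm_flat))) rm_flat[, r] <- rm[, 1]
  tab_flat <- tab
  attr(tab_flat, "replica_means") <- rm_flat
  tab_flat$mean_pN <- rowMeans(rm_flat)
  cc_flat <- convergence_curve(tab_flat)
  expect_equal(diff(cc_flat$mean_abs_diff_pN), rep(0, 3), tolerance = 1e-12)

  cc <- convergence_curve(tab)
  # k = 1 definition check against a direct computation
  res <- attr(tab, "residues")
  stress_of <- function(v) {
    s <- setNames(numeric(length(res)), res)
    for (r in seq_len(nrow(tab))) {
      s[tab$label_u[r]] <- s[tab$label_u[r]] + v[r]
      s[tab$label_v[r]] <- s[tab$label_v[r]] + v[r]
    }
    s
  }
  per_rep <- vapply(seq_len(ncol(rm)), function(r) {
    s <- stress_of(rm[, r])
    mean(abs(s[startsWith(names(s), "A:")] - s[paste0("B:", sub("A:", "", names(s)[startsWith(names(s), "A:")]))]))
  }, numeric(1))
  expect_equal(cc$mean_abs_diff_pN[1], mean(per_rep), tolerance = 1e-12)
  expect_error(convergence_curve(tab, k_max = 10), "exceeds replica count")
})

test_that("residue relabelling permutes tables consistently (equivariance)", {
  m <- build_enm_dimer(5, seed = 29)
  ens <- sample_ensemble(m, ensemble_spec(1, 10, seed = 10))
  pfs <- pairwise_forces_from_model(m, ens)
  tab <- average_table(residue_pair_forces(pfs))
  # relabel: swap chains A and B in the topology (a pure renaming)
  top2 <- m$topology
  top2$atoms$chain <- ifelse(top2$atoms$chain == "A", "B", "A")
  pfs2 <- pfs
  pfs2$topology <- top2
  tab2 <- average_table(residue_pair_forces(pfs2))
  relab <- function(x) ifelse(startsWith(x, "A:"), sub("^A", "B", x),
                              sub("^B", "A", x))
  key1 <- paste(pmin(relab(tab$label_u), relab(tab$label_v)),
                pmax(relab(tab$label_u), relab(tab$label_v)))
  key2 <- paste(pmin(tab2$label_u, tab2$label_v),
                pmax(tab2$label_u, tab2$label_v))
  expect_setequal(key1, key2)
  expect_equal(tab2$mean_pN[match(key1, key2)], tab$mean_pN, tolerance = 1e-12)
})
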