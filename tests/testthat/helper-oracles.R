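# Independent oracles and small fixture builders used across the suite.

kB_ <- 0.008314462618
hbar_ <- 0.0635077993
PN_ <- 1.66053906892

# ---- brute-force FDA oracle (triple loops + union-find), independent of the
# package's grouped/vectorised implementation ----

# residue-pair force scalars by explicit triple loop over frames, pairs, atoms
brute_residue_pair_forces <- function(pfs, topology) {
  ri <- residue_index(topology)
  serial <- topology$atoms$serial
  arr <- pfs$replicas[[1]]
  nf <- dim(arr)[1]
  lab <- unique(residue_labels(topology))
  nres <- length(lab)
  out <- list()
  for (u in 1:(nres - 1)) {
    for (v in (u + 1):nres) {
      fs <- matrix(0, nf, 3)
      any_rec <- FALSE
      for (e in seq_len(nrow(pfs$pairs))) {
        iu <- ri[match(pfs$pairs$i[e], serial)]
        iv <- ri[match(pfs$pairs$j[e], serial)]
        if (iu == u && iv == v) {
          fs <- fs + arr[, e, ]; any_rec <- TRUE
        } else if (iu == v && iv == u) {
          fs <- fs - arr[, e, ]; any_rec <- TRUE
        }
      }
      if (any_rec) {
        out[[paste(lab[u], lab[v])]] <- sqrt(rowSums(fs^2))
      }
    }
  }
  out
}

# union-find connected components over an edge list of labels
brute_components <- function(edges_u, edges_v) {
  verts <- unique(c(edges_u, edges_v))
  parent <- stats::setNames(verts, verts)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edges_u)) {
    ru <- find(edges_u[k]); rv <- find(edges_v[k])
    if (ru != rv) parent[[ru]] <- rv
  }
  roots <- vapply(verts, find, character(1))
  split(verts, roots)
}

# ---- 1-D quantum oracle: finite-difference Schrodinger eigenvalues ----

# exact quantum entropy (kJ/mol/K) of a 1-D particle in potential V(x)
schrodinger_entropy <- function(Vfun, mass, temperature, L, npts = 3000,
                                nlevels = 300) {
  x <- seq(-L, L, length.out = npts)
  h <- x[2] - x[1]
  V <- Vfun(x)
  co <- hbar_^2 / (2 * mass * h^2)
  H <- diag(V + 2 * co)
  idx <- seq_len(npts - 1)
  H[cbind(idx, idx + 1)] <- -co
  H[cbind(idx + 1, idx)] <- -co
  E <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)[1:nlevels]
  b <- 1 / (kB_ * temperature)
  w <- exp(-b * (E - E[1]))
  Z <- sum(w)
  kB_ * log(Z) + sum(w * (E - E[1])) / Z / temperature
}

# sample the classical Boltzmann distribution of a 1-D potential (inverse CDF)
boltzmann_sample_1d <- function(Vfun, temperature, L, n, seed = 1,
                                npts = 200001) {
  x <- seq(-L, L, length.out = npts)
  p <- exp(-Vfun(x) / (kB_ * temperature))
  cdf <- cumsum(p); cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  set.seed(seed)
  stats::approx(cdf[keep], x[keep], stats::runif(n), rule = 2)$y
}

# ---- small model fixtures ----

# two nodes joined by one spring along x (1 stretch mode, 5 rigid modes)
two_node_model <- function(k = 400, r0 = 0.5, mass = 110) {
  atoms <- data.frame(serial = 1:2, name = "CA", resno = 1:2, resname = "ALA",
                      chain = c("A", "B"), mass = mass, het = FALSE)
  structure(
    list(topology = topology(atoms), xyz = rbind(c(0, 0, 0), c(r0, 0, 0)),
         springs = data.frame(i = 1L, j = 2L, k = k, r0 = r0),
         pathway_edges = NULL, ligand_serials = integer(),
         n_res_per_protomer = 1L, contact_cutoff = 1, k_default = k,
         seed = 1L),
    class = "toy_model")
}

# tiny hand-built pair-force set: 2 residues x 2 atoms, forces chosen per test
manual_pair_force_set <- function(pairs, force_list, topology, dt_ps = 1) {
  nf <- length(force_list)
  arr <- array(0, dim = c(nf, nrow(pairs), 3))
  for (f in seq_len(nf)) arr[f, , ] <- force_list[[f]]
  structure(list(pairs = pairs, topology = topology, replicas = list(arr),
                 state = "manual", dt_ps = dt_ps),
            class = "pair_force_set")
}

four_atom_topology <- function() {
  atoms <- data.frame(serial = 1:4, name = c("CA", "CB", "CA", "CB"),
                      resno = c(1, 1, 2, 2), resname = "ALA",
                      chain = "A", mass = 12, het = FALSE)
  topology(atoms)
}

# independent S^2 from the cone formula
cone_s2 <- function(theta0) (cos(theta0) * (1 + cos(theta0)) / 2)^2
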