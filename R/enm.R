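# Synthetic elastic-network dimer models with analytic ground truth.

# roughly uniform points filling a ball of radius R (golden-angle spiral)
.fibonacci_ball <- function(n, R) {
  i <- seq_len(n)
  g <- pi * (3 - sqrt(5))
  r <- R * ((i - 0.5) / n)^(1 / 3)
  z <- 1 - 2 * (i - 0.5) / n
  s <- sqrt(pmax(0, 1 - z^2))
  th <- g * (i - 1)
  cbind(r * s * cos(th), r * s * sin(th), r * z)
}

# local frame vectors for the 4-point residue representation
.residue_frame <- function(ca, center) {
  out <- ca - center
  n1 <- sqrt(sum(out^2))
  out <- if (n1 > 1e-8) out / n1 else c(0, 0, 1)
  ref <- if (abs(out[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * out) * out
  t1 <- t1 / sqrt(sum(t1^2))
  list(out = out, t1 = t1)
}

#' Build a C2-symmetric elastic-network dimer
#'
#' Generates two compact globular protomers (pseudo-atoms roughly uniform in a
#' ball) related by a two-fold rotation about the z axis, and connects all
#' node pairs within `contact_cutoff` by harmonic springs whose equilibrium
#' length is the build-time distance. The resulting model is an exact
#' stationary point of its own potential, so its mass-weighted Hessian defines
#' the analytic mode spectrum and entropy of the system.
#'
#' An optional `pathway_spec` designates residue-pair springs whose stiffness
#' differs between two states by `dk`; these are recorded as ground truth in
#' `pathway_edges` and applied by [perturb_pathway()].
#'
#' @param n_res_per_protomer residues per protomer (>= 4)
#' @param contact_cutoff spring cutoff distance, nm
#' @param k_default spring stiffness, kJ mol^-1 nm^-2
#' @param pathway_spec NULL or data.frame with columns `u`, `v` (global residue
#'   indices, 1..n for protomer A, n+1..2n for protomer B) and `dk`
#'   (stiffness delta, kJ mol^-1 nm^-2)
#' @param seed integer seed for the (C2-preserving) coordinate jitter
#' @param nodes_per_residue 1 (single node) or 4 (N, CA, C, side-chain centroid)
#' @param mass node mass in amu (single-node models); 4-point models use
#'   N 15, CA 13, C 28, side chain `mass - 56`
#' @param jitter_sd coordinate jitter (nm) applied to protomer A and mirrored
#' @param gap surface gap between the protomers, nm
#' @return an object of class `toy_model`
#' @export
build_enm_dimer <- function(n_res_per_protomer, contact_cutoff = 1.2,
                            k_default = 500, pathway_spec = NULL, seed = 1L,
                            nodes_per_residue = 1L, mass = 110,
                            jitter_sd = 0.02, gap = 0.1) {
  n <- as.integer(n_res_per_protomer)
  if (n < 4) stop("n_res_per_protomer must be >= 4")
  if (k_default <= 0) stop("k_default must be positive")
  nodes_per_residue <- as.integer(nodes_per_residue)
  if (!nodes_per_residue %in% c(1L, 4L)) stop("nodes_per_residue must be 1 or 4")

  R <- 0.276 * n^(1 / 3)
  ca <- .fibonacci_ball(n, R)
  set.seed(as.integer(seed))
  ca <- ca + matrix(stats::rnorm(3 * n, sd = jitter_sd), n, 3)
  ca[, 1] <- ca[, 1] + (R + gap / 2)   # shift protomer A to +x

  center <- colMeans(ca)
  if (nodes_per_residue == 1L) {
    xyzA <- ca
    names_res <- "CA"
    masses_res <- mass
  } else {
    pts <- vector("list", n)
    for (i in seq_len(n)) {
      fr <- .residue_frame(ca[i, ], center)
      pts[[i]] <- rbind(
        ca[i, ] + 0.12 * fr$t1,         # N
        ca[i, ],                        # CA
        ca[i, ] - 0.12 * fr$t1,         # C
        ca[i, ] + 0.25 * fr$out         # side-chain centroid, pointing outward
      )
    }
    xyzA <- do.call(rbind, pts)
    names_res <- c("N", "CA", "C", "SC")
    masses_res <- c(15, 13, 28, max(mass - 56, 10))
  }

  # C2 image: rotate by pi about z
  xyzB <- cbind(-xyzA[, 1], -xyzA[, 2], xyzA[, 3])
  xyz <- rbind(xyzA, xyzB)
  npp <- nodes_per_residue
  natom_pp <- n * npp

  atoms <- data.frame(
    serial = seq_len(2 * natom_pp),
    name = rep(rep(names_res, n), 2),
    resno = rep(rep(seq_len(n), each = npp), 2),
    resname = "ALA",
    chain = rep(c("A", "B"), each = natom_pp),
    mass = rep(rep(masses_res, n), 2),
    het = FALSE,
    stringsAsFactors = FALSE
  )

  axes <- NULL
  dihedrals <- NULL
  if (npp == 4L) {
    # axis vector CA -> SC per residue (pseudo methyl axis)
    base <- (seq_len(2 * n) - 1) * 4L
    axes <- data.frame(
      label = paste0(rep(c("A", "B"), each = n), ":", rep(seq_len(n), 2)),
      from = base + 2L, to = base + 4L
    )
    # backbone phi (C- , N, CA, C) and psi (N, CA, C, N+) within each chain
    dih <- list()
    for (p in 0:1) {
      off <- p * natom_pp
      ch <- c("A", "B")[p + 1]
      for (i in seq_len(n)) {
        b <- off + (i - 1) * 4L
        if (i > 1) {
          dih[[length(dih) + 1]] <- data.frame(
            label = paste0(ch, ":", i, ":phi"), residue = paste0(ch, ":", i),
            a1 = b - 4L + 3L, a2 = b + 1L, a3 = b + 2L, a4 = b + 3L)
        }
        if (i < n) {
          dih[[length(dih) + 1]] <- data.frame(
            label = paste0(ch, ":", i, ":psi"), residue = paste0(ch, ":", i),
            a1 = b + 1L, a2 = b + 2L, a3 = b + 3L, a4 = b + 4L + 1L)
        }
      }
    }
    dihedrals <- do.call(rbind, dih)
  }

  top <- topology(atoms, nodes_per_residue = npp, axes = axes,
                  dihedrals = dihedrals)

  D <- as.matrix(stats::dist(xyz))
  hit <- which(D < contact_cutoff & upper.tri(D), arr.ind = TRUE)
  if (nrow(hit) == 0) {
    stop("spring network is disconnected; isolated nodes (serials): ",
         paste(seq_len(nrow(xyz)), collapse = ", "))
  }
  springs <- data.frame(i = hit[, 1], j = hit[, 2], k = k_default,
                        r0 = D[hit])

  model <- structure(
    list(topology = top, xyz = xyz, springs = springs,
         pathway_edges = NULL, ligand_serials = integer(),
         n_res_per_protomer = n, contact_cutoff = contact_cutoff,
         k_default = k_default, seed = as.integer(seed)),
    class = "toy_model"
  )
  .check_connected(model)

  if (!is.null(pathway_spec)) model <- plant_pathway(model, pathway_spec)
  model
}

.check_connected <- function(model) {
  g <- igraph::graph_from_edgelist(as.matrix(model$springs[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(model$xyz) - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    big <- which.max(comp$csize)
    isolated <- which(comp$membership != big)
    stop("spring network is disconnected; isolated nodes (serials): ",
         paste(isolated, collapse = ", "))
  }
  invisible(TRUE)
}

# global residue index (1..2n, ligands after) -> CA (or single-node) serial
.residue_node_serial <- function(model, res, node = "CA") {
  a <- model$topology$atoms
  lab <- residue_labels(model$topology)
  ulab <- unique(lab)
  if (any(res < 1 | res > length(ulab))) {
    stop("unknown residue index: ", paste(res[res < 1 | res > length(ulab)],
                                          collapse = ", "))
  }
  vapply(res, function(r) {
    rows <- which(lab == ulab[r])
    hit <- rows[a$name[rows] == node]
    a$serial[if (length(hit)) hit[1] else rows[1]]
  }, integer(1))
}

#' Record a planted allosteric pathway on a model
#'
#' Marks residue-pair springs as the designed pathway whose stiffness differs
#' between states. Springs absent from the contact network are added (at
#' `k_default`, equilibrium length = build distance) so that both states share
#' the same spring topology and differ only in stiffness once
#' [perturb_pathway()] is applied.
#'
#' @param model a `toy_model`
#' @param pathway_spec data.frame with columns `u`, `v` (global residue
#'   indices) and `dk` (kJ mol^-1 nm^-2)
#' @return the model with `pathway_edges` recorded
#' @export
plant_pathway <- function(model, pathway_spec) {
  stopifnot(is.data.frame(pathway_spec),
            all(c("u", "v", "dk") %in% names(pathway_spec)))
  si <- .residue_node_serial(model, pathway_spec$u)
  sj <- .residue_node_serial(model, pathway_spec$v)
  lo <- pmin(si, sj); hi <- pmax(si, sj)
  key <- paste(model$springs$i, model$springs$j)
  at <- match(paste(lo, hi), key)
  for (e in which(is.na(at))) {
    r0 <- sqrt(sum((model$xyz[hi[e], ] - model$xyz[lo[e], ])^2))
    model$springs <- rbind(model$springs,
                           data.frame(i = lo[e], j = hi[e],
                                      k = model$k_default, r0 = r0))
    at[e] <- nrow(model$springs)
  }
  model$pathway_edges <- data.frame(u = pathway_spec$u, v = pathway_spec$v,
                                    dk = pathway_spec$dk,
                                    i = lo, j = hi, spring = at)
  model
}

#' Find a residue chain linking two residues through the contact network
#'
#' Shortest path in the residue-level spring graph, useful for designing an
#' inter-protomer pathway that follows existing contacts.
#'
#' @param model a `toy_model`
#' @param from,to global residue indices
#' @return data.frame with columns `u`, `v`, one row per consecutive edge
#' @export
pathway_chain <- function(model, from, to) {
  ri <- residue_index(model$topology)
  eu <- ri[model$springs$i]; ev <- ri[model$springs$j]
  keep <- eu != ev
  g <- igraph::graph_from_edgelist(cbind(eu[keep], ev[keep]), directed = FALSE)
  g <- igraph::simplify(g)
  p <- igraph::shortest_paths(g, from, to)$vpath[[1]]
  p <- as.integer(p)
  if (length(p) < 2) stop("no path between residues ", from, " and ", to)
  data.frame(u = p[-length(p)], v = p[-1])
}

#' Apply the planted pathway stiffness deltas
#'
#' Returns the perturbed state of the model: every pathway edge's stiffness is
#' shifted by `scale * dk`. The input model is unchanged.
#'
#' @param model a `toy_model` with `pathway_edges`
#' @param scale multiplier on the recorded deltas
#' @return a new `toy_model`
#' @export
perturb_pathway <- function(model, scale = 1) {
  if (is.null(model$pathway_edges)) stop("model has no pathway_edges")
  k <- model$springs$k
  k[model$pathway_edges$spring] <- k[model$pathway_edges$spring] +
    scale * model$pathway_edges$dk
  if (any(k <= 0)) stop("pathway perturbation drives a stiffness non-positive")
  model$springs$k <- k
  model
}

#' Attach a ligand node to a binding pocket
#'
#' Adds one pseudo-atom (the ligand) connected by one spring to each pocket
#' residue. For 4-point residues the spring attaches to the side-chain
#' centroid node; for single-node residues to the node itself. The ligand is
#' placed at the pocket centroid, nudged outward along the local surface
#' normal, and its springs are at equilibrium at build geometry (so the model
#' stays a stationary point). The input model is not modified.
#'
#' @param model a `toy_model`
#' @param pocket_residues global residue indices forming the pocket
#' @param k_ligand ligand spring stiffness, kJ mol^-1 nm^-2 (> 0)
#' @param mass ligand mass, amu (default roughly cAMP)
#' @param attach "tip" (default): one spring per pocket residue, to the
#'   side-chain node (or the single node); "both": springs to both the CA and
#'   side-chain nodes of each pocket residue (4-point models only), emulating
#'   a ligand that contacts side chain and backbone and therefore stiffens
#'   the side-chain axis
#' @return a new `toy_model` with one extra node and one (`attach = "tip"`)
#'   or two (`attach = "both"`) extra springs per pocket residue
#' @export
add_ligand <- function(model, pocket_residues, k_ligand = 500, mass = 329,
                       attach = c("tip", "both")) {
  attach <- match.arg(attach)
  if (length(pocket_residues) == 0) stop("pocket_residues must be non-empty")
  if (k_ligand <= 0) stop("k_ligand must be positive")
  four_pt <- model$topology$nodes_per_residue == 4L
  if (attach == "both" && !four_pt) {
    stop("attach = \"both\" needs a 4-point model")
  }
  node <- if (four_pt) "SC" else "CA"
  ser <- .residue_node_serial(model, pocket_residues, node = node)
  if (attach == "both") {
    ser <- c(ser, .residue_node_serial(model, pocket_residues, node = "CA"))
  }
  a <- model$topology$atoms
  pc <- colMeans(model$xyz[ser, , drop = FALSE])
  allc <- colMeans(model$xyz)
  outv <- pc - allc
  nn <- sqrt(sum(outv^2))
  if (nn > 1e-8) pc <- pc + 0.15 * outv / nn
  new_serial <- max(a$serial) + 1L
  chain <- names(sort(table(a$chain[match(ser, a$serial)]), decreasing = TRUE))[1]
  new_atom <- data.frame(serial = new_serial, name = "LIG",
                         resno = max(a$resno[a$chain == chain]) + 1L,
                         resname = "CMP", chain = chain, mass = mass,
                         het = TRUE, stringsAsFactors = FALSE)
  top <- model$topology
  top$atoms <- rbind(top$atoms, new_atom)
  model$topology <- topology(top$atoms, top$nodes_per_residue, top$axes,
                             top$dihedrals)
  model$xyz <- rbind(model$xyz, pc)
  r0 <- sqrt(rowSums((model$xyz[ser, , drop = FALSE] -
                        matrix(pc, length(ser), 3, byrow = TRUE))^2))
  model$springs <- rbind(model$springs,
                         data.frame(i = ser, j = new_serial, k = k_ligand,
                                    r0 = r0))
  model$ligand_serials <- c(model$ligand_serials, new_serial)
  model
}

#' @export
print.toy_model <- function(x, ...) {
  cat("toy_model: C2 elastic-network dimer\n")
  cat("  ", x$n_res_per_protomer, "residues/protomer,",
      x$topology$nodes_per_residue, "node(s)/residue,",
      nrow(x$xyz), "atoms\n")
  cat("  ", nrow(x$springs), "springs (cutoff", x$contact_cutoff, "nm, k",
      x$k_default, "kJ/mol/nm^2)\n")
  if (!is.null(x$pathway_edges))
    cat("  planted pathway:", nrow(x$pathway_edges), "edges\n")
  if (length(x$ligand_serials))
    cat("  ligand nodes:", length(x$ligand_serials), "\n")
  invisible(x)
}

#' Hessian of an elastic-network model
#'
#' Second-derivative matrix of the spring potential at the model's reference
#' coordinates (a stationary point, so only the longitudinal projector term
#' survives per spring).
#'
#' @param model a `toy_model`
#' @param mass_weighted if TRUE, returns M^-1/2 H M^-1/2 (eigenvalues are
#'   squared angular frequencies in rad^2/ps^2)
#' @return a 3N x 3N symmetric matrix
#' @export
enm_hessian <- function(model, mass_weighted = FALSE) {
  X <- model$xyz
  N <- nrow(X)
  H <- matrix(0, 3 * N, 3 * N)
  sp <- model$springs
  for (e in seq_len(nrow(sp))) {
    i <- sp$i[e]; j <- sp$j[e]
    d <- X[j, ] - X[i, ]
    u <- d / sqrt(sum(d^2))
    blk <- sp$k[e] * tcrossprod(u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  if (mass_weighted) {
    w <- rep(1 / sqrt(model$topology$atoms$mass), each = 3)
    H <- H * outer(w, w)
  }
  H
}

#' Analytic configurational entropy of a model
#'
#' Quantum harmonic-oscillator entropy summed over the vibrational modes of
#' the mass-weighted Hessian (rigid-body null modes excluded). This is the
#' exact entropy of the harmonic system the Gaussian sampler draws from, and
#' serves as the ground truth for the trajectory-based estimators.
#'
#' @param model a `toy_model`
#' @param temperature temperature in K
#' @return an `entropy_result` (estimator tag "analytic")
#' @export
analytic_entropy <- function(model, temperature = 300) {
  Ht <- enm_hessian(model, mass_weighted = TRUE)
  w2 <- eigen(Ht, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-9 * max(w2)
  null_modes <- sum(w2 < tol)
  if (null_modes > 6)
    warning("model has ", null_modes - 6, " near-zero modes beyond rigid-body; ",
            "it is mechanically floppy")
  w <- sqrt(w2[w2 >= tol])
  .entropy_result(estimator = "analytic", omega = sort(w),
                  temperature = temperature, selection = "full",
                  n_frames = NA_integer_, replica_stats = NULL)
}
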