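# Force distribution analysis: residue-pairwise forces, averaging over time
# and replicas, state differences, thresholded networks, punctual stress and
# the replica-subset convergence diagnostic.
#
# The residue-pair force is the norm of the summed atom-pair force vectors,
#   F_uv = || sum_{i in u, j in v} F_ij ||,
# computed per frame and only then averaged: time-averaged pairwise forces
# are generally non-zero even at equilibrium, unlike atomic forces.

#' Per-frame residue-pair force scalars
#'
#' Maps atom-pair force vectors onto residue pairs: for each frame and each
#' residue pair (u, v), all F_ij with i in u and j in v are summed as vectors
#' and the norm taken. Intra-residue pairs are excluded. Ligand nodes form
#' their own pseudo-residues and can be dropped with `include_ligand = FALSE`
#' (useful when differencing states with different ligand counts).
#'
#' @param pfs a `pair_force_set`
#' @param topology the matching `topology` (defaults to the one in `pfs`)
#' @param include_ligand keep pairs involving ligand pseudo-residues
#' @return class `respair_frames`: per replica a frames x residue-pairs matrix
#'   of force norms (kJ mol^-1 nm^-1), plus the pair bookkeeping
#' @export
residue_pair_forces <- function(pfs, topology = NULL, include_ligand = TRUE) {
  stopifnot(inherits(pfs, "pair_force_set"))
  if (is.null(topology)) topology <- pfs$topology
  serial <- topology$atoms$serial
  ri_of_serial <- function(s) {
    idx <- match(s, serial)
    if (anyNA(idx)) stop("pair list references unknown serials: ",
                         paste(s[is.na(idx)], collapse = ", "))
    residue_index(topology)[idx]
  }
  ru <- ri_of_serial(pfs$pairs$i)
  rv <- ri_of_serial(pfs$pairs$j)
  keep <- ru != rv
  lig_res <- unique(residue_index(topology)[topology$atoms$het])
  if (!include_ligand) {
    keep <- keep & !(ru %in% lig_res) & !(rv %in% lig_res)
  }
  universe <- unique(residue_labels(topology))
  chains <- topology$atoms$chain[!duplicated(residue_labels(topology))]
  if (!include_ligand && length(lig_res)) {
    chains <- chains[-lig_res]
    universe <- universe[-lig_res]
  }
  # orient each record so the stored vector is the force on the atom in
  # min(ru, rv) from the atom in max(ru, rv)
  lo <- pmin(ru, rv); hi <- pmax(ru, rv)
  sgn <- ifelse(ru <= rv, 1, -1)
  rec <- which(keep)
  if (!length(rec)) {
    pairs <- data.frame(u = integer(), v = integer(),
                        label_u = character(), label_v = character())
    reps <- lapply(pfs$replicas, function(a) matrix(0, dim(a)[1], 0))
    return(structure(list(pairs = pairs, replicas = reps, state = pfs$state,
                          topology = topology, universe = universe,
                          chains = chains), class = "respair_frames"))
  }
  key <- paste(lo[rec], hi[rec])
  grp <- match(key, unique(key))
  ng <- max(grp)
  first <- rec[!duplicated(grp)]
  ulab <- unique(residue_labels(topology))
  pairs <- data.frame(u = lo[first], v = hi[first],
                      label_u = ulab[lo[first]], label_v = ulab[hi[first]],
                      stringsAsFactors = FALSE)
  replicas <- lapply(pfs$replicas, function(arr) {
    nf <- dim(arr)[1]
    sx <- matrix(0, nf, ng); sy <- matrix(0, nf, ng); sz <- matrix(0, nf, ng)
    for (m in seq_along(rec)) {
      e <- rec[m]; g <- grp[m]; s <- sgn[e]
      sx[, g] <- sx[, g] + s * arr[, e, 1]
      sy[, g] <- sy[, g] + s * arr[, e, 2]
      sz[, g] <- sz[, g] + s * arr[, e, 3]
    }
    sqrt(sx^2 + sy^2 + sz^2)
  })
  structure(list(pairs = pairs, replicas = replicas, state = pfs$state,
                 topology = topology, universe = universe, chains = chains),
            class = "respair_frames")
}

#' Average residue-pair forces over time and replicas
#'
#' Per-frame scalars are averaged over frames within each replica, then
#' unweighted over replicas (replicas are treated as equal-length independent
#' runs). Per-replica means are retained for convergence diagnostics.
#'
#' @param rpf a `respair_frames` object
#' @return class `pair_force_table`: data.frame with residue-pair labels and
#'   `mean_pN`; per-replica means in `attr(, "replica_means")` (pN)
#' @export
average_table <- function(rpf) {
  stopifnot(inherits(rpf, "respair_frames"))
  per_rep <- vapply(rpf$replicas, colMeans,
                    numeric(nrow(rpf$pairs)))
  per_rep <- matrix(per_rep, nrow = nrow(rpf$pairs)) * .PN_PER_KJ_MOL_NM
  tab <- cbind(rpf$pairs, mean_pN = rowMeans(per_rep))
  attr(tab, "replica_means") <- per_rep
  attr(tab, "state") <- rpf$state
  attr(tab, "residues") <- rpf$universe
  attr(tab, "chains") <- rpf$chains
  class(tab) <- c("pair_force_table", "data.frame")
  tab
}

#' Difference of two residue-pair force tables
#'
#' Delta F_uv = <F_uv>_B - <F_uv>_A per residue pair; pairs present in only
#' one table are treated as zero in the other. The residue sets of the two
#' states must be identical (drop ligand pseudo-residues upstream when
#' comparing different liganded states).
#'
#' @param a,b `pair_force_table` objects for states A and B
#' @return class `force_delta`: data.frame with `label_u`, `label_v`,
#'   `delta_pN` (signed)
#' @export
force_difference <- function(a, b) {
  stopifnot(inherits(a, "pair_force_table"), inherits(b, "pair_force_table"))
  ra <- attr(a, "residues"); rb <- attr(b, "residues")
  if (!setequal(ra, rb)) {
    stop("residue sets differ between tables: ",
         paste(union(setdiff(ra, rb), setdiff(rb, ra)), collapse = ", "))
  }
  key_a <- paste(a$label_u, a$label_v)
  key_b <- paste(b$label_u, b$label_v)
  keys <- union(key_a, key_b)
  va <- a$mean_pN[match(keys, key_a)]; va[is.na(va)] <- 0
  vb <- b$mean_pN[match(keys, key_b)]; vb[is.na(vb)] <- 0
  lab <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  out <- data.frame(label_u = lab[, 1], label_v = lab[, 2],
                    delta_pN = vb - va, stringsAsFactors = FALSE)
  attr(out, "residues") <- ra
  attr(out, "states") <- c(attr(a, "state"), attr(b, "state"))
  class(out) <- c("force_delta", "data.frame")
  out
}

#' Thresholded force-difference network
#'
#' Keeps residue pairs with |Delta F| >= cutoff as undirected edges and
#' extracts connected components. Components are ordered by residue count,
#' ties broken by summed |Delta F| (descending) then by the lexicographically
#' smallest residue label, so the ordering is deterministic. `keep = "largest"`
#' restricts the network to the first component, the convention used to
#' suppress undersampling noise.
#'
#' @param delta a `force_delta` table
#' @param cutoff_pN force-difference cutoff in pN (> 0); 40 and 50 pN are the
#'   standard presets
#' @param keep "largest" or "all"
#' @return class `force_network`
#' @export
threshold_network <- function(delta, cutoff_pN, keep = c("largest", "all")) {
  keep <- match.arg(keep)
  stopifnot(cutoff_pN > 0)
  ed <- delta[abs(delta$delta_pN) >= cutoff_pN, , drop = FALSE]
  if (nrow(ed) == 0) {
    out <- list(edges = data.frame(label_u = character(), label_v = character(),
                                   delta_pN = numeric(), component = integer()),
                components = list(), cutoff_pN = cutoff_pN, keep = keep)
    class(out) <- "force_network"
    return(out)
  }
  verts <- sort(unique(c(ed$label_u, ed$label_v)))
  g <- igraph::graph_from_data_frame(ed[, c("label_u", "label_v")],
                                     directed = FALSE,
                                     vertices = data.frame(name = verts))
  comp <- igraph::components(g)
  memb <- comp$membership[verts]
  stat <- lapply(seq_len(comp$no), function(ci) {
    res <- verts[memb == ci]
    in_c <- ed$label_u %in% res & ed$label_v %in% res
    list(res = res, n = length(res), wt = sum(abs(ed$delta_pN[in_c])),
         minlab = min(res))
  })
  ord <- order(-vapply(stat, `[[`, numeric(1), "n"),
               -vapply(stat, `[[`, numeric(1), "wt"),
               vapply(stat, `[[`, character(1), "minlab"))
  rank_of <- match(seq_len(comp$no), ord)
  ed$component <- rank_of[memb[ed$label_u]]
  if (keep == "largest") {
    ed <- ed[ed$component == 1, , drop = FALSE]
    comps <- list(stat[[ord[1]]]$res)
  } else {
    comps <- lapply(ord, function(ci) stat[[ci]]$res)
  }
  ed <- ed[order(ed$component, ed$label_u, ed$label_v), , drop = FALSE]
  rownames(ed) <- NULL
  out <- list(edges = ed[, c("label_u", "label_v", "delta_pN", "component")],
              components = comps, cutoff_pN = cutoff_pN, keep = keep)
  class(out) <- "force_network"
  out
}

#' @export
print.force_network <- function(x, ...) {
  cat("force_network: cutoff ", x$cutoff_pN, " pN, ", nrow(x$edges),
      " edge(s), ", length(x$components), " component(s) kept (",
      x$keep, ")\n", sep = "")
  if (length(x$components)) {
    cat("  largest component: ", length(x$components[[1]]), " residues\n",
        sep = "")
  }
  invisible(x)
}

#' Punctual stress profile
#'
#' Per-residue stress S_u = sum_v <F_uv>: the sum of the mean pairwise force
#' magnitudes of all residue pairs involving u.
#'
#' @param table a `pair_force_table`
#' @return class `stress_profile`: data.frame with `label`, `chain`, `resno`,
#'   `stress_pN`; per-replica stresses in `attr(, "replica_stress")`
#' @export
punctual_stress <- function(table) {
  stopifnot(inherits(table, "pair_force_table"))
  res <- attr(table, "residues")
  chains <- attr(table, "chains")
  iu <- match(table$label_u, res)
  iv <- match(table$label_v, res)
  acc <- function(v) {
    s <- numeric(length(res))
    s[seq_along(res)] <- 0
    for (r in seq_len(nrow(table))) {
      s[iu[r]] <- s[iu[r]] + v[r]
      s[iv[r]] <- s[iv[r]] + v[r]
    }
    s
  }
  stress <- acc(table$mean_pN)
  rm <- attr(table, "replica_means")
  rep_stress <- if (!is.null(rm)) apply(rm, 2, acc) else NULL
  resno <- as.integer(sub("^[^:]*:", "", res))
  out <- data.frame(label = res, chain = chains, resno = resno,
                    stress_pN = stress, stringsAsFactors = FALSE)
  attr(out, "replica_stress") <- rep_stress
  attr(out, "state") <- attr(table, "state")
  class(out) <- c("stress_profile", "data.frame")
  out
}

#' Replica-subset convergence of the protomer stress difference
#'
#' For a homodimer sampled with R replicas, the punctual stress of the two
#' protomers must agree in the limit of infinite sampling. For every subset
#' size k <= `k_max`, the pair table is re-averaged over each k-subset of
#' replicas (all subsets, or a seeded random sample of `n_subsets` when the
#' binomial count explodes), the per-residue stress computed, and the mean
#' absolute stress difference between C2-partner residues recorded. The
#' resulting curve decreasing with k indicates converging force differences.
#'
#' @param table a `pair_force_table` with per-replica means
#' @param k_max largest subset size (default: number of replicas)
#' @param n_subsets cap on the number of subsets per k (random sample beyond)
#' @param seed seed for subset sampling
#' @return data.frame with `k`, `mean_abs_diff_pN`, `n_subsets`
#' @export
convergence_curve <- function(table, k_max = NULL, n_subsets = 2000,
                              seed = 1L) {
  stopifnot(inherits(table, "pair_force_table"))
  rm <- attr(table, "replica_means")
  if (is.null(rm)) stop("table carries no per-replica means")
  R <- ncol(rm)
  if (R < 2) stop("convergence diagnostic needs at least 2 replicas")
  if (is.null(k_max)) k_max <- R
  if (k_max > R) stop("k_max (", k_max, ") exceeds replica count (", R, ")")
  res <- attr(table, "residues")
  chains <- attr(table, "chains")
  resno <- as.integer(sub("^[^:]*:", "", res))
  pr <- sort(unique(chains[!is.na(chains)]))
  pr <- pr[pr %in% c("A", "B")]
  if (length(pr) != 2) stop("need exactly two protomer chains A and B")
  ia <- which(chains == "A")
  ib <- match(paste0("B:", resno[ia]), res)
  ok <- !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  if (!length(ia)) stop("no C2-partner residues shared between chains")
  iu <- match(table$label_u, res)
  iv <- match(table$label_v, res)
  stress_of <- function(v) {
    s <- numeric(length(res))
    for (r in seq_len(nrow(table))) {
      s[iu[r]] <- s[iu[r]] + v[r]
      s[iv[r]] <- s[iv[r]] + v[r]
    }
    s
  }
  set.seed(as.integer(seed))
  out <- data.frame(k = seq_len(k_max), mean_abs_diff_pN = NA_real_,
                    n_subsets = NA_integer_)
  for (k in seq_len(k_max)) {
    ns <- choose(R, k)
    if (ns <= n_subsets) {
      subsets <- utils::combn(R, k, simplify = FALSE)
    } else {
      subsets <- replicate(n_subsets, sort(sample(R, k)), simplify = FALSE)
    }
    vals <- vapply(subsets, function(ss) {
      v <- rowMeans(rm[, ss, drop = FALSE])
      s <- stress_of(v)
      mean(abs(s[ia] - s[ib]))
    }, numeric(1))
    out$mean_abs_diff_pN[k] <- mean(vals)
    out$n_subsets[k] <- length(subsets)
  }
  out
}
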