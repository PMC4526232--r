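# Collective motions: PCA of coordinate covariance, motion matrices
# (differences of CA-CA distance matrices) and their correlation, projections
# onto eigenvectors, RMSF/B-factor conversion and local RMSD ensembles.

#' Principal component analysis of an ensemble
#'
#' Superposes all frames onto their mean (fit group = analysis selection) and
#' eigen-decomposes the Cartesian coordinate covariance of the selection.
#' Eigenvectors carry a deterministic sign (largest-magnitude component
#' positive); eigenvalues are in nm^2, descending.
#'
#' @param x a `traj_ensemble`, or a frames matrix (rows = frames, 3N columns)
#' @param selection for ensembles: "full", "mainchain", "calpha", "protein" or
#'   atom serials; ignored for plain matrices
#' @param superpose superpose frames to the mean first (default TRUE)
#' @param topology optional `topology` when `x` is a plain matrix
#' @return class `eigen_system`: mean structure, orthonormal `vectors`
#'   (columns), `values` (nm^2)
#' @export
pca_ensemble <- function(x, selection = "mainchain", superpose = TRUE,
                         topology = NULL) {
  if (inherits(x, "traj_ensemble")) {
    if (is.null(topology)) topology <- x$topology
    idx <- .select_atoms(topology, selection)
    mat <- .ens_frames(x, idx)
    sel_label <- if (is.character(selection)) selection else "custom"
  } else {
    mat <- as.matrix(x)
    idx <- seq_len(ncol(mat) / 3)
    sel_label <- "matrix"
  }
  if (nrow(mat) < 2) stop("need at least 2 frames")
  if (superpose) mat <- superpose_frames(mat)
  mu <- colMeans(mat)
  cmat <- stats::cov(mat)
  e <- eigen(cmat, symmetric = TRUE)
  nmode <- ncol(e$vectors)
  nrank <- min(nmode, nrow(mat) - 1)
  if (nrank < nmode) {
    warning("fewer frames than modes; truncating to ", nrank, " modes")
  }
  vec <- e$vectors[, seq_len(nrank), drop = FALSE]
  # deterministic sign: largest-magnitude component positive
  for (k in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, k]))
    if (vec[i, k] < 0) vec[, k] <- -vec[, k]
  }
  structure(list(mean = mu, vectors = vec,
                 values = pmax(e$values[seq_len(nrank)], 0),
                 selection = sel_label, atom_idx = idx),
            class = "eigen_system")
}

#' @export
print.eigen_system <- function(x, ...) {
  v <- x$values
  cat("eigen_system: ", length(v), " modes over ", length(x$mean) / 3,
      " atoms (", x$selection, ")\n", sep = "")
  cat("  top eigenvalues (nm^2):", signif(utils::head(v, 5), 4), "\n")
  cat("  variance in mode 1:", signif(100 * v[1] / sum(v), 3), "%\n")
  invisible(x)
}

#' Project frames onto an eigenvector
#'
#' Superposes frames onto the eigen-system's mean structure and returns the
#' dot product of the displacement with the requested mode: the per-frame
#' collective coordinate (nm).
#'
#' @param x a `traj_ensemble` (its selection atoms are used) or a frames
#'   matrix over the same coordinates as `eig`
#' @param eig an `eigen_system`
#' @param mode mode number (1 = largest variance)
#' @param superpose superpose onto the eigen mean first (default TRUE)
#' @return numeric vector of projections
#' @export
project_frames <- function(x, eig, mode = 1, superpose = TRUE) {
  stopifnot(inherits(eig, "eigen_system"))
  if (mode > ncol(eig$vectors)) stop("mode ", mode, " not available")
  mat <- if (inherits(x, "traj_ensemble")) {
    .ens_frames(x, eig$atom_idx)
  } else {
    as.matrix(x)
  }
  if (ncol(mat) != length(eig$mean)) {
    stop("selection mismatch: frames have ", ncol(mat), " coordinates, ",
         "eigen system has ", length(eig$mean))
  }
  if (superpose) mat <- superpose_frames(mat, ref = eig$mean)
  as.vector(sweep(mat, 2, eig$mean) %*% eig$vectors[, mode])
}

#' Project a set of structures onto an eigenvector
#'
#' Same as [project_frames()] for a structure set (one row per structure),
#' e.g. crystal structures alongside trajectory data.
#'
#' @inheritParams project_frames
#' @param structures matrix of flat coordinates, one structure per row
#' @return numeric vector of projections
#' @export
project_structures <- function(structures, eig, mode = 1, superpose = TRUE) {
  project_frames(as.matrix(structures), eig, mode, superpose)
}

#' Motion matrix: difference of two CA-CA distance matrices
#'
#' M = D(a) - D(b) over the selected nodes. Distance matrices are internal
#' coordinates, so the comparison needs no fitting and is invariant to
#' rigid-body placement of either conformation.
#'
#' @param a,b conformations: N x 3 coordinate matrices (same atom set)
#' @return class `motion_matrix` (symmetric, zero diagonal, nm)
#' @export
motion_matrix <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("conformations differ in size")
  M <- as.matrix(stats::dist(a)) - as.matrix(stats::dist(b))
  dimnames(M) <- NULL
  class(M) <- c("motion_matrix", class(M))
  M
}

#' Motion matrix of an eigenvector mode
#'
#' Displaces the mean structure by +/- `amplitude` along the mode and takes
#' the motion matrix of the two end conformations. The default amplitude is
#' one standard deviation along the mode (sqrt of the eigenvalue).
#'
#' @param eig an `eigen_system`
#' @param mode mode number
#' @param amplitude displacement amplitude in nm (default sqrt(eigenvalue))
#' @return class `motion_matrix`
#' @export
motion_matrix_from_mode <- function(eig, mode = 1, amplitude = NULL) {
  stopifnot(inherits(eig, "eigen_system"))
  if (is.null(amplitude)) amplitude <- sqrt(eig$values[mode])
  v <- eig$vectors[, mode]
  plus <- matrix(eig$mean + amplitude * v, ncol = 3, byrow = TRUE)
  minus <- matrix(eig$mean - amplitude * v, ncol = 3, byrow = TRUE)
  motion_matrix(plus, minus)
}

#' Correlation between two motion matrices
#'
#' Pearson correlation over the unique off-diagonal entries; 1 for identical
#' motions, -1 for opposed ones.
#'
#' @param m1,m2 `motion_matrix` objects of the same size
#' @return correlation coefficient in [-1, 1]; NA with a warning when either
#'   matrix has zero variance
#' @export
motion_correlation <- function(m1, m2) {
  if (!all(dim(m1) == dim(m2))) stop("motion matrices differ in shape")
  ut <- upper.tri(m1)
  x <- m1[ut]; y <- m2[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance motion matrix; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' RMSF and crystallographic B-factors of an ensemble
#'
#' Per-atom root mean square fluctuation about the mean structure after
#' superposition, in Angstrom, and the harmonic B-factor equivalent
#' B = (8 pi^2 / 3) RMSF^2 (Angstrom^2). When a reference B-factor column is
#' supplied (e.g. from a crystal structure) the Pearson correlation is
#' reported alongside.
#'
#' @param ens a `traj_ensemble`
#' @param selection atom selection (default "calpha")
#' @param bfactors optional experimental B-factors, one per selected atom
#' @param superpose superpose frames first (default TRUE)
#' @return data.frame with `label`, `rmsf_A`, `bfactor_A2` and attribute
#'   `cor_bfactor` when `bfactors` given
#' @export
rmsf_bfactor <- function(ens, selection = "calpha", bfactors = NULL,
                         superpose = TRUE) {
  idx <- .select_atoms(ens$topology, selection)
  mat <- .ens_frames(ens, idx)
  if (superpose) mat <- superpose_frames(mat)
  mu <- colMeans(mat)
  dev2 <- sweep(mat, 2, mu)^2
  msf <- colMeans(dev2)
  per_atom <- sqrt(msf[seq(1, length(msf), 3)] + msf[seq(2, length(msf), 3)] +
                     msf[seq(3, length(msf), 3)])
  rmsf_A <- 10 * per_atom  # nm -> Angstrom
  out <- data.frame(label = residue_labels(ens$topology)[idx],
                    rmsf_A = rmsf_A,
                    bfactor_A2 = (8 * pi^2 / 3) * rmsf_A^2,
                    stringsAsFactors = FALSE)
  if (!is.null(bfactors)) {
    if (length(bfactors) != nrow(out)) {
      stop("bfactors length (", length(bfactors), ") != selection size (",
           nrow(out), ")")
    }
    attr(out, "cor_bfactor") <- stats::cor(out$bfactor_A2, bfactors)
  }
  out
}

#' Local RMSD ensemble of a residue
#'
#' For each frame: fit the frame onto the reference using only the residues
#' whose atoms lie within `fit_cutoff_nm` of the target residue in the
#' reference (the target itself excluded), then report the RMSD of the target
#' residue's atoms. Local rearrangements are thus tracked without global
#' motions. The reference should be the average structure over all states so
#' that conformational ensembles of different states are directly comparable.
#'
#' @param ens a `traj_ensemble`
#' @param target_residue residue label ("A:5") or global residue index
#' @param reference reference coordinates (N x 3 matrix or flat vector)
#' @param fit_cutoff_nm neighbourhood cutoff in nm (default 0.6, i.e. 6 A)
#' @return numeric vector of per-frame RMSDs in Angstrom, with the neighbour
#'   residue labels as attribute `fit_residues`
#' @export
local_rmsd <- function(ens, target_residue, reference, fit_cutoff_nm = 0.6) {
  top <- ens$topology
  if (is.matrix(reference)) reference <- as.vector(t(reference))
  if (length(reference) != 3 * n_atoms(top)) {
    stop("reference size does not match topology")
  }
  lab <- residue_labels(top)
  ulab <- unique(lab)
  tl <- if (is.numeric(target_residue)) ulab[target_residue] else target_residue
  if (!tl %in% ulab) stop("unknown residue: ", tl)
  t_idx <- which(lab == tl)
  refm <- matrix(reference, ncol = 3, byrow = TRUE)
  dmin <- apply(refm, 1, function(p) {
    min(sqrt(rowSums(sweep(refm[t_idx, , drop = FALSE], 2, p)^2)))
  })
  fit_res <- setdiff(unique(lab[dmin <= fit_cutoff_nm]), tl)
  if (!length(fit_res)) {
    stop("no neighbour residues within ", fit_cutoff_nm, " nm of ", tl)
  }
  f_idx <- which(lab %in% fit_res)
  out <- unlist(lapply(ens$replicas, function(xyz) {
    fitted <- superpose_frames(xyz, ref = reference, fit_idx = f_idx)
    vapply(seq_len(nrow(fitted)), function(f) {
      .rmsd_flat(fitted[f, ], reference, t_idx)
    }, numeric(1))
  }))
  out <- out * 10  # nm -> Angstrom
  attr(out, "fit_residues") <- fit_res
  attr(out, "target") <- tl
  out
}
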