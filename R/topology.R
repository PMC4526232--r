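#' Construct a topology
#'
#' A topology maps atoms to residues and protomers (chains) and carries the
#' per-atom masses used by mass-weighted analyses. Optional selection groups
#' define methyl-style axis vectors and dihedral quadruples.
#'
#' @param atoms data.frame with columns `serial` (unique, 1-based), `name`,
#'   `resno`, `resname`, `chain`, `mass` (amu) and optionally `het` (logical,
#'   ligand/heteroatom flag).
#' @param nodes_per_residue pseudo-atom granularity bookkeeping (1 or 4)
#' @param axes optional data.frame of axis-vector definitions with columns
#'   `label`, `from`, `to` (atom serials; the axis is the from->to unit vector)
#' @param dihedrals optional data.frame of dihedral definitions with columns
#'   `label`, `residue`, `a1`..`a4` (atom serials)
#' @return an object of class `topology`
#' @export
topology <- function(atoms, nodes_per_residue = 1L, axes = NULL, dihedrals = NULL) {
  req <- c("serial", "name", "resno", "resname", "chain", "mass")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$serial)) {
    d <- atoms$serial[duplicated(atoms$serial)]
    stop("duplicate atom serials: ", paste(unique(d), collapse = ", "))
  }
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    stop("all atom masses must be positive")
  }
  if (any(is.na(atoms$chain) | atoms$chain == "")) stop("every atom needs a chain id")
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, nodes_per_residue = as.integer(nodes_per_residue),
         axes = axes, dihedrals = dihedrals),
    class = "topology"
  )
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat("topology:", nrow(a), "atoms,", length(unique(residue_labels(x))),
      "residues,", length(unique(a$chain)), "chains (",
      paste(unique(a$chain), collapse = ", "), ")\n")
  if (any(a$het)) cat("  heteroatoms:", sum(a$het), "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a `topology`
#' @return integer atom count
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Residue labels, one per atom
#'
#' Labels are `chain:resno` so that residues of the second protomer stay
#' distinguishable from the first (the prime convention of homodimer work).
#'
#' @param top a `topology`
#' @return character vector, one label per atom
#' @export
residue_labels <- function(top) paste0(top$atoms$chain, ":", top$atoms$resno)

#' Per-atom residue index
#'
#' Integer residue index per atom, numbering residues in order of first
#' appearance (protomer A first, then B, then ligand pseudo-residues).
#'
#' @param top a `topology`
#' @return integer vector, one index per atom
#' @export
residue_index <- function(top) {
  lab <- residue_labels(top)
  match(lab, unique(lab))
}

# index of atoms (row positions, not serials) matching a selection
.select_atoms <- function(top, selection = "full") {
  a <- top$atoms
  if (is.numeric(selection)) {
    idx <- match(selection, a$serial)
    if (anyNA(idx)) stop("unknown atom serials in selection: ",
                         paste(selection[is.na(idx)], collapse = ", "))
    return(idx)
  }
  selection <- match.arg(selection, c("full", "mainchain", "calpha", "protein"))
  switch(selection,
    full = seq_len(nrow(a)),
    protein = which(!a$het),
    mainchain = {
      i <- which(a$name %in% c("N", "CA", "C", "O") & !a$het)
      if (!length(i)) stop("no main-chain atoms (N, CA, C, O) in topology")
      i
    },
    calpha = {
      i <- which(a$name == "CA" & !a$het)
      if (!length(i)) stop("no CA atoms in topology")
      i
    })
}

# expand atom row indices to xyz column indices of a flat (3N) coordinate row
.xyz_cols <- function(atom_idx) {
  as.vector(rbind(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx))
}
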