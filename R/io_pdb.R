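# PDB structure I/O. Parsing proper is delegated to bio3d; a light pre-scan
# of the raw records supplies the validation (duplicate serials, missing
# chain ids) with line numbers, which a generic parser cannot report.

.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974)

.guess_mass <- function(name, resname) {
  el <- substr(trimws(name), 1, 1)
  m <- .element_mass[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records into a topology plus coordinates (converted to
#' nm). Chains become protomers; heteroatom groups (ligands) are flagged.
#' Atom masses are assigned from the element implied by the atom name.
#'
#' @param path path to a PDB file
#' @return list with `topology` (class `topology`) and `xyz` (N x 3, nm)
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  ln <- which(is_atom)
  serial <- suppressWarnings(as.integer(substr(lines[ln], 7, 11)))
  chain <- substr(lines[ln], 22, 22)
  if (anyDuplicated(serial)) {
    d <- which(duplicated(serial))[1]
    stop("duplicate atom serial ", serial[d], " at line ", ln[d])
  }
  bad <- which(chain == " " | is.na(chain))
  if (length(bad)) {
    stop("missing chain id at line ", ln[bad[1]])
  }
  if (all(rec[is_atom] == "HETATM")) {
    stop("no polymer atoms: file contains only HETATM records")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = a$elety,
    resno = as.integer(a$resno),
    resname = a$resid,
    chain = a$chain,
    mass = .guess_mass(a$elety, a$resid),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  # preserve insertion codes in resno labels when present
  if (!is.null(a$insert) && any(!is.na(a$insert) & a$insert != "")) {
    ins <- ifelse(is.na(a$insert) | a$insert == "", "", a$insert)
    atoms$resno <- as.integer(atoms$resno)
    attr(atoms, "insert") <- ins
  }
  top <- topology(atoms)
  xyz <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
  list(topology = top, xyz = xyz)
}

#' Write a structure (or toy model) as PDB
#'
#' Pseudo-atoms are written as CA-style ATOM records with their chain ids;
#' ligand nodes become HETATM records. Coordinates are converted from nm to
#' Angstrom.
#'
#' @param x a `toy_model`, or a list with `topology` and `xyz`
#' @param path output path
#' @return invisibly, the path
#' @export
write_pdb <- function(x, path) {
  top <- x$topology
  xyz <- x$xyz
  a <- top$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(xyz)) * 10,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain)
  invisible(path)
}
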