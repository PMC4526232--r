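# Force-network output: TSV edge lists (with protomer-labelled residues) and
# a molecular-viewer (PyMOL) script drawing the edges on a structure.

#' Write a force network as a TSV edge list
#'
#' Columns: `residue_u`, `residue_v` (protomer-labelled, `chain:resno`),
#' `deltaF_pN`, `component_id`. Optionally also writes a PyMOL script that
#' draws each edge as a dashed connection on the corresponding PDB.
#'
#' @param network a `force_network`
#' @param path output TSV path
#' @param pml_path optional path for a PyMOL viewer script
#' @param pdb_name object name the script refers to (basename of the PDB)
#' @return invisibly, the TSV path
#' @export
write_network <- function(network, path, pml_path = NULL, pdb_name = "model") {
  stopifnot(inherits(network, "force_network"))
  ed <- network$edges
  df <- data.frame(residue_u = ed$label_u, residue_v = ed$label_v,
                   deltaF_pN = sprintf("%.17g", ed$delta_pN),
                   component_id = ed$component, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pml_path)) {
    lines <- c(paste0("# force-difference network, cutoff ",
                      network$cutoff_pN, " pN"),
               paste0("load ", pdb_name, ".pdb"))
    for (r in seq_len(nrow(ed))) {
      cu <- strsplit(ed$label_u[r], ":", fixed = TRUE)[[1]]
      cv <- strsplit(ed$label_v[r], ":", fixed = TRUE)[[1]]
      lines <- c(lines, sprintf(
        "distance edge_%d, (%s and chain %s and resi %s), (%s and chain %s and resi %s)",
        r, pdb_name, cu[1], cu[2], pdb_name, cv[1], cv[2]))
    }
    lines <- c(lines, "hide labels", "set dash_gap, 0")
    writeLines(lines, pml_path)
  }
  invisible(path)
}

#' Read a force-network TSV edge list
#'
#' @param path file written by [write_network()]
#' @return a `force_network` (cutoff unknown unless recorded upstream)
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "character",
                                         "integer"))
  ed <- data.frame(label_u = df$residue_u, label_v = df$residue_v,
                   delta_pN = as.numeric(df$deltaF_pN),
                   component = df$component_id, stringsAsFactors = FALSE)
  comps <- lapply(sort(unique(ed$component)), function(ci) {
    sort(unique(c(ed$label_u[ed$component == ci], ed$label_v[ed$component == ci])))
  })
  out <- list(edges = ed, components = comps, cutoff_pN = NA_real_,
              keep = "file")
  class(out) <- "force_network"
  out
}

#' Write model ground truth as a YAML sidecar
#'
#' Records the generator inputs and planted structures (pathway edges, ligand
#' nodes) of a synthetic model, labelled as synthetic, so downstream results
#' can always be audited against the ground truth.
#'
#' @param model a `toy_model`
#' @param path output YAML path
#' @return invisibly, the path
#' @export
write_model_sidecar <- function(model, path) {
  info <- list(
    kind = "synthetic elastic-network dimer (stand-in, not a real protein)",
    n_res_per_protomer = model$n_res_per_protomer,
    nodes_per_residue = model$topology$nodes_per_residue,
    contact_cutoff_nm = model$contact_cutoff,
    k_default = model$k_default,
    seed = model$seed,
    n_atoms = nrow(model$xyz),
    n_springs = nrow(model$springs),
    ligand_serials = as.list(model$ligand_serials)
  )
  if (!is.null(model$pathway_edges)) {
    pe <- model$pathway_edges
    info$pathway_edges <- lapply(seq_len(nrow(pe)), function(r) {
      list(u = pe$u[r], v = pe$v[r], dk = pe$dk[r])
    })
  }
  yaml::write_yaml(info, path)
  invisible(path)
}
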