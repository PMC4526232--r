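# Plain-text trajectory exchange format: zero-dependency, lossless
# round-trips (coordinates written with 17 significant digits).
#
#   # comments
#   natoms <N>
#   replica <r>
#   frame <t_ps>
#   <x> <y> <z>          (N lines, nm)

#' Write a trajectory ensemble as plain text
#'
#' @param ens a `traj_ensemble`
#' @param path output path
#' @return invisibly, the path
#' @export
write_traj <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# state ", ens$state),
               paste0("# dt_ps ", format(ens$dt_ps, digits = 17)),
               paste0("natoms ", ncol(ens$replicas[[1]]) / 3)), con)
  for (r in seq_along(ens$replicas)) {
    writeLines(paste0("replica ", r), con)
    xyz <- ens$replicas[[r]]
    for (f in seq_len(nrow(xyz))) {
      writeLines(paste0("frame ", format((f - 1) * ens$dt_ps, digits = 17)), con)
      m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      writeLines(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]), con)
    }
  }
  invisible(path)
}

#' Read a plain-text trajectory ensemble
#'
#' @param path file written by [write_traj()]
#' @param topology optional `topology` to attach (atom count is validated)
#' @return a `traj_ensemble` (without topology unless supplied)
#' @export
read_traj <- function(path, topology = NULL) {
  lines <- readLines(path)
  state <- NA_character_
  dt_ps <- NA_real_
  for (l in lines[startsWith(lines, "#")]) {
    if (grepl("^# state ", l)) state <- sub("^# state ", "", l)
    if (grepl("^# dt_ps ", l)) dt_ps <- as.numeric(sub("^# dt_ps ", "", l))
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  natoms_line <- grep("^natoms ", body)
  if (length(natoms_line) != 1) stop("missing natoms header in ", path)
  N <- as.integer(sub("^natoms ", "", body[natoms_line]))
  if (!is.null(topology) && N != n_atoms(topology)) {
    stop("trajectory has ", N, " atoms; topology has ", n_atoms(topology))
  }
  body <- body[-natoms_line]
  rep_at <- grep("^replica ", body)
  if (!length(rep_at)) stop("no replica blocks in ", path)
  bounds <- c(rep_at, length(body) + 1)
  replicas <- vector("list", length(rep_at))
  for (r in seq_along(rep_at)) {
    blk <- body[(bounds[r] + 1):(bounds[r + 1] - 1)]
    fr_at <- grep("^frame ", blk)
    if (!length(fr_at)) stop("replica ", r, " has no frames")
    fb <- c(fr_at, length(blk) + 1)
    xyz <- matrix(0, length(fr_at), 3 * N)
    for (f in seq_along(fr_at)) {
      rows <- blk[(fb[f] + 1):(fb[f + 1] - 1)]
      if (length(rows) != N) {
        stop("frame ", f, " of replica ", r, " has ", length(rows),
             " coordinate lines, expected ", N)
      }
      vals <- scan(text = rows, quiet = TRUE)
      xyz[f, ] <- vals
    }
    replicas[[r]] <- xyz
  }
  structure(list(state = state, topology = topology, replicas = replicas,
                 dt_ps = dt_ps, temperature = NA_real_, sampler = NA_character_,
                 seeds = NULL),
            class = "traj_ensemble")
}
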