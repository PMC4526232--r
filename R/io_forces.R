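# Pairwise-force record files. One replica per file:
#
#   # comments
#   frame <t_ps>
#   <serial_i> <serial_j> <fx> <fy> <fz>
#
# 1-based atom serials with i < j (F_ji = -F_ij implied), forces in
# kJ mol^-1 nm^-1. Records absent from a frame are zero. The on-disk format
# is declared by this package, not inherited from any MD engine.

#' Write one replica of a pairwise-force set
#'
#' @param pfs a `pair_force_set`
#' @param path output path
#' @param replica which replica to write (default 1)
#' @return invisibly, the path
#' @export
write_pairforce_file <- function(pfs, path, replica = 1L) {
  stopifnot(inherits(pfs, "pair_force_set"))
  arr <- pfs$replicas[[replica]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# state ", pfs$state),
               "# pairwise forces, kJ/mol/nm, serials 1-based, i < j"), con)
  nf <- dim(arr)[1]
  for (f in seq_len(nf)) {
    writeLines(paste0("frame ", format((f - 1) * pfs$dt_ps, digits = 17)), con)
    writeLines(sprintf("%d %d %.17g %.17g %.17g",
                       pfs$pairs$i, pfs$pairs$j,
                       arr[f, , 1], arr[f, , 2], arr[f, , 3]), con)
  }
  invisible(path)
}

#' Read a pairwise-force file
#'
#' Validates serials against the topology, requires i < j and strictly
#' increasing frame times; errors carry the offending line number.
#'
#' @param path file in the pairwise-force text format
#' @param topology the `topology` the serials refer to
#' @return a `pair_force_set` with one replica; pairs are the union of the
#'   records seen (absent records in a frame are zero)
#' @export
read_pairforce_file <- function(path, topology) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  body <- lines[keep]
  fr_at <- grep("^frame ", body)
  if (!length(fr_at)) stop("no frame blocks in ", path)
  times <- as.numeric(sub("^frame +", "", body[fr_at]))
  if (anyNA(times)) stop("unparseable frame time at line ", lineno[fr_at[which(is.na(times))[1]]])
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1] + 1
    stop("non-monotone frame time at line ", lineno[fr_at[bad]])
  }
  serials <- topology$atoms$serial
  fb <- c(fr_at, length(body) + 1)
  recs <- vector("list", length(fr_at))
  for (f in seq_along(fr_at)) {
    if (fb[f] + 1 > fb[f + 1] - 1) {
      recs[[f]] <- matrix(numeric(0), 0, 5)
      next
    }
    rows <- (fb[f] + 1):(fb[f + 1] - 1)
    m <- matrix(scan(text = body[rows], quiet = TRUE), ncol = 5, byrow = TRUE)
    bad_serial <- !(m[, 1] %in% serials) | !(m[, 2] %in% serials)
    if (any(bad_serial)) {
      b <- which(bad_serial)[1]
      stop("unknown atom serial at line ", lineno[rows[b]])
    }
    if (any(m[, 2] <= m[, 1])) {
      b <- which(m[, 2] <= m[, 1])[1]
      stop("record must have i < j at line ", lineno[rows[b]])
    }
    recs[[f]] <- m
  }
  # pairs keep their order of first appearance, so a write -> read cycle
  # reproduces the writer's pair ordering bit-exactly
  allp <- unique(do.call(rbind, lapply(recs, function(m) m[, 1:2, drop = FALSE])))
  key <- paste(allp[, 1], allp[, 2])
  arr <- array(0, dim = c(length(fr_at), nrow(allp), 3))
  for (f in seq_along(recs)) {
    m <- recs[[f]]
    if (!nrow(m)) next
    at <- match(paste(m[, 1], m[, 2]), key)
    arr[f, at, ] <- m[, 3:5]
  }
  dt <- if (length(times) > 1) times[2] - times[1] else NA_real_
  structure(list(pairs = data.frame(i = allp[, 1], j = allp[, 2]),
                 topology = topology, replicas = list(arr),
                 state = NA_character_, dt_ps = dt),
            class = "pair_force_set")
}
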