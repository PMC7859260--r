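#' Read a GRO coordinate/trajectory file
#'
#' Reads a GROMACS `.gro` file. Files holding several concatenated
#' configurations (a common text trajectory form) yield one frame per
#' block. Frame time is taken from a `t=` tag on the title line when
#' present, otherwise the block ordinal.
#'
#' @param path path to the `.gro` file.
#' @return list of frames; each frame is a list with `title`, `time` (ns),
#'   `natoms`, `atoms` (data.frame: resno, resname, atom, x, y, z in nm)
#'   and `box` (3-vector, nm).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    natoms <- as.integer(trimws(lines[i + 1L]))
    if (is.na(natoms)) stop("malformed GRO file: bad atom count at line ", i + 1L)
    at <- lines[(i + 2L):(i + 1L + natoms)]
    atoms <- data.frame(
      resno   = as.integer(substr(at, 1, 5)),
      resname = trimws(substr(at, 6, 10)),
      atom    = trimws(substr(at, 11, 15)),
      x = as.numeric(substr(at, 21, 28)),
      y = as.numeric(substr(at, 29, 36)),
      z = as.numeric(substr(at, 37, 44)),
      stringsAsFactors = FALSE)
    box <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]])[1:3]
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else length(frames)
    frames[[length(frames) + 1L]] <-
      list(title = title, time = time, natoms = natoms, atoms = atoms, box = box)
    i <- i + 3L + natoms
  }
  if (!length(frames)) stop("no configurations found in ", path)
  frames
}

#' Write a trajectory to a (multi-frame) GRO file
#'
#' Writes every frame of a bundle trajectory as a concatenated GRO block
#' with the frame time tagged on the title line. Coordinates are written in
#' nm at the format's 0.001 nm precision.
#'
#' @param traj a `bundle_trajectory`.
#' @param path output path.
#' @param bead_name atom name used for every backbone bead (default "BB").
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, bead_name = "BB") {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    nat <- sum(vapply(fr$helices, function(h) nrow(h$xyz), integer(1)))
    writeLines(sprintf("helix bundle, t= %.4f", fr$time), con)
    writeLines(format(nat, width = 5), con)
    serial <- 0L
    resctr <- 0L
    for (h in fr$helices) {
      for (k in seq_len(nrow(h$xyz))) {
        serial <- serial + 1L
        # GRO residue field wraps at 99999; one running residue counter
        writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                           (resctr + k - 1L) %% 99999L + 1L,
                           substr(h$resname[k], 1, 5), bead_name,
                           serial %% 99999L,
                           h$xyz[k, 1], h$xyz[k, 2], h$xyz[k, 3]), con)
      }
      resctr <- resctr + nrow(h$xyz)
    }
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]), con)
  }
  invisible(path)
}
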