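# GROMACS TRR trajectory format: per frame a big-endian XDR header
# (magic 1993, "GMX_trn_file", section byte sizes, natoms, step, time,
# lambda) followed by the 3x3 box and the coordinate/velocity/force blocks
# that the size fields declare. Single precision only (x_size = 12*natoms);
# that is what GROMACS writes for CG runs by default.

.trr_magic <- 1993L
.trr_tag <- "GMX_trn_file"

#' Read a TRR trajectory file
#'
#' @param path path to the `.trr` file.
#' @return list of frames, each with `natoms`, `step`, `time` (ps as stored;
#'   GROMACS writes ps), `box` (3-vector of diagonal elements, nm), and
#'   `xyz` (natoms x 3 matrix, nm). Velocity/force blocks are skipped.
#' @export
read_trr <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rint <- function(n = 1L) readBin(con, "integer", n, size = 4L, endian = "big")
  rflt <- function(n = 1L) readBin(con, "numeric", n, size = 4L, endian = "big")
  frames <- list()
  repeat {
    magic <- rint()
    if (!length(magic)) break
    if (magic != .trr_magic) stop("not a TRR file (bad magic ", magic, ")")
    slen <- rint()              # strlen + 1
    len <- rint()
    tag <- rawToChar(readBin(con, "raw", (len + 3L) %/% 4L * 4L))
    if (substr(tag, 1, len) != .trr_tag)
      stop("unrecognized TRR version tag")
    sz <- rint(10L)  # ir, e, box, vir, pres, top, sym, x, v, f
    names(sz) <- c("ir", "e", "box", "vir", "pres", "top", "sym", "x", "v", "f")
    natoms <- rint(); step <- rint(); nre <- rint()
    dbl <- sz[["box"]] == 72L || (sz[["box"]] == 0L && sz[["x"]] == 24L * natoms)
    if (dbl) stop("double-precision TRR not supported")
    time <- rflt(); lambda <- rflt()
    box <- NULL
    if (sz[["box"]] > 0L) {
      m <- matrix(rflt(9L), 3, 3, byrow = TRUE)
      box <- diag(m)
    }
    if (sz[["vir"]] > 0L) rflt(9L)
    if (sz[["pres"]] > 0L) rflt(9L)
    xyz <- NULL
    if (sz[["x"]] > 0L)
      xyz <- matrix(rflt(3L * natoms), ncol = 3, byrow = TRUE)
    if (sz[["v"]] > 0L) rflt(3L * natoms)
    if (sz[["f"]] > 0L) rflt(3L * natoms)
    frames[[length(frames) + 1L]] <-
      list(natoms = natoms, step = step, time = time, box = box, xyz = xyz)
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

#' Write a trajectory to a TRR file
#'
#' Writes coordinates and the (diagonal, orthorhombic) box of every frame
#' in single precision. Times are written in ps (GROMACS convention), so
#' the trajectory's ns times are multiplied by 1000.
#'
#' @param traj a `bundle_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trr <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "big")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "big")
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    xyz <- do.call(rbind, lapply(fr$helices, `[[`, "xyz"))
    natoms <- nrow(xyz)
    wint(.trr_magic)
    wint(nchar(.trr_tag) + 1L); wint(nchar(.trr_tag))
    writeBin(charToRaw(.trr_tag), con)
    wint(c(0L, 0L, 36L, 0L, 0L, 0L, 0L, 12L * natoms, 0L, 0L))
    wint(c(natoms, i - 1L, 0L))
    wflt(c(fr$time * 1000, 0))                      # ps, lambda
    box <- diag(fr$box)
    wflt(as.numeric(t(box)))
    wflt(as.numeric(t(xyz)))
  }
  invisible(path)
}
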