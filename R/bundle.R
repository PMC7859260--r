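#' Construct a single helix (ordered backbone beads)
#'
#' A helix is the ordered list of coarse-grained backbone (BB) beads of one
#' transmembrane segment: an N x 3 coordinate matrix in nm plus residue
#' metadata. Residue numbers follow the author (source-file) numbering;
#' all internal indexing is sequence-local and 1-based (R convention).
#'
#' @param xyz N x 3 numeric matrix of BB bead positions, nm.
#' @param resno integer vector of author residue numbers, length N.
#' @param resname character vector of 3-letter residue codes, length N.
#' @return An object of class `helix`.
#' @export
helix_beads <- function(xyz, resno = seq_len(nrow(xyz)), resname = rep("ALA", nrow(xyz))) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("helix coordinates must be an N x 3 matrix")
  if (!all(is.finite(xyz))) stop("helix coordinates must be finite")
  n <- nrow(xyz)
  resno <- as.integer(resno)
  if (length(resno) != n || length(resname) != n)
    stop("resno/resname length must match bead count")
  if (n > 1L && any(diff(resno) <= 0L))
    stop("residue numbers must be strictly increasing within a helix")
  structure(list(xyz = xyz, resno = resno, resname = as.character(resname)),
            class = "helix")
}

#' Construct one trajectory frame of a helix bundle
#'
#' @param helices list of `helix` objects, ordered by helix id.
#' @param time frame time in ns.
#' @param box orthorhombic box vector (x, y, z) in nm.
#' @param periodic logical; `FALSE` for NMR-derived frames, where distance
#'   code must not apply the minimum-image convention.
#' @return An object of class `bundle_frame`.
#' @export
bundle_frame <- function(helices, time = 0, box = c(25, 25, 10), periodic = TRUE) {
  if (!length(helices)) stop("a bundle frame needs at least one helix")
  helices <- lapply(helices, function(h) {
    if (inherits(h, "helix")) h else helix_beads(h)
  })
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be a positive 3-vector (nm)")
  structure(list(time = as.numeric(time), box = box,
                 periodic = isTRUE(periodic), helices = helices),
            class = "bundle_frame")
}

#' Construct a bundle trajectory
#'
#' @param frames time-ordered list of `bundle_frame` objects.
#' @param variant peptide variant label (see [peptide_registry()]).
#' @param source character vector of source file paths, if any.
#' @return An object of class `bundle_trajectory`.
#' @export
bundle_trajectory <- function(frames, variant = NA_character_, source = character()) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  stopifnot(all(vapply(frames, inherits, logical(1), "bundle_frame")))
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (is.unsorted(times)) stop("frame times must be non-decreasing")
  nh <- vapply(frames, function(f) length(f$helices), integer(1))
  if (length(unique(nh)) != 1L)
    stop("helix count must be constant across frames")
  structure(list(frames = frames, variant = variant, source = source),
            class = "bundle_trajectory")
}

#' @export
print.bundle_trajectory <- function(x, ...) {
  f1 <- x$frames[[1]]
  nres <- vapply(f1$helices, function(h) nrow(h$xyz), integer(1))
  cat("Helix bundle trajectory\n")
  if (!is.na(x$variant)) cat("  variant : ", x$variant, "\n", sep = "")
  cat("  frames  : ", length(x$frames), " (",
      format(f1$time), " .. ", format(x$frames[[length(x$frames)]]$time),
      " ns)\n", sep = "")
  cat("  helices : ", length(f1$helices), " x ",
      paste(unique(range(nres)), collapse = "-"), " residues\n", sep = "")
  cat("  box     : ", paste(format(f1$box, digits = 4), collapse = " x "),
      " nm", if (!f1$periodic) " (non-periodic)", "\n", sep = "")
  invisible(x)
}

#' @export
length.bundle_trajectory <- function(x) length(x$frames)

n_helices <- function(traj) length(traj$frames[[1]]$helices)

frame_times <- function(traj) vapply(traj$frames, `[[`, numeric(1), "time")

#' Minimum-image displacement between two points
#'
#' Component-wise nearest-image displacement `b - a` under an orthorhombic
#' box; plain displacement when `box` is `NULL` (non-periodic frames).
#'
#' @param a,b 3-vectors, nm.
#' @param box 3-vector box (nm) or `NULL`.
#' @return displacement 3-vector b - a, nearest image.
#' @export
min_image <- function(a, b, box = NULL) {
  d <- b - a
  if (!is.null(box)) d <- d - box * round(d / box)
  d
}

frame_box <- function(frame) if (frame$periodic) frame$box else NULL

#' Select trajectory frames inside a time window
#'
#' @param traj a `bundle_trajectory`.
#' @param window `(t_start, t_end)` ns; `NULL` end means trajectory end.
#' @return integer indices of frames with `t_start <= time <= t_end`.
#' @keywords internal
window_frames <- function(traj, window = NULL) {
  times <- frame_times(traj)
  if (is.null(window)) return(seq_along(times))
  t0 <- window[[1]]
  t1 <- if (length(window) < 2L || is.na(window[[2]])) max(times) else window[[2]]
  idx <- which(times >= t0 & times <= t1)
  if (!length(idx)) stop("analysis window [", t0, ", ", t1,
                         "] ns contains no trajectory frames")
  idx
}

#' Apply a global rigid transform to every frame
#'
#' Rotates every bead of every helix by `rot` (3 x 3) and then translates by
#' `shift`. Used to check frame invariance of downstream analyses: radial
#' maps and the oligomer census must not change under a global Z-rotation
#' plus translation.
#'
#' @param traj a `bundle_trajectory`.
#' @param rot 3 x 3 rotation matrix.
#' @param shift translation 3-vector, nm.
#' @return the transformed trajectory.
#' @export
transform_trajectory <- function(traj, rot = diag(3), shift = c(0, 0, 0)) {
  traj$frames <- lapply(traj$frames, function(fr) {
    fr$helices <- lapply(fr$helices, function(h) {
      h$xyz <- sweep(h$xyz %*% t(rot), 2, shift, `+`)
      h
    })
    fr
  })
  traj
}

#' Rotation matrix about the Z axis
#' @param deg angle in degrees, counterclockwise.
#' @return 3 x 3 rotation matrix.
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
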