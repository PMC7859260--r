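#' Helix centroid from a residue triplet
#'
#' The per-helix reference point is the arithmetic mean of the BB bead of a
#' chosen central residue and `halfwidth` consecutive beads at each side
#' (default one, i.e. `(r[i-1] + r[i] + r[i+1]) / 3`). Widening to two
#' beads per side changes the centroid by well under 0.05 nm on a regular
#' helix.
#'
#' @param helix a `helix` object.
#' @param center_residue sequence-local index (1-based) of the central bead.
#' @param halfwidth beads included at each side of the centre.
#' @return centroid 3-vector, nm.
#' @export
helix_centroid <- function(helix, center_residue, halfwidth = 1L) {
  n <- nrow(helix$xyz)
  lo <- center_residue - halfwidth
  hi <- center_residue + halfwidth
  if (lo < 1L || hi > n)
    stop("center residue ", center_residue, " +/- ", halfwidth,
         " falls outside the helix (1..", n, ")")
  colMeans(helix$xyz[lo:hi, , drop = FALSE])
}

#' In-plane helix orientation by the bisection-vector method
#'
#' The orientation of a helix about its axis is taken as the bisector of
#' the two bonds leaving the central bead,
#' `v = (r[i-1] - r[i]) + (r[i+1] - r[i])`, which on a regular alpha-helix
#' points from the surface residue inward toward the helix axis. The
#' bisector is projected onto the membrane (XY) plane and normalized. The
#' result is flagged invalid when the projected norm is below 1e-3 nm
#' (beads collinear along Z) -- a degenerate in-plane direction.
#'
#' @inheritParams helix_centroid
#' @return list with `xy` (unit 2-vector) and `valid` flag.
#' @export
orientation_vector <- function(helix, center_residue) {
  n <- nrow(helix$xyz)
  if (center_residue < 2L || center_residue > n - 1L)
    stop("center residue must have a neighbour at each side")
  r <- helix$xyz
  v <- (r[center_residue - 1L, ] - r[center_residue, ]) +
       (r[center_residue + 1L, ] - r[center_residue, ])
  vxy <- v[1:2]
  nv <- sqrt(sum(vxy^2))
  if (nv < 1e-3) return(list(xy = c(NA_real_, NA_real_), valid = FALSE))
  list(xy = vxy / nv, valid = TRUE)
}

# principal axis of the bead cloud; used to reject strongly tilted helices
.helix_axis <- function(helix) {
  x <- sweep(helix$xyz, 2, colMeans(helix$xyz))
  svd(x, nu = 0, nv = 1)$v[, 1]
}

#' Body-fixed frame descriptor of one helix at one time point
#'
#' Combines [helix_centroid()] and [orientation_vector()] into the
#' reference-frame descriptor used by the radial density and census
#' machinery. Helices tilted more than `max_tilt` degrees away from the
#' membrane normal (Z) are flagged invalid rather than producing a
#' meaningless in-plane frame.
#'
#' @param frame a `bundle_frame`.
#' @param helix_id helix index within the frame (1-based).
#' @inheritParams helix_centroid
#' @param max_tilt maximum helix tilt from Z, degrees.
#' @return a `helix_descriptor`: `helix_id`, `time`, `centroid`,
#'   `orientation_xy`, `valid`.
#' @export
helix_descriptor <- function(frame, helix_id, center_residue, halfwidth = 1L,
                             max_tilt = 80) {
  h <- frame$helices[[helix_id]]
  ctr <- helix_centroid(h, center_residue, halfwidth)
  ov <- orientation_vector(h, center_residue)
  valid <- ov$valid
  if (valid) {
    ax <- .helix_axis(h)
    tilt <- acos(min(1, abs(ax[3]))) * 180 / pi
    if (tilt > max_tilt) valid <- FALSE
  }
  structure(list(helix_id = helix_id, time = frame$time, centroid = ctr,
                 orientation_xy = ov$xy, valid = valid),
            class = "helix_descriptor")
}

#' Express a neighbour centroid in a reference helix's body frame
#'
#' The body frame has the reference centroid at the origin and the
#' reference orientation vector as the +X direction. The minimum-image
#' displacement to the neighbour centroid is projected onto the membrane
#' plane and rotated accordingly. The result is invariant under global
#' rotation about Z and global translation.
#'
#' @param ref a valid `helix_descriptor`.
#' @param neighbor_centroid 3-vector, nm.
#' @param box box 3-vector (nm) or `NULL`.
#' @return `(x, y)` position, nm, in the reference body frame.
#' @export
to_reference_frame <- function(ref, neighbor_centroid, box = NULL) {
  if (!ref$valid) stop("reference descriptor is invalid (degenerate frame)")
  d <- min_image(ref$centroid, neighbor_centroid, box)[1:2]
  o <- ref$orientation_xy
  c(o[1] * d[1] + o[2] * d[2], -o[2] * d[1] + o[1] * d[2])
}

#' Default reference residue (author numbering) per peptide variant
#'
#' The body-frame construction is anchored on the residue triplet at the
#' oligomer interface: S258/I259/L260 for p75, L181/L182/P183 for Fas and
#' V218/T219/V220 for DR5 (G217-centred for the DR5 dimer-interface
#' analysis). The returned value is the central author residue number.
#'
#' @param variant variant label understood by [peptide_registry()].
#' @param mode `"trimer"` (default interface) or `"dimer"` (DR5 G217).
#' @return author residue number of the central reference residue.
#' @export
default_center_residue <- function(variant, mode = c("trimer", "dimer")) {
  mode <- match.arg(mode)
  key <- .canon_name(variant)
  if (grepl("^p75", key)) return(259L)
  if (grepl("^fas", key)) return(182L)
  if (grepl("^dr5", key)) return(if (mode == "dimer") 217L else 219L)
  stop("no default reference residue for variant '", variant, "'")
}

#' Convert an author residue number to a sequence-local index
#' @param traj a `bundle_trajectory`.
#' @param resno author residue number (looked up on the first helix).
#' @return 1-based local index.
#' @export
local_residue_index <- function(traj, resno) {
  rn <- traj$frames[[1]]$helices[[1]]$resno
  idx <- match(resno, rn)
  if (is.na(idx)) stop("residue number ", resno, " not present (",
                       min(rn), "..", max(rn), ")")
  idx
}

#' Accumulated radial cloud of neighbour centroids
#'
#' For every strided time point and every (reference, neighbour) ordered
#' helix pair, records the neighbour centroid position in the reference
#' helix's body frame, together with the pair's relative orientation angle
#' beta. The accumulated cloud is the scatter that the radial density map
#' summarizes; invalid reference frames are skipped and counted.
#'
#' @param traj a `bundle_trajectory`.
#' @param center_residue central reference residue; sequence-local index by
#'   default, author number when `numbering = "author"`.
#' @param stride_ns time between analysed frames, ns; each tick maps to
#'   the nearest stored frame at or after it.
#' @param window `(t_start, t_end)` ns or `NULL` for the full trajectory.
#' @param numbering `"local"` or `"author"`.
#' @param halfwidth centroid halfwidth, residues.
#' @return a `radial_cloud`: `points` data.frame (time, ref, neighbor, x,
#'   y, distance, alpha, beta), `center_residue`, `n_skipped`,
#'   `n_frames`, `n_helices`.
#' @export
radial_cloud <- function(traj, center_residue, stride_ns = 100, window = NULL,
                         numbering = c("local", "author"), halfwidth = 1L) {
  numbering <- match.arg(numbering)
  if (numbering == "author")
    center_residue <- local_residue_index(traj, center_residue)
  idx <- window_frames(traj, window)
  times <- frame_times(traj)[idx]
  ticks <- seq(times[1], times[length(times)], by = stride_ns)
  pick <- vapply(ticks, function(tk) idx[which(times >= tk - 1e-9)[1]], integer(1))
  pick <- unique(pick)

  H <- n_helices(traj)
  rows <- vector("list", length(pick))
  n_skipped <- 0L
  for (w in seq_along(pick)) {
    fr <- traj$frames[[pick[w]]]
    box <- frame_box(fr)
    desc <- lapply(seq_len(H), helix_descriptor, frame = fr,
                   center_residue = center_residue, halfwidth = halfwidth)
    ok <- vapply(desc, `[[`, logical(1), "valid")
    n_skipped <- n_skipped + sum(!ok) * (H - 1L)
    out <- vector("list", sum(ok))
    j <- 0L
    for (r in which(ok)) {
      nbr <- setdiff(seq_len(H), r)
      xy <- t(vapply(nbr, function(k)
        to_reference_frame(desc[[r]], desc[[k]]$centroid, box), numeric(2)))
      beta <- vapply(nbr, function(k) {
        if (!desc[[k]]$valid) return(NA_real_)
        .ccw_angle(desc[[r]]$orientation_xy, desc[[k]]$orientation_xy)
      }, numeric(1))
      j <- j + 1L
      out[[j]] <- data.frame(time = fr$time, ref = r, neighbor = nbr,
                             x = xy[, 1], y = xy[, 2],
                             distance = sqrt(rowSums(xy^2)),
                             alpha = (atan2(xy[, 2], xy[, 1]) * 180 / pi) %% 360,
                             beta = beta)
    }
    rows[[w]] <- do.call(rbind, out)
  }
  pts <- do.call(rbind, rows)
  structure(list(points = pts, center_residue = center_residue,
                 n_skipped = n_skipped, n_frames = length(pick),
                 n_helices = H),
            class = "radial_cloud")
}

# signed CCW angle (degrees, [0, 360)) from unit 2-vector a to b
.ccw_angle <- function(a, b) {
  (atan2(a[1] * b[2] - a[2] * b[1], a[1] * b[1] + a[2] * b[2]) * 180 / pi) %% 360
}

#' @export
print.radial_cloud <- function(x, ...) {
  cat("Radial cloud: ", nrow(x$points), " neighbour-centroid points\n", sep = "")
  cat("  frames ", x$n_frames, ", helices ", x$n_helices,
      ", reference residue index ", x$center_residue,
      ", skipped pair slots ", x$n_skipped, "\n", sep = "")
  invisible(x)
}

#' Gaussian kernel density map of a radial cloud
#'
#' Evaluates a fixed-bandwidth Gaussian kernel density of the cloud points
#' on a regular grid and scales it to integrate (trapezoid rule) to the
#' number of points used. Points outside the grid extent are excluded and
#' counted; the census machinery works from raw points, so the map is a
#' visual summary only and its bandwidth does not affect any count.
#'
#' @param cloud a `radial_cloud`.
#' @param bandwidth Gaussian kernel standard deviation, nm.
#' @param grid_step grid spacing, nm.
#' @param extent half-width of the square grid, nm.
#' @return a `density_map`: `grid` (matrix, x by y), `x`, `y` (grid axes),
#'   `extent`, `bandwidth`, `total_mass`, `n_points`, `n_excluded`.
#' @export
density_map <- function(cloud, bandwidth = 0.1, grid_step = 0.05, extent = 3) {
  pts <- cloud$points
  if (is.null(pts) || !nrow(pts)) stop("empty radial cloud")
  keep <- abs(pts$x) <= extent & abs(pts$y) <= extent
  if (!any(keep)) stop("no cloud points within the grid extent")
  px <- pts$x[keep]; py <- pts$y[keep]
  n_grid <- round(2 * extent / grid_step) + 1L
  kd <- MASS::kde2d(px, py, h = 4 * bandwidth, n = n_grid,
                    lims = c(-extent, extent, -extent, extent))
  grid <- kd$z * length(px)
  mass <- .trapz2(kd$x, kd$y, grid)
  structure(list(grid = grid, x = kd$x, y = kd$y,
                 extent = c(-extent, extent, -extent, extent),
                 bandwidth = bandwidth, total_mass = mass,
                 n_points = length(px), n_excluded = sum(!keep)),
            class = "density_map")
}

.trapz2 <- function(x, y, z) {
  wx <- diff(x); wy <- diff(y)
  zc <- (z[-1, -1] + z[-nrow(z), -1] + z[-1, -ncol(z)] + z[-nrow(z), -ncol(z)]) / 4
  sum(zc * outer(wx, wy))
}

#' Grid location of a density map's maximum
#' @param map a `density_map`.
#' @return `(x, y)` of the argmax grid node, nm.
#' @export
map_argmax <- function(map) {
  ij <- arrayInd(which.max(map$grid), dim(map$grid))
  c(map$x[ij[1]], map$y[ij[2]])
}

#' @export
print.density_map <- function(x, ...) {
  cat("Radial density map ", nrow(x$grid), " x ", ncol(x$grid),
      " (bandwidth ", x$bandwidth, " nm)\n", sep = "")
  cat("  points ", x$n_points, " (", x$n_excluded, " outside extent), mass ",
      format(x$total_mass, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
plot.density_map <- function(x, ...) {
  graphics::image(x$x, x$y, x$grid, xlab = "x (nm)", ylab = "y (nm)",
                  main = "radial density", asp = 1, ...)
  invisible(x)
}
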