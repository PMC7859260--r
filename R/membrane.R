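#' Projected area per lipid
#'
#' Standard bilayer equilibration diagnostic: the projected membrane area
#' (box XY face) divided by the lipids per leaflet,
#' `2 * box_x * box_y / n_lipids_total`. No protein-area correction is
#' applied; with 36 helices in a 625 nm^2 patch the protein bias is a few
#' percent and is reported alongside in the CLI output.
#'
#' @param box_xy box X and Y lengths, nm (2-vector).
#' @param n_lipids_total total lipid count over both leaflets (even).
#' @return area per lipid, nm^2.
#' @export
area_per_lipid <- function(box_xy, n_lipids_total) {
  if (n_lipids_total <= 0) stop("lipid count must be positive")
  if (n_lipids_total %% 2 != 0) stop("lipid count must be even (two leaflets)")
  2 * box_xy[[1]] * box_xy[[2]] / n_lipids_total
}

#' Bilayer thickness from head-group bead positions
#'
#' Assigns head beads to leaflets by their z position relative to the
#' bilayer midplane (the overall mean z) and returns the distance between
#' the two leaflet means, the phosphate-analog head-to-head thickness.
#'
#' @param headgroup_z z coordinates of the lipid head beads, nm.
#' @return thickness, nm.
#' @export
bilayer_thickness <- function(headgroup_z) {
  mid <- mean(headgroup_z)
  up <- headgroup_z[headgroup_z > mid]
  lo <- headgroup_z[headgroup_z <= mid]
  if (!length(up) || !length(lo))
    stop("all head beads fall in one leaflet; cannot measure thickness")
  abs(mean(up) - mean(lo))
}

#' Membrane time series from per-frame box and head-bead data
#'
#' @param times frame times, ns.
#' @param box_xy matrix (frames x 2) of box X/Y lengths, nm.
#' @param n_lipids_total total lipid count.
#' @param headgroup_z optional list (per frame) of head-bead z
#'   coordinates; when given, per-frame thickness is included.
#' @return a `membrane_timeseries` data.frame: `time`, `apl`, `thickness`
#'   (NA when no head beads were supplied).
#' @export
membrane_timeseries <- function(times, box_xy, n_lipids_total,
                                headgroup_z = NULL) {
  box_xy <- matrix(box_xy, ncol = 2)
  apl <- apply(box_xy, 1, area_per_lipid, n_lipids_total = n_lipids_total)
  th <- if (is.null(headgroup_z)) rep(NA_real_, length(times))
        else vapply(headgroup_z, bilayer_thickness, numeric(1))
  structure(data.frame(time = times, apl = apl, thickness = th),
            class = c("membrane_timeseries", "data.frame"))
}

#' Detect convergence of a membrane time series
#'
#' Operational convergence criterion: split the series into consecutive
#' windows of `window_ns` and report the earliest time from which
#' `k_windows` consecutive window means agree pairwise within `rel_tol`
#' (relative). Returns `NA` when the series never settles; errors when the
#' series is too short to judge.
#'
#' @param times sample times, ns.
#' @param values metric values (APL or thickness).
#' @param window_ns window length, ns.
#' @param rel_tol relative tolerance between window means.
#' @param k_windows number of consecutive agreeing windows required.
#' @return convergence onset time (ns) or `NA_real_`.
#' @export
convergence_check <- function(times, values, window_ns, rel_tol = 0.02,
                              k_windows = 3L) {
  span <- max(times) - min(times)
  if (span < (k_windows + 1) * window_ns)
    stop("insufficient data: series spans ", span, " ns but ",
         (k_windows + 1) * window_ns, " ns are needed")
  bins <- floor((times - min(times)) / window_ns)
  means <- tapply(values, bins, mean)
  starts <- min(times) + as.numeric(names(means)) * window_ns
  nb <- length(means)
  for (w in seq_len(nb - k_windows + 1L)) {
    grp <- means[w:(w + k_windows - 1L)]
    if ((max(grp) - min(grp)) / abs(mean(grp)) < rel_tol)
      return(starts[w])
  }
  NA_real_
}
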