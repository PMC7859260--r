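#' Inter-bead contact indicator
#'
#' A contact exists when two backbone beads lie at an XYZ distance equal to
#' or less than the cut-off (the boundary is inclusive). Under a periodic
#' box the minimum-image distance is used.
#'
#' @param pos_a,pos_b bead positions, 3-vectors in nm.
#' @param cutoff contact cut-off, nm (typically 0.5 or 0.8).
#' @param box orthorhombic box 3-vector (nm) or `NULL` for non-periodic.
#' @return integer 0 or 1.
#' @export
contact_indicator <- function(pos_a, pos_b, cutoff, box = NULL) {
  if (!all(is.finite(pos_a)) || !all(is.finite(pos_b)))
    stop("non-finite coordinates")
  if (cutoff <= 0) stop("cutoff must be positive")
  d <- min_image(pos_a, pos_b, box)
  as.integer(sum(d * d) <= cutoff^2)
}

.residue_labels <- function(helix) {
  aa1 <- tryCatch(bio3d::aa321(helix$resname), warning = function(w) NULL,
                  error = function(e) NULL)
  if (is.null(aa1) || any(is.na(aa1)) || length(aa1) != length(helix$resno))
    aa1 <- rep("", length(helix$resno))
  paste0(aa1, helix$resno)
}

#' Accumulated inter-helix residue contact matrix
#'
#' Counts, over the trajectory frames in the analysis window, every ordered
#' helix pair (H, K != H) whose residues i (on K) and j (on H) are in
#' contact at the given cut-off. Intra-helix pairs are never counted.
#' Because both orderings of each helix pair are accumulated, the matrix is
#' symmetric by construction and raw counts are twice the number of
#' unordered contacting pairs; normalization (see
#' [normalize_contacts()]) is invariant to this convention.
#'
#' @param traj a `bundle_trajectory`; all helices must share a residue count.
#' @param cutoff contact cut-off, nm.
#' @param window `(t_start, t_end)` ns, or `NULL` for every frame. The
#'   production analysis window for the simulated bundles is
#'   `c(3000, NA)` (from 3 us to the end of the run).
#' @param stride keep every `stride`-th frame inside the window.
#' @return a `contact_matrix` object: `counts` (N_res x N_res), `cutoff`,
#'   `n_frames`, `window`, `normalized`, `residue_labels`.
#' @export
contact_matrix <- function(traj, cutoff, window = NULL, stride = 1L) {
  idx <- window_frames(traj, window)
  idx <- idx[seq(1L, length(idx), by = stride)]
  nres <- vapply(traj$frames[[1]]$helices, function(h) nrow(h$xyz), integer(1))
  if (length(unique(nres)) != 1L)
    stop("contact matrices require all helices to share one residue count")
  n <- nres[[1]]
  counts <- matrix(0, n, n)
  for (f in idx)
    counts <- counts + .frame_contact_counts(traj$frames[[f]], cutoff)
  labels <- .residue_labels(traj$frames[[1]]$helices[[1]])
  dimnames(counts) <- list(labels, labels)
  times <- frame_times(traj)[idx]
  structure(list(counts = counts, cutoff = cutoff, n_frames = length(idx),
                 window = range(times), normalized = FALSE,
                 all_zero = all(counts == 0), residue_labels = labels),
            class = "contact_matrix")
}

# dense vectorized bead-pair evaluation for one frame; residue-pair counts
# via indicator aggregation t(R) %*% A %*% R. At the study scale (36
# helices x ~35 residues, ~1260 beads) this is a ~12 MB boolean matrix.
.frame_contact_counts <- function(frame, cutoff) {
  xyz <- do.call(rbind, lapply(frame$helices, `[[`, "xyz"))
  nres <- vapply(frame$helices, function(h) nrow(h$xyz), integer(1))
  hid <- rep(seq_along(frame$helices), nres)
  rid <- unlist(lapply(nres, seq_len), use.names = FALSE)
  box <- frame_box(frame)
  d2 <- matrix(0, nrow(xyz), nrow(xyz))
  for (k in 1:3) {
    dk <- outer(xyz[, k], xyz[, k], `-`)
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  adj <- (d2 <= cutoff^2) & outer(hid, hid, `!=`)
  n <- nres[[1]]
  R <- matrix(0, nrow(xyz), n)
  R[cbind(seq_along(rid), rid)] <- 1
  t(R) %*% adj %*% R
}

#' Normalize a contact matrix to its most frequent contact
#'
#' Divides every entry by the maximum entry so the strongest residue pair
#' maps to exactly 1. An all-zero matrix is returned unchanged with its
#' `all_zero` flag set (a warning is raised).
#'
#' @param mat a `contact_matrix` (not yet normalized).
#' @return the normalized `contact_matrix`.
#' @export
normalize_contacts <- function(mat) {
  stopifnot(inherits(mat, "contact_matrix"))
  if (mat$normalized) stop("contact matrix is already normalized")
  mx <- max(mat$counts)
  if (mx == 0) {
    warning("all-zero contact matrix; normalization is a no-op")
    mat$all_zero <- TRUE
    return(mat)
  }
  mat$counts <- mat$counts / mx
  mat$normalized <- TRUE
  mat
}

#' Contact totals across a cut-off sweep
#'
#' Recomputes the contact matrix at each cut-off and tabulates the total
#' raw count and the number of distinct (unordered) residue pairs with at
#' least one contact. Totals are monotone non-decreasing in the cut-off,
#' and the support at a larger cut-off contains the support at a smaller
#' one; cut-offs that are too short (0.4 nm at CG resolution) detect no
#' interactions at all.
#'
#' @inheritParams contact_matrix
#' @param cutoffs numeric vector of cut-offs, nm.
#' @return data.frame with columns `cutoff`, `total_contacts`,
#'   `n_nonzero_pairs`.
#' @export
cutoff_sweep <- function(traj, cutoffs, window = NULL, stride = 1L) {
  if (!length(cutoffs)) stop("at least one cutoff is required")
  rows <- lapply(sort(cutoffs), function(cf) {
    cm <- contact_matrix(traj, cf, window, stride)
    up <- cm$counts[upper.tri(cm$counts, diag = TRUE)]
    data.frame(cutoff = cf, total_contacts = sum(cm$counts),
               n_nonzero_pairs = sum(up > 0))
  })
  do.call(rbind, rows)
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("Inter-helix residue contact matrix (",
      nrow(x$counts), " x ", ncol(x$counts), ")\n", sep = "")
  cat("  cutoff   : ", x$cutoff, " nm\n", sep = "")
  cat("  frames   : ", x$n_frames, " in window [",
      paste(format(x$window), collapse = ", "), "] ns\n", sep = "")
  cat("  ", if (x$normalized) "normalized to most frequent contact"
      else paste0("raw ordered-pair counts, total ", sum(x$counts)), "\n", sep = "")
  if (x$all_zero) cat("  (no contacts found)\n")
  invisible(x)
}

#' Plot a contact matrix as a heat map
#'
#' @param x a `contact_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.contact_matrix <- function(x, ...) {
  n <- nrow(x$counts)
  graphics::image(seq_len(n), seq_len(n), t(x$counts), xaxt = "n", yaxt = "n",
                  xlab = "residue", ylab = "residue",
                  main = sprintf("contacts at %.1f nm", x$cutoff), ...)
  at <- pretty(seq_len(n))
  at <- at[at >= 1 & at <= n]
  graphics::axis(1, at = at, labels = x$residue_labels[at], las = 2, cex.axis = 0.7)
  graphics::axis(2, at = at, labels = x$residue_labels[at], las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Write a contact matrix as CSV plus JSON sidecar
#'
#' @param mat a `contact_matrix`.
#' @param path CSV output path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(mat, path) {
  utils::write.csv(mat$counts, path)
  meta <- list(cutoff = mat$cutoff, n_frames = mat$n_frames,
               window = mat$window, normalized = mat$normalized,
               all_zero = mat$all_zero)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
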