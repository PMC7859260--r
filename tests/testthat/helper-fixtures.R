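# Shared fixtures and independent brute-force oracles.

# random bundle of rigid ideal helices scattered in the box
random_bundle <- function(n_helices, n_residues = 12, box = c(8, 8, 6),
                          n_frames = 1, seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    hs <- lapply(seq_len(n_helices), function(h)
      ideal_helix(n_residues, rot = rot_z(runif(1, 0, 360)),
                  shift = c(runif(2, 0, box[1:2]), box[3] / 2)))
    bundle_frame(hs, time = f - 1, box = box)
  })
  bundle_trajectory(frames)
}

# O(H^2 N^2) brute-force contact matrix with explicit loops (the oracle
# stays independent of the package's vectorized accumulation path)
bf_contact_matrix <- function(traj, cutoff) {
  f1 <- traj$frames[[1]]
  n <- nrow(f1$helices[[1]]$xyz)
  counts <- matrix(0, n, n)
  for (fr in traj$frames) {
    box <- if (fr$periodic) fr$box else NULL
    H <- length(fr$helices)
    for (hH in seq_len(H)) for (hK in seq_len(H)) {
      if (hK == hH) next
      for (i in seq_len(n)) for (j in seq_len(n)) {
        d <- fr$helices[[hK]]$xyz[i, ] - fr$helices[[hH]]$xyz[j, ]
        if (!is.null(box)) d <- d - box * round(d / box)
        if (sum(d * d) <= cutoff^2) counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  counts
}

# all-images minimum distance oracle: wrap both points into the primary
# cell, then scan the 27 surrounding images exhaustively
bf_min_image_dist <- function(a, b, box) {
  a <- a %% box
  b <- b %% box
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- b + c(ix, iy, iz) * box - a
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# explicit rotation-matrix change of basis into a reference body frame
bf_reference_frame <- function(centroid, orient_xy, nbr, box = NULL) {
  d <- nbr - centroid
  if (!is.null(box)) d <- d - box * round(d / box)
  th <- atan2(orient_xy[2], orient_xy[1])
  R <- matrix(c(cos(-th), sin(-th), -sin(-th), cos(-th)), 2, 2)
  as.numeric(R %*% d[1:2])
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
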