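.as_coords <- function(x) {
  if (inherits(x, "bundle_frame"))
    return(do.call(rbind, lapply(x$helices, `[[`, "xyz")))
  if (inherits(x, "helix")) return(x$xyz)
  as.matrix(x)
}

#' Optimal rigid superposition (Kabsch) of two bead sets
#'
#' Least-squares rigid superposition of `mobile` onto `reference` by
#' singular value decomposition of the covariance matrix, with the usual
#' determinant correction so the result is a proper rotation (no
#' reflection). The RMSD is computed after applying the transform.
#'
#' @param mobile,reference N x 3 coordinate matrices (nm), or
#'   `bundle_frame`/`helix` objects.
#' @param correspondence integer index map: bead `k` of `mobile`
#'   corresponds to bead `correspondence[k]` of `reference` (default
#'   identity).
#' @return a `superposition`: `rotation` (3 x 3, det +1), `translation`
#'   (applied after rotation), `rmsd` (nm), `n_atoms`, and `transformed`
#'   (the superposed mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, reference, correspondence = NULL) {
  M <- .as_coords(mobile)
  R0 <- .as_coords(reference)
  if (!is.null(correspondence)) R0 <- R0[correspondence, , drop = FALSE]
  if (nrow(M) != nrow(R0)) stop("bead counts differ (", nrow(M), " vs ",
                                nrow(R0), ")")
  if (nrow(M) < 3L) stop("superposition needs at least 3 beads")
  cm <- colMeans(M); cr <- colMeans(R0)
  A <- sweep(M, 2, cm); B <- sweep(R0, 2, cr)
  s <- svd(t(A) %*% B)
  if (s$d[2] < 1e-12 * max(s$d[1], 1))
    stop("degenerate (collinear) bead set: rotation is not determined")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  rot <- s$v %*% D %*% t(s$u)
  transformed <- sweep(sweep(M, 2, cm) %*% t(rot), 2, cr, `+`)
  rmsd <- sqrt(mean(rowSums((transformed - R0)^2)))
  structure(list(rotation = rot, translation = cr - as.numeric(rot %*% cm),
                 rmsd = rmsd, n_atoms = nrow(M), transformed = transformed),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid superposition of %d beads: RMSD %.4f nm (%.2f A)\n",
              x$n_atoms, x$rmsd, x$rmsd * 10))
  invisible(x)
}

#' Ensemble-average structure of a multi-model trajectory
#'
#' Superposes every model onto the first, averages the coordinates, and
#' reports the per-bead RMS spread about the mean. This is the "NMR
#' average model" used as the alignment reference.
#'
#' @param traj a `bundle_trajectory` with at least two frames (models).
#' @return list with `frame` (a `bundle_frame` holding the averaged
#'   coordinates) and `spread` (per-bead RMS about the mean, nm).
#' @export
ensemble_average <- function(traj) {
  if (length(traj$frames) < 2L) stop("ensemble averaging needs >= 2 models")
  ref <- traj$frames[[1]]
  nbead <- vapply(ref$helices, function(h) nrow(h$xyz), integer(1))
  stack <- lapply(traj$frames, function(fr)
    kabsch_superpose(fr, ref)$transformed)
  arr <- simplify2array(stack)              # nbead_total x 3 x n_models
  avg <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), avg)^2
  spread <- sqrt(apply(dev2, 1, mean) * 3)  # mean over models of |dev|^2
  out <- ref
  off <- 0L
  for (h in seq_along(out$helices)) {
    out$helices[[h]]$xyz <- avg[off + seq_len(nbead[h]), , drop = FALSE]
    off <- off + nbead[h]
  }
  list(frame = out, spread = spread)
}

#' Best superposition of two oligomeric assemblies over chain permutations
#'
#' Oligomer chains have no canonical order, so the assembly RMSD is the
#' minimum over chain correspondences. All permutations of the (equal)
#' chain counts are searched exhaustively -- at the oligomer sizes handled
#' here (n <= 6, at most 720 correspondences) this is always feasible.
#'
#' @param mobile,reference `bundle_frame` objects (or lists of `helix`)
#'   with the same number of chains and beads per chain.
#' @return the minimum-RMSD `superposition`, with `permutation` recording
#'   the winning chain order (mobile chain k matched reference chain
#'   `permutation[k]`).
#' @export
best_oligomer_match <- function(mobile, reference) {
  mh <- if (inherits(mobile, "bundle_frame")) mobile$helices else mobile
  rh <- if (inherits(reference, "bundle_frame")) reference$helices else reference
  if (length(mh) != length(rh))
    stop("assembly sizes differ (", length(mh), " vs ", length(rh), " chains)")
  nb <- vapply(mh, function(h) nrow(h$xyz), integer(1))
  if (!all(nb == vapply(rh, function(h) nrow(h$xyz), integer(1))))
    stop("per-chain bead counts differ")
  M <- do.call(rbind, lapply(mh, `[[`, "xyz"))
  perms <- .permutations(length(rh))
  best <- NULL
  for (p in seq_len(nrow(perms))) {
    Rp <- do.call(rbind, lapply(rh[perms[p, ]], `[[`, "xyz"))
    sp <- kabsch_superpose(M, Rp)
    if (is.null(best) || sp$rmsd < best$rmsd) {
      best <- sp
      best$permutation <- perms[p, ]
    }
  }
  best
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
  dimnames(out) <- NULL
  out
}

#' Fit a Cn symmetry axis to an oligomeric assembly
#'
#' Places the axis through the assembly centroid along the Z-dominant
#' principal direction of the bead cloud, groups the chains into `n`
#' consecutive protomers, and measures how evenly the protomer centroids
#' are spaced around the axis: for perfect Cn symmetry consecutive
#' azimuth gaps all equal 360/n degrees.
#'
#' @param assembly a `bundle_frame` (or list of `helix`) whose chain count
#'   is divisible by `n`.
#' @param n symmetry order (>= 2).
#' @return list: `point` (axis anchor), `direction` (unit 3-vector),
#'   `azimuths` (per protomer, degrees), `gaps` (consecutive azimuth
#'   gaps), `deviation` (max |gap - 360/n|, degrees).
#' @export
fit_cn_axis <- function(assembly, n) {
  hs <- if (inherits(assembly, "bundle_frame")) assembly$helices else assembly
  if (n < 2L) stop("symmetry order must be >= 2")
  if (length(hs) %% n != 0L)
    stop("chain count ", length(hs), " is not divisible by n = ", n)
  per <- length(hs) / n
  all_xyz <- do.call(rbind, lapply(hs, `[[`, "xyz"))
  ctr <- colMeans(all_xyz)
  X <- sweep(all_xyz, 2, ctr)
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  zdom <- which.max(abs(ev$vectors[3, ]))
  u <- ev$vectors[, zdom]
  if (u[3] < 0) u <- -u
  # in-plane orthonormal basis
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  proto <- split(seq_along(hs), ceiling(seq_along(hs) / per))
  az <- vapply(proto, function(ids) {
    pc <- colMeans(do.call(rbind, lapply(hs[ids], `[[`, "xyz"))) - ctr
    if (sqrt(sum(pc^2) - sum(pc * u)^2) < 1e-9)
      stop("degenerate geometry: protomer centroid lies on the axis")
    (atan2(sum(pc * e2), sum(pc * e1)) * 180 / pi) %% 360
  }, numeric(1))
  az_s <- sort(az)
  gaps <- diff(c(az_s, az_s[1] + 360))
  list(point = ctr, direction = u, azimuths = az, gaps = gaps,
       deviation = max(abs(gaps - 360 / n)))
}

#' Radial/tangential/axial decomposition of assembly RMSD
#'
#' Expresses each per-bead deviation (mobile minus reference, after
#' superposition) in the local cylindrical basis about a symmetry axis:
#' axial along the axis, radial outward from it, tangential completing
#' the right-handed triad. Because the basis is orthonormal, the
#' component RMSDs satisfy radial^2 + tangential^2 + axial^2 = total
#' RMSD^2 exactly. Beads lying on the axis (radial direction undefined)
#' are excluded and counted.
#'
#' @param mobile,reference aligned coordinate sets (N x 3 nm matrices or
#'   `bundle_frame`s); superposition must already have been applied.
#' @param axis list with `point` and `direction`, e.g. from
#'   [fit_cn_axis()].
#' @return an `rta_decomposition`: `radial`, `tangential`, `axial`,
#'   `total` (nm), `n_beads`, `n_excluded`.
#' @export
rta_rmsd <- function(mobile, reference, axis) {
  M <- .as_coords(mobile); R0 <- .as_coords(reference)
  if (nrow(M) != nrow(R0)) stop("bead counts differ")
  u <- axis$direction / sqrt(sum(axis$direction^2))
  rel <- sweep(R0, 2, axis$point)
  ax_comp <- as.numeric(rel %*% u)
  rad_vec <- rel - outer(ax_comp, u)
  rad_norm <- sqrt(rowSums(rad_vec^2))
  keep <- rad_norm > 1e-9
  if (!any(keep)) stop("all beads lie on the axis")
  er <- rad_vec[keep, , drop = FALSE] / rad_norm[keep]
  et <- cbind(u[2] * er[, 3] - u[3] * er[, 2],
              u[3] * er[, 1] - u[1] * er[, 3],
              u[1] * er[, 2] - u[2] * er[, 1])
  dev <- (M - R0)[keep, , drop = FALSE]
  r <- rowSums(dev * er)
  t_ <- rowSums(dev * et)
  a <- as.numeric(dev %*% u)
  structure(list(radial = sqrt(mean(r^2)), tangential = sqrt(mean(t_^2)),
                 axial = sqrt(mean(a^2)), total = sqrt(mean(rowSums(dev^2))),
                 n_beads = sum(keep), n_excluded = sum(!keep)),
            class = "rta_decomposition")
}

#' @export
print.rta_decomposition <- function(x, ...) {
  cat(sprintf(
    "RMSD decomposition (nm): R %.4f, T %.4f, A %.4f (total %.4f, %d beads)\n",
    x$radial, x$tangential, x$axial, x$total, x$n_beads))
  if (x$n_excluded) cat("  ", x$n_excluded, " on-axis beads excluded\n", sep = "")
  invisible(x)
}
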