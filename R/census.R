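# circular distance between two angles in degrees
.circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Relative geometry of a helix pair
#'
#' Describes one ordered (reference, neighbour) helix pair by three
#' quantities: the in-plane (XY, minimum-image) centroid distance; alpha,
#' the angular position of the neighbour around the reference in its body
#' frame; and beta, the counterclockwise in-plane angle from the reference
#' orientation vector to the neighbour's. Beta is the symmetry fingerprint:
#' 180 deg for a C2 dimer, 120/240 deg for the adjacent protomers of a C3
#' trimer, independent of the assembly's global pose.
#'
#' @param ref_desc,nbr_desc valid `helix_descriptor` objects.
#' @param box box 3-vector (nm) or `NULL`.
#' @return a `pair_geometry` list: `ref`, `neighbor`, `time`, `distance`
#'   (nm), `alpha`, `beta` (degrees in `[0, 360)`).
#' @export
pair_geometry <- function(ref_desc, nbr_desc, box = NULL) {
  if (!ref_desc$valid || !nbr_desc$valid)
    stop("pair geometry requires two valid helix descriptors")
  xy <- to_reference_frame(ref_desc, nbr_desc$centroid, box)
  structure(list(ref = ref_desc$helix_id, neighbor = nbr_desc$helix_id,
                 time = ref_desc$time,
                 distance = sqrt(sum(xy^2)),
                 alpha = (atan2(xy[2], xy[1]) * 180 / pi) %% 360,
                 beta = .ccw_angle(ref_desc$orientation_xy,
                                   nbr_desc$orientation_xy)),
            class = "pair_geometry")
}

#' Classify oligomer geometry in one frame
#'
#' Applies the distance plus relative-orientation criteria to every helix
#' pair of one frame's descriptors: a C2 pair has centroid distance at
#' most `d_max` and beta within `beta_tol` of 180 deg; a C3-compatible
#' pair has beta within `beta_tol` of 120 or 240 deg at the same distance.
#' A closed trimer is a 3-cycle of C3-compatible pairs whose signed betas,
#' taken around the cycle, sum to 0 mod 360 within `3 * beta_tol`
#' (cyclic consistency: an ideal trimer contributes 120 * 3 = 360).
#' With the default 25 deg tolerance the 120/180/240 windows cannot
#' overlap, so the C2 and C3 categories are disjoint.
#'
#' @param descriptors list of `helix_descriptor` objects for one frame.
#' @param d_max first-orbit distance cut-off, nm.
#' @param beta_tol angular tolerance, degrees.
#' @param box box 3-vector (nm) or `NULL`.
#' @return a `frame_census` list: `c2_pairs` and `c3_pairs` (data.frames
#'   i, j, distance, beta with i < j), `trimers` (data.frame i, j, k),
#'   `n_c2`, `n_c3`, `n_trimers`, `time`.
#' @export
census_frame <- function(descriptors, d_max = 1.5, beta_tol = 25, box = NULL) {
  ok <- which(vapply(descriptors, `[[`, logical(1), "valid"))
  if (length(ok) < 2L) stop("census needs at least two valid descriptors")
  empty <- data.frame(i = integer(), j = integer(),
                      distance = numeric(), beta = numeric())
  ctr <- t(vapply(descriptors[ok], `[[`, numeric(3), "centroid"))
  ids <- vapply(descriptors[ok], `[[`, integer(1), "helix_id")
  time <- descriptors[[ok[1]]]$time

  pr <- which(upper.tri(matrix(0, length(ok), length(ok))), arr.ind = TRUE)
  dxy <- ctr[pr[, 2], 1:2, drop = FALSE] - ctr[pr[, 1], 1:2, drop = FALSE]
  if (!is.null(box))
    dxy <- dxy - sweep(round(sweep(dxy, 2, box[1:2], `/`)), 2, box[1:2], `*`)
  dist <- sqrt(rowSums(dxy^2))
  near <- which(dist <= d_max)

  beta_fwd <- vapply(near, function(p)
    .ccw_angle(descriptors[[ok[pr[p, 1]]]]$orientation_xy,
               descriptors[[ok[pr[p, 2]]]]$orientation_xy), numeric(1))

  tab <- data.frame(i = ids[pr[near, 1]], j = ids[pr[near, 2]],
                    distance = dist[near], beta = beta_fwd)
  is_c2 <- .circ_dist(tab$beta, 180) <= beta_tol
  is_c3 <- .circ_dist(tab$beta, 120) <= beta_tol |
           .circ_dist(tab$beta, 240) <= beta_tol
  c2 <- if (nrow(tab)) tab[is_c2, , drop = FALSE] else empty
  c3 <- if (nrow(tab)) tab[is_c3, , drop = FALSE] else empty

  trimers <- data.frame(i = integer(), j = integer(), k = integer())
  if (nrow(c3) >= 3L) {
    verts <- sort(unique(c(c3$i, c3$j)))
    adj <- matrix(FALSE, length(verts), length(verts),
                  dimnames = list(verts, verts))
    bmat <- matrix(NA_real_, length(verts), length(verts),
                   dimnames = list(verts, verts))
    for (r in seq_len(nrow(c3))) {
      a <- as.character(c3$i[r]); b <- as.character(c3$j[r])
      adj[a, b] <- adj[b, a] <- TRUE
      bmat[a, b] <- c3$beta[r]
      bmat[b, a] <- (360 - c3$beta[r]) %% 360
    }
    tri <- list()
    nv <- length(verts)
    for (a in seq_len(nv - 2)) for (b in (a + 1):(nv - 1)) {
      if (!adj[a, b]) next
      for (cc in (b + 1):nv) {
        if (!(adj[a, cc] && adj[b, cc])) next
        s <- (bmat[a, b] + bmat[b, cc] + bmat[cc, a]) %% 360
        if (.circ_dist(s, 0) <= 3 * beta_tol)
          tri[[length(tri) + 1L]] <- verts[c(a, b, cc)]
      }
    }
    if (length(tri)) {
      m <- do.call(rbind, tri)
      trimers <- data.frame(i = m[, 1], j = m[, 2], k = m[, 3])
    }
  }
  structure(list(time = time, c2_pairs = c2, c3_pairs = c3, trimers = trimers,
                 n_c2 = nrow(c2), n_c3 = nrow(c3), n_trimers = nrow(trimers)),
            class = "frame_census")
}

#' Oligomer census over a trajectory
#'
#' Runs [census_frame()] on every strided frame, anchored on the variant's
#' reference residue.
#'
#' @inheritParams radial_cloud
#' @param d_max,beta_tol see [census_frame()].
#' @return an `oligomer_census`: `frames` (list of `frame_census`),
#'   `counts` data.frame (time, n_c2, n_c3, n_trimers), `dt` (stride, ns),
#'   and the parameters used.
#' @export
oligomer_census <- function(traj, center_residue, stride_ns = 100,
                            window = NULL, numbering = c("local", "author"),
                            d_max = 1.5, beta_tol = 25, halfwidth = 1L) {
  numbering <- match.arg(numbering)
  if (numbering == "author")
    center_residue <- local_residue_index(traj, center_residue)
  idx <- window_frames(traj, window)
  times <- frame_times(traj)[idx]
  ticks <- seq(times[1], times[length(times)], by = stride_ns)
  pick <- unique(vapply(ticks, function(tk) idx[which(times >= tk - 1e-9)[1]],
                        integer(1)))
  H <- n_helices(traj)
  out <- vector("list", length(pick))
  for (w in seq_along(pick)) {
    fr <- traj$frames[[pick[w]]]
    desc <- lapply(seq_len(H), helix_descriptor, frame = fr,
                   center_residue = center_residue, halfwidth = halfwidth)
    out[[w]] <- census_frame(desc, d_max = d_max, beta_tol = beta_tol,
                             box = frame_box(fr))
  }
  counts <- data.frame(time = vapply(out, `[[`, numeric(1), "time"),
                       n_c2 = vapply(out, `[[`, integer(1), "n_c2"),
                       n_c3 = vapply(out, `[[`, integer(1), "n_c3"),
                       n_trimers = vapply(out, `[[`, integer(1), "n_trimers"))
  dt <- if (length(pick) > 1L) stats::median(diff(counts$time)) else stride_ns
  structure(list(frames = out, counts = counts, dt = dt,
                 d_max = d_max, beta_tol = beta_tol,
                 center_residue = center_residue),
            class = "oligomer_census")
}

#' @export
print.oligomer_census <- function(x, ...) {
  cat("Oligomer census over ", nrow(x$counts), " frames (dt ", x$dt, " ns; ",
      "d_max ", x$d_max, " nm, beta_tol ", x$beta_tol, " deg)\n", sep = "")
  cat(sprintf("  mean per frame: %.2f C2 pairs, %.2f C3-compatible pairs, %.2f closed trimers\n",
              mean(x$counts$n_c2), mean(x$counts$n_c3), mean(x$counts$n_trimers)))
  invisible(x)
}

.member_key <- function(v) paste(sort(v), collapse = "-")

#' Association intervals and lifetimes of oligomer member sets
#'
#' Converts the per-frame census into association records: for every
#' distinct member set (a pair for the C2/C3 categories, a triple for
#' closed trimers) an interval opens when the set first satisfies its
#' criterion and closes when it fails for more than `gap_tolerance`
#' consecutive strides. Each frame contributes one stride `dt` of
#' association time; bridged gaps count toward the bridging interval.
#'
#' @param census an `oligomer_census`.
#' @param category `"c2"`, `"c3"` or `"trimer"`.
#' @param gap_tolerance number of consecutive absent strides bridged
#'   inside one interval (default 0: strict).
#' @return an `association_records` object: `records` (list with
#'   `members`, `intervals` matrix (t_on, t_off), `accumulated`,
#'   `longest`), `summary` list (n_records, n_helices, accumulated_total,
#'   mean_interval, longest).
#' @export
association_records <- function(census, category = c("c2", "c3", "trimer"),
                                gap_tolerance = 0L) {
  category <- match.arg(category)
  dt <- census$dt
  nF <- length(census$frames)
  times <- census$counts$time
  present <- list()  # member key -> integer frame indices
  members <- list()
  for (f in seq_len(nF)) {
    fc <- census$frames[[f]]
    sets <- switch(category,
      c2 = if (nrow(fc$c2_pairs)) asplit(as.matrix(fc$c2_pairs[, c("i", "j")]), 1),
      c3 = if (nrow(fc$c3_pairs)) asplit(as.matrix(fc$c3_pairs[, c("i", "j")]), 1),
      trimer = if (nrow(fc$trimers)) asplit(as.matrix(fc$trimers), 1))
    for (s in sets) {
      k <- .member_key(s)
      if (is.null(present[[k]])) { present[[k]] <- integer(); members[[k]] <- as.integer(s) }
      present[[k]] <- c(present[[k]], f)
    }
  }
  records <- lapply(names(present), function(k) {
    fidx <- present[[k]]
    gaps <- which(diff(fidx) > gap_tolerance + 1L)
    starts <- fidx[c(1L, gaps + 1L)]
    ends <- fidx[c(gaps, length(fidx))]
    iv <- cbind(t_on = times[starts], t_off = times[ends] + dt)
    list(members = members[[k]], intervals = iv,
         accumulated = sum(iv[, 2] - iv[, 1]),
         longest = max(iv[, 2] - iv[, 1]))
  })
  acc <- vapply(records, `[[`, numeric(1), "accumulated")
  all_iv <- unlist(lapply(records, function(r) r$intervals[, 2] - r$intervals[, 1]))
  structure(list(
    category = category, records = records,
    summary = list(
      n_records = length(records),
      n_helices = length(unique(unlist(lapply(records, `[[`, "members")))),
      accumulated_total = sum(acc),
      mean_interval = if (length(all_iv)) mean(all_iv) else NA_real_,
      longest = if (length(acc)) max(vapply(records, `[[`, numeric(1), "longest")) else NA_real_)),
    class = "association_records")
}

#' @export
print.association_records <- function(x, ...) {
  s <- x$summary
  cat("Association records (", x$category, "): ", s$n_records,
      " member sets over ", s$n_helices, " helices\n", sep = "")
  if (s$n_records)
    cat(sprintf("  accumulated %.1f ns, mean interval %.1f ns, longest %.1f ns\n",
                s$accumulated_total, s$mean_interval, s$longest))
  invisible(x)
}

# density-based clustering (DBSCAN) with a cell-list neighbour search
.dbscan_xy <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  cell <- floor(sweep(xy, 2, apply(xy, 2, min)) / eps)
  key <- paste(cell[, 1], cell[, 2])
  buckets <- split(seq_len(n), key)
  cellmap <- new.env(hash = TRUE)
  for (k in names(buckets)) assign(k, buckets[[k]], envir = cellmap)
  neighbours <- function(p) {
    cands <- integer()
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cell[p, 1] + dx, cell[p, 2] + dy)
      if (exists(k, envir = cellmap, inherits = FALSE))
        cands <- c(cands, get(k, envir = cellmap))
    }
    d2 <- (xy[cands, 1] - xy[p, 1])^2 + (xy[cands, 2] - xy[p, 2])^2
    cands[d2 <= eps^2]
  }
  labels <- integer(n)        # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  for (p in seq_len(n)) {
    if (visited[p]) next
    visited[p] <- TRUE
    nb <- neighbours(p)
    if (length(nb) < min_pts) next  # noise (may be claimed as border later)
    cl <- cl + 1L
    labels[p] <- cl
    queue <- setdiff(nb, p)
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      if (!visited[q]) {
        visited[q] <- TRUE
        nbq <- neighbours(q)
        if (length(nbq) >= min_pts) queue <- c(queue, setdiff(nbq, q))
      }
      if (labels[q] == 0L) labels[q] <- cl
    }
  }
  labels
}

#' Cluster the first-orbit spots of a radial cloud
#'
#' Isolates the main spots of the innermost orbit (points closer than
#' `first_orbit` to the reference helix) by density-based clustering, and
#' characterizes each spot by its centroid, angular position alpha, mean
#' distance and the distribution of pair orientations beta carried by its
#' points. Points not assigned to any cluster, or beyond the first orbit,
#' are labelled "outside".
#'
#' @param cloud a `radial_cloud`.
#' @param first_orbit orbit radius, nm.
#' @param eps clustering neighbourhood radius, nm.
#' @param min_fraction minimum cluster size as a fraction of the in-orbit
#'   points (floor of 5 points).
#' @return a `spot_clusters` object: `clusters` (data.frame label, n, x,
#'   y, alpha, mean_distance, beta_mode), `beta_values` (list per
#'   cluster), `assignment` (per cloud point: cluster label or 0 for
#'   outside), `first_orbit`, `eps`.
#' @export
cluster_spots <- function(cloud, first_orbit = 1.5, eps = 0.25,
                          min_fraction = 0.01) {
  pts <- cloud$points
  if (is.null(pts) || !nrow(pts)) stop("empty radial cloud")
  inorb <- which(pts$distance < first_orbit)
  assignment <- integer(nrow(pts))
  if (!length(inorb)) {
    return(structure(list(clusters = data.frame(), beta_values = list(),
                          assignment = assignment, first_orbit = first_orbit,
                          eps = eps), class = "spot_clusters"))
  }
  xy <- cbind(pts$x[inorb], pts$y[inorb])
  min_pts <- max(5L, ceiling(min_fraction * length(inorb)))
  lab <- .dbscan_xy(xy, eps, min_pts)
  assignment[inorb] <- lab
  labs <- sort(unique(lab[lab > 0L]))
  beta_values <- lapply(labs, function(l) pts$beta[inorb][lab == l])
  clusters <- do.call(rbind, lapply(seq_along(labs), function(ii) {
    sel <- inorb[lab == labs[ii]]
    bv <- beta_values[[ii]]
    bmode <- if (any(!is.na(bv))) .circ_mean(bv[!is.na(bv)]) else NA_real_
    data.frame(label = labs[ii], n = length(sel),
               x = mean(pts$x[sel]), y = mean(pts$y[sel]),
               alpha = (atan2(mean(pts$y[sel]), mean(pts$x[sel])) * 180 / pi) %% 360,
               mean_distance = mean(pts$distance[sel]),
               beta_mode = bmode)
  }))
  structure(list(clusters = if (is.null(clusters)) data.frame() else clusters,
                 beta_values = beta_values, assignment = assignment,
                 first_orbit = first_orbit, eps = eps),
            class = "spot_clusters")
}

.circ_mean <- function(deg) {
  a <- deg * pi / 180
  (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
}

#' @export
print.spot_clusters <- function(x, ...) {
  cat("First-orbit spot clusters (< ", x$first_orbit, " nm, eps ",
      x$eps, " nm): ", nrow(x$clusters), " clusters, ",
      sum(x$assignment == 0L), " points outside\n", sep = "")
  if (nrow(x$clusters)) print(x$clusters, digits = 3)
  invisible(x)
}

#' Markov transition matrix over radial clusters
#'
#' Follows every (reference, neighbour) helix pair through the strided
#' frames of the cloud, assigns it the label of the spot cluster its point
#' belongs to (or "outside"), and counts transitions between consecutive
#' strides. Rows are normalized to transition probabilities; rows with no
#' outgoing counts are flagged rather than normalized.
#'
#' @param cloud a `radial_cloud` (its points carry frame tags).
#' @param clusters a `spot_clusters` fitted on the same cloud.
#' @return a `transition_matrix`: `states`, `counts` (integer matrix),
#'   `P` (row-stochastic matrix), `empty_rows` (logical).
#' @export
markov_transitions <- function(cloud, clusters) {
  pts <- cloud$points
  if (length(clusters$assignment) != nrow(pts))
    stop("cluster assignment does not match the cloud")
  labs <- if (nrow(clusters$clusters)) clusters$clusters$label else integer()
  states <- c(paste0("spot", labs), "outside")
  st <- ifelse(clusters$assignment > 0L,
               paste0("spot", clusters$assignment), "outside")
  key <- paste(pts$ref, pts$neighbor)
  times <- sort(unique(pts$time))
  if (length(times) < 2L) stop("Markov transitions need at least two strided frames")
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(states, states))
  ord <- order(key, pts$time)
  k <- key[ord]; tm <- pts$time[ord]; s <- st[ord]
  same_pair <- k[-1] == k[-length(k)]
  from <- s[-length(s)][same_pair]
  to <- s[-1][same_pair]
  for (ii in seq_along(from))
    counts[from[ii], to[ii]] <- counts[from[ii], to[ii]] + 1L
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, 1, rs)
  structure(list(states = states, counts = counts, P = P,
                 empty_rows = rs == 0),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Markov transition matrix over radial clusters (",
      length(x$states), " states)\n", sep = "")
  print(round(x$P, 3))
  if (any(x$empty_rows))
    cat("  empty rows (no outgoing transitions): ",
        paste(x$states[x$empty_rows], collapse = ", "), "\n", sep = "")
  invisible(x)
}
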