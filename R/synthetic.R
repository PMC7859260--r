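# Canonical alpha-helix CG geometry: 0.15 nm rise per residue, 100 deg
# twist, 0.23 nm helical radius for the BB bead trace.

#' Ideal alpha-helix backbone bead trace
#'
#' Places `n_residues` BB beads on a regular helix curve (axis along the
#' pose Z), centred on the axis midpoint, then applies a rigid pose.
#'
#' @param n_residues number of beads (>= 3).
#' @param rise_per_res axial rise per residue, nm.
#' @param twist_deg rotation per residue about the axis, degrees.
#' @param radius helical radius of the bead trace, nm.
#' @param rot 3 x 3 pose rotation.
#' @param shift pose translation (axis midpoint position), nm.
#' @param resno_start first author residue number.
#' @return a `helix` object.
#' @export
ideal_helix <- function(n_residues, rise_per_res = 0.15, twist_deg = 100,
                        radius = 0.23, rot = diag(3), shift = c(0, 0, 0),
                        resno_start = 1L) {
  if (n_residues < 3L) stop("an ideal helix needs at least 3 residues")
  i <- seq_len(n_residues) - 1L
  a <- i * twist_deg * pi / 180
  local <- cbind(radius * cos(a), radius * sin(a),
                 (i - (n_residues - 1) / 2) * rise_per_res)
  helix_beads(sweep(local %*% t(rot), 2, shift, `+`),
              resno = resno_start + i)
}

#' Rigid poses of an ideal Cn (or dimer-of-trimers) assembly
#'
#' Builds the member poses of an ideal symmetric assembly: `"C2"` gives
#' two poses related by a 180 deg rotation about the vertical axis through
#' the assembly centre, `"C3"` three poses related by 120 deg rotations,
#' and `"C3x2"` a dimer of trimers -- two C3 units joined through a C2
#' interface (the whole second trimer is the 180 deg rotation of the
#' first about the joint vertical axis). Adjacent members within a Cn
#' unit sit `pair_distance` apart; for `"C3x2"` the two facing members
#' across the interface do.
#'
#' @param type `"C2"`, `"C3"` or `"C3x2"`.
#' @param center assembly centre, 3-vector nm.
#' @param pair_distance adjacent-member axis distance, nm.
#' @param phase global phase rotation of the assembly about Z, degrees.
#' @return list of poses, each `list(rot, shift)`.
#' @export
place_assembly <- function(type = c("C2", "C3", "C3x2"), center = c(0, 0, 0),
                           pair_distance = 1.0, phase = 0) {
  type <- match.arg(type)
  cn_poses <- function(n, ctr, ph) {
    rr <- pair_distance / (2 * sin(pi / n))
    lapply(seq_len(n) - 1L, function(k) {
      Rk <- rot_z(ph + k * 360 / n)
      list(rot = Rk, shift = ctr + as.numeric(Rk %*% c(rr, 0, 0)))
    })
  }
  if (type == "C2") return(cn_poses(2L, center, phase))
  if (type == "C3") return(cn_poses(3L, center, phase))
  # C3x2: trimer A centred left of the joint axis with member 1 facing it
  rr3 <- pair_distance / (2 * sin(pi / 3))
  s <- rr3 + pair_distance / 2
  a_poses <- cn_poses(3L, c(-s, 0, 0), 0)
  Rg <- rot_z(180)
  b_poses <- lapply(a_poses, function(p)
    list(rot = Rg %*% p$rot, shift = as.numeric(Rg %*% p$shift)))
  Rp <- rot_z(phase)
  lapply(c(a_poses, b_poses), function(p)
    list(rot = Rp %*% p$rot, shift = center + as.numeric(Rp %*% p$shift)))
}

#' Build an ideal assembly as a list of helices
#'
#' Convenience wrapper combining [place_assembly()] and [ideal_helix()].
#'
#' @inheritParams place_assembly
#' @param n_residues residues per helix.
#' @return list of `helix` objects.
#' @export
build_assembly <- function(type = c("C2", "C3", "C3x2"), n_residues = 30L,
                           center = c(0, 0, 0), pair_distance = 1.0,
                           phase = 0) {
  lapply(place_assembly(type, center, pair_distance, phase), function(p)
    ideal_helix(n_residues, rot = p$rot, shift = p$shift))
}

#' Specification of a synthetic bundle trajectory
#'
#' Captures the full recipe of a ground-truth-labelled synthetic CG bundle
#' emulating the simulated membrane patch: `n_helices` helices (default
#' 36) evenly spaced on a square grid in the XY plane of a 25 x 25 x 10 nm
#' box, each randomly oriented about Z, with planted symmetric assemblies,
#' independent per-frame rigid-body jitter and bounded orientation noise.
#' No physical dynamics are modelled: the generator produces labelled
#' geometry for validating the analysis chain, not an MD surrogate.
#'
#' @param n_helices total helix count.
#' @param n_residues residues per helix.
#' @param box box vector, nm.
#' @param planted list of planted assemblies, each
#'   `list(type, members = NULL, phase = NULL, pair_distance = 1.0,
#'   on_off = NULL)`; `members` defaults to the next unused helix ids,
#'   `phase` to a seeded random angle, `on_off` to always-on (otherwise a
#'   list of `c(first_frame, last_frame)` 1-based inclusive intervals).
#' @param jitter_sigma per-frame rigid-body displacement SD, nm.
#' @param orientation_noise per-frame orientation noise half-range, degrees
#'   (uniform in `[-noise, +noise]`).
#' @param n_frames number of frames.
#' @param dt_ns time step between frames, ns.
#' @param seed RNG seed; the output is a deterministic function of the
#'   spec including this seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_helices = 36L, n_residues = 30L,
                           box = c(25, 25, 10), planted = list(),
                           jitter_sigma = 0, orientation_noise = 0,
                           n_frames = 61L, dt_ns = 100, seed = 1L) {
  memb <- unlist(lapply(planted, `[[`, "members"))
  if (anyDuplicated(memb))
    stop("planted assembly member ids must be disjoint")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  structure(list(n_helices = as.integer(n_helices),
                 n_residues = as.integer(n_residues), box = box,
                 planted = planted, jitter_sigma = jitter_sigma,
                 orientation_noise = orientation_noise,
                 n_frames = as.integer(n_frames), dt_ns = dt_ns,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.assembly_size <- function(type) switch(type, C2 = 2L, C3 = 3L, C3x2 = 6L)

#' Generate a ground-truth-labelled synthetic bundle trajectory
#'
#' Realizes a [synthetic_spec()]: planted assemblies occupy alternating
#' grid cells (keeping assemblies well separated), the remaining helices
#' fill the other cells with fixed random orientations, and every helix
#' receives independent per-frame jitter and orientation noise. When an
#' assembly is scheduled "off" its members are displaced radially apart so
#' that no census criterion can hold. The returned ground truth lists, per
#' frame, exactly the planted C2 pairs, C3-compatible pairs and closed
#' trimers that are "on", plus every helix's true centre and orientation
#' phase.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `trajectory` (a `bundle_trajectory`) and `truth` (a
#'   `ground_truth` list: per-frame `c2_pairs`, `c3_pairs`, `trimers`
#'   data.frames and `pose` data.frame of true helix poses).
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  H <- spec$n_helices
  g <- ceiling(sqrt(H))
  sx <- spec$box[1] / g; sy <- spec$box[2] / g
  cells <- expand.grid(cx = (seq_len(g) - 0.5) * sx,
                       cy = (seq_len(g) - 0.5) * sy)[seq_len(max(H, 1)), ]

  n_assembly <- length(spec$planted)
  if (2L * n_assembly - 1L > nrow(cells) && n_assembly > 0L)
    stop("too many planted assemblies for the grid")
  asm_cells <- seq_len(max(0L, n_assembly)) * 2L - 1L   # alternating cells
  planted <- spec$planted
  used <- integer()
  for (a in seq_along(planted)) {
    p <- planted[[a]]
    sz <- .assembly_size(p$type)
    if (is.null(p$members)) {
      p$members <- setdiff(seq_len(H), used)[seq_len(sz)]
    } else {
      p$members <- as.integer(unlist(p$members))
      if (length(p$members) != sz)
        stop("assembly ", a, " (", p$type, ") needs ", sz, " members")
    }
    if (!is.null(p$on_off))
      p$on_off <- lapply(p$on_off, function(iv) as.numeric(unlist(iv)))
    if (is.null(p$phase)) p$phase <- stats::runif(1, 0, 360)
    if (is.null(p$pair_distance)) p$pair_distance <- 1.0
    used <- c(used, p$members)
    planted[[a]] <- p
  }
  free_helices <- setdiff(seq_len(H), used)
  free_cells <- setdiff(seq_len(nrow(cells)), asm_cells)[seq_along(free_helices)]
  free_phase <- stats::runif(length(free_helices), 0, 360)

  # static base pose per helix: rot (phase) + axis position
  base_rot <- vector("list", H)
  base_pos <- matrix(0, H, 3)
  for (a in seq_along(planted)) {
    p <- planted[[a]]
    ctr <- c(cells$cx[asm_cells[a]], cells$cy[asm_cells[a]], spec$box[3] / 2)
    poses <- place_assembly(p$type, ctr, p$pair_distance, p$phase)
    for (m in seq_along(p$members)) {
      base_rot[[p$members[m]]] <- poses[[m]]$rot
      base_pos[p$members[m], ] <- poses[[m]]$shift
    }
    planted[[a]]$center <- ctr
  }
  for (k in seq_along(free_helices)) {
    h <- free_helices[k]
    base_rot[[h]] <- rot_z(free_phase[k])
    base_pos[h, ] <- c(cells$cx[free_cells[k]], cells$cy[free_cells[k]],
                       spec$box[3] / 2)
  }

  d2min <- Inf
  if (H > 1L) {
    dd <- stats::dist(base_pos[, 1:2])
    d2min <- min(dd)
    if (d2min < 0.5) {
      close_pair <- which(as.matrix(dd) < 0.5 & upper.tri(as.matrix(dd)),
                          arr.ind = TRUE)[1, ]
      stop("overlapping helix placements (< 0.5 nm): helices ",
           close_pair[1], " and ", close_pair[2])
    }
  }

  asm_on <- function(a, f) {
    oo <- planted[[a]]$on_off
    if (is.null(oo)) return(TRUE)
    any(vapply(oo, function(iv) f >= iv[1] && f <= iv[2], logical(1)))
  }

  frames <- vector("list", spec$n_frames)
  truth_frames <- vector("list", spec$n_frames)
  pose_rows <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    time <- (f - 1L) * spec$dt_ns
    pos_f <- base_pos
    # scheduled-off assemblies: scatter members radially from the centre
    for (a in seq_along(planted)) {
      if (asm_on(a, f)) next
      p <- planted[[a]]
      for (m in seq_along(p$members)) {
        h <- p$members[m]
        dir <- base_pos[h, 1:2] - p$center[1:2]
        dir <- dir / sqrt(sum(dir^2))
        # 1.25 nm outward: members move > 1.5 nm apart (criterion broken)
        # while staying clear of the neighbouring grid cells
        pos_f[h, 1:2] <- pos_f[h, 1:2] + 1.25 * dir
      }
    }
    jit <- if (spec$jitter_sigma > 0)
      matrix(stats::rnorm(H * 3, 0, spec$jitter_sigma), H, 3)
    else matrix(0, H, 3)
    onoise <- if (spec$orientation_noise > 0)
      stats::runif(H, -spec$orientation_noise, spec$orientation_noise)
    else rep(0, H)
    helices <- lapply(seq_len(H), function(h)
      ideal_helix(spec$n_residues, rot = rot_z(onoise[h]) %*% base_rot[[h]],
                  shift = pos_f[h, ] + jit[h, ]))
    frames[[f]] <- bundle_frame(helices, time = time, box = spec$box,
                                periodic = TRUE)

    c2 <- list(); c3 <- list(); tri <- list()
    for (a in seq_along(planted)) {
      if (!asm_on(a, f)) next
      p <- planted[[a]]; m <- p$members
      if (p$type == "C2") c2[[length(c2) + 1L]] <- m
      if (p$type == "C3") {
        c3 <- c(c3, list(m[1:2], m[2:3], m[c(1, 3)]))
        tri[[length(tri) + 1L]] <- m
      }
      if (p$type == "C3x2") {
        c3 <- c(c3, list(m[1:2], m[2:3], m[c(1, 3)]),
                list(m[4:5], m[5:6], m[c(4, 6)]))
        tri <- c(tri, list(m[1:3], m[4:6]))
        c2[[length(c2) + 1L]] <- m[c(1, 4)]   # facing interface members
      }
    }
    pairs_df <- function(lst) {
      if (!length(lst)) return(data.frame(i = integer(), j = integer()))
      m <- t(vapply(lst, function(v) sort(v), integer(2)))
      data.frame(i = m[, 1], j = m[, 2])
    }
    tri_df <- if (length(tri)) {
      m <- t(vapply(tri, function(v) sort(v), integer(3)))
      data.frame(i = m[, 1], j = m[, 2], k = m[, 3])
    } else data.frame(i = integer(), j = integer(), k = integer())
    truth_frames[[f]] <- list(time = time, c2_pairs = pairs_df(c2),
                              c3_pairs = pairs_df(c3), trimers = tri_df)
    ang <- vapply(seq_len(H), function(h) {
      R <- if (spec$orientation_noise > 0)
        rot_z(onoise[h]) %*% base_rot[[h]] else base_rot[[h]]
      (atan2(R[2, 1], R[1, 1]) * 180 / pi) %% 360
    }, numeric(1))
    pose_rows[[f]] <- data.frame(time = time, helix = seq_len(H),
                                 x = pos_f[, 1] + jit[, 1],
                                 y = pos_f[, 2] + jit[, 2],
                                 z = pos_f[, 3] + jit[, 3],
                                 phase = ang)
  }
  truth <- structure(list(frames = truth_frames,
                          pose = do.call(rbind, pose_rows),
                          spec = spec),
                     class = "ground_truth")
  list(trajectory = bundle_trajectory(frames, variant = "synthetic"),
       truth = truth)
}

#' Flat synthetic membrane head-bead fixture
#'
#' Two flat leaflets of lipid head beads at plus/minus half the target
#' thickness around the box midplane, species labelled DOPC:DLPC in a 7:3
#' ratio. Geometry only -- no force field, no tails.
#'
#' @param n_lipids total lipid count (even).
#' @param box box vector, nm.
#' @param thickness head-to-head bilayer thickness, nm.
#' @param z_sigma optional Gaussian roughness of the leaflets, nm.
#' @param seed RNG seed used when `z_sigma > 0`.
#' @return list: `xyz` (n_lipids x 3, nm), `species`, `leaflet` (+1/-1),
#'   `n_lipids`, `box`.
#' @export
membrane_fixture <- function(n_lipids = 1700L, box = c(25, 25, 10),
                             thickness = 3.6, z_sigma = 0, seed = 1L) {
  if (n_lipids %% 2 != 0) stop("lipid count must be even")
  per <- n_lipids / 2
  g <- ceiling(sqrt(per))
  gx <- ((seq_len(g) - 0.5) / g) * box[1]
  gy <- ((seq_len(g) - 0.5) / g) * box[2]
  grid <- expand.grid(x = gx, y = gy)[seq_len(per), ]
  z0 <- box[3] / 2
  zs <- c(rep(z0 + thickness / 2, per), rep(z0 - thickness / 2, per))
  if (z_sigma > 0) {
    set.seed(seed)
    zs <- zs + stats::rnorm(n_lipids, 0, z_sigma)
  }
  xyz <- cbind(rbind(as.matrix(grid), as.matrix(grid)), z = zs)
  n_dopc <- round(0.7 * n_lipids)
  per_dopc <- round(0.7 * per)
  species <- rep(c(rep("DOPC", per_dopc), rep("DLPC", per - per_dopc)), 2)
  list(xyz = xyz, species = species,
       leaflet = rep(c(1L, -1L), each = per),
       n_lipids = n_lipids, box = box)
}

#' Write the ground truth of a synthetic trajectory as JSON
#' @param truth a `ground_truth` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(spec = unclass(truth$spec),
         frames = lapply(truth$frames, function(fr)
           list(time = fr$time, c2_pairs = fr$c2_pairs,
                c3_pairs = fr$c3_pairs, trimers = fr$trimers))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
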