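make_desc <- function(centroid, angle_deg, id = 1L, time = 0) {
  structure(list(helix_id = as.integer(id), time = time,
                 centroid = centroid,
                 orientation_xy = c(cos(angle_deg * pi / 180),
                                    sin(angle_deg * pi / 180)),
                 valid = TRUE),
            class = "helix_descriptor")
}

test_that("pair geometry reports the symmetry fingerprint angles exactly", {
  a <- make_desc(c(0, 0, 0), 30, 1)
  expect_equal(pair_geometry(a, make_desc(c(1, 0, 0), 30, 2))$beta, 0)
  expect_equal(pair_geometry(a, make_desc(c(1, 0, 0), 210, 2))$beta, 180)

  hs <- build_assembly("C2", center = c(8, 8, 5), phase = 123)
  fr <- bundle_frame(hs)
  d <- lapply(1:2, helix_descriptor, frame = fr, center_residue = 15)
  expect_equal(pair_geometry(d[[1]], d[[2]], fr$box)$beta, 180)

  hs3 <- build_assembly("C3", center = c(8, 8, 5), phase = 289)
  fr3 <- bundle_frame(hs3)
  d3 <- lapply(1:3, helix_descriptor, frame = fr3, center_residue = 15)
  expect_equal(pair_geometry(d3[[1]], d3[[2]], fr3$box)$beta, 120)
  expect_equal(pair_geometry(d3[[1]], d3[[3]], fr3$box)$beta, 240)
  # distance and alpha basics
  pg <- pair_geometry(a, make_desc(c(0, 2, 0), 30, 2))
  expect_equal(pg$distance, 2)
  expect_error(pair_geometry(a, structure(list(valid = FALSE),
                                          class = "helix_descriptor")),
               "valid")
})

test_that("frame census classifies planted ideal assemblies", {
  # lone C2 dimer among far-apart helices
  d_c2 <- c(lapply(1:2, function(k)
    make_desc(place_assembly("C2", c(3, 3, 5))[[k]]$shift, k * 180, k)),
    list(make_desc(c(12, 12, 5), 40, 3), make_desc(c(20, 20, 5), 260, 4)))
  cf <- census_frame(d_c2, box = c(25, 25, 10))
  expect_equal(cf$n_c2, 1)
  expect_equal(cf$n_trimers, 0)
  expect_equal(unlist(cf$c2_pairs[1, c("i", "j")], use.names = FALSE), c(1L, 2L))

  # ideal C3 trimer: 3 C3-compatible pairs, 1 closed trimer, no C2
  hs <- build_assembly("C3", center = c(10, 10, 5), phase = 45)
  fr <- bundle_frame(hs)
  d3 <- lapply(1:3, helix_descriptor, frame = fr, center_residue = 15)
  cf3 <- census_frame(d3, box = fr$box)
  expect_equal(cf3$n_c3, 3)
  expect_equal(cf3$n_trimers, 1)
  expect_equal(cf3$n_c2, 0)
  expect_equal(unlist(cf3$trimers[1, ], use.names = FALSE), c(1L, 2L, 3L))

  # dimer of trimers: 2 closed trimers plus the inter-trimer C2 interface
  hs6 <- build_assembly("C3x2", center = c(12, 12, 5), phase = 31)
  fr6 <- bundle_frame(hs6)
  d6 <- lapply(1:6, helix_descriptor, frame = fr6, center_residue = 15)
  cf6 <- census_frame(d6, box = fr6$box)
  expect_equal(cf6$n_trimers, 2)
  expect_gte(cf6$n_c2, 1)

  # 36 helices on the even grid: all distances exceed 1.5 nm, empty census
  sp <- synthetic_spec(planted = list(), n_frames = 1, seed = 5)
  traj <- generate_trajectory(sp)$trajectory
  dall <- lapply(1:36, helix_descriptor, frame = traj$frames[[1]],
                 center_residue = 15)
  cfe <- census_frame(dall, box = c(25, 25, 10))
  expect_equal(cfe$n_c2 + cfe$n_c3 + cfe$n_trimers, 0)
})

test_that("census counts are invariant under global pose and helix relabelling", {
  sp <- synthetic_spec(n_helices = 12, n_residues = 20,
                       planted = list(list(type = "C2"), list(type = "C3")),
                       n_frames = 2, dt_ns = 1, seed = 8)
  traj <- generate_trajectory(sp)$trajectory
  cen <- oligomer_census(traj, 10, stride_ns = 1)

  # 90-degree rotation: a symmetry of the square periodic box
  moved <- transform_trajectory(traj, rot_z(90), c(3, -2, 0))
  cen2 <- oligomer_census(moved, 10, stride_ns = 1)
  expect_equal(cen2$counts, cen$counts)

  perm <- c(12:1)
  relab <- traj
  relab$frames <- lapply(relab$frames, function(f) { f$helices <- f$helices[perm]; f })
  cen3 <- oligomer_census(relab, 10, stride_ns = 1)
  expect_equal(cen3$counts, cen$counts)
  # member sets are the permuted originals
  orig_pairs <- cen$frames[[1]]$c2_pairs
  relab_pairs <- cen3$frames[[1]]$c2_pairs
  expect_equal(nrow(relab_pairs), nrow(orig_pairs))
  remap <- match(seq_len(12), perm)
  expect_setequal(paste(pmin(remap[orig_pairs$i], remap[orig_pairs$j]),
                        pmax(remap[orig_pairs$i], remap[orig_pairs$j])),
                  paste(relab_pairs$i, relab_pairs$j))
})

test_that("association records follow interval and gap-tolerance semantics", {
  sched <- list(list(type = "C2", on_off = list(c(1, 5), c(7, 10))))
  sp <- synthetic_spec(n_helices = 4, n_residues = 12, planted = sched,
                       n_frames = 10, dt_ns = 1, seed = 10)
  traj <- generate_trajectory(sp)$trajectory
  cen <- oligomer_census(traj, 6, stride_ns = 1)

  strict <- association_records(cen, "c2", gap_tolerance = 0)
  expect_equal(strict$summary$n_records, 1)
  iv <- strict$records[[1]]$intervals
  expect_equal(unname(iv[, "t_on"]), c(0, 6))
  expect_equal(unname(iv[, 2] - iv[, 1]), c(5, 4))
  expect_equal(strict$records[[1]]$accumulated, 9)
  expect_equal(strict$records[[1]]$longest, 5)

  bridged <- association_records(cen, "c2", gap_tolerance = 1)
  expect_equal(nrow(bridged$records[[1]]$intervals), 1)
  expect_equal(bridged$records[[1]]$accumulated, 10)

  # pair present in every frame: one interval of F * dt
  sp2 <- synthetic_spec(n_helices = 4, n_residues = 12,
                        planted = list(list(type = "C2")),
                        n_frames = 6, dt_ns = 1, seed = 11)
  cen2 <- oligomer_census(generate_trajectory(sp2)$trajectory, 6, stride_ns = 1)
  ar2 <- association_records(cen2, "c2")
  expect_equal(nrow(ar2$records[[1]]$intervals), 1)
  expect_equal(ar2$records[[1]]$accumulated, 6)
  expect_equal(ar2$summary$n_helices, 2)
})

test_that("association schedule is recovered exactly at zero noise", {
  sched <- list(
    list(type = "C2", on_off = list(c(1, 20), c(31, 50))),
    list(type = "C3", on_off = list(c(11, 40))))
  sp <- synthetic_spec(n_helices = 16, n_residues = 20, planted = sched,
                       n_frames = 50, dt_ns = 1, seed = 12)
  gen <- generate_trajectory(sp)
  cen <- oligomer_census(gen$trajectory, 10, stride_ns = 1)

  ar_c2 <- association_records(cen, "c2")
  expect_equal(ar_c2$summary$n_records, 1)
  expect_equal(unname(ar_c2$records[[1]]$intervals[, "t_on"]), c(0, 30))
  expect_equal(ar_c2$records[[1]]$accumulated, 40)

  ar_tri <- association_records(cen, "trimer")
  expect_equal(ar_tri$summary$n_records, 1)
  expect_equal(unname(ar_tri$records[[1]]$intervals[, "t_on"]), 10)
  expect_equal(ar_tri$records[[1]]$accumulated, 30)
})

test_that("spot clustering recovers planted first-orbit clusters", {
  set.seed(31)
  ctrs <- rbind(c(0.9, 0.2), c(-0.4, -0.8))
  pts <- do.call(rbind, lapply(1:2, function(k)
    cbind(ctrs[k, 1] + rnorm(500, 0, 0.05),
          ctrs[k, 2] + rnorm(500, 0, 0.05))))
  cloud <- structure(list(points = data.frame(
    time = rep(1:500, 2), ref = 1, neighbor = rep(2:3, each = 500),
    x = pts[, 1], y = pts[, 2], distance = sqrt(rowSums(pts^2)),
    alpha = (atan2(pts[, 2], pts[, 1]) * 180 / pi) %% 360,
    beta = c(rnorm(500, 180, 4) %% 360, rnorm(500, 120, 4) %% 360))),
    class = "radial_cloud")
  sc <- cluster_spots(cloud)
  expect_equal(nrow(sc$clusters), 2)
  got <- as.matrix(sc$clusters[order(sc$clusters$x), c("x", "y")])
  expect_lt(max(abs(got - ctrs[order(ctrs[, 1]), ])), 0.05)

  # beta distribution of the C2-like spot concentrates near 180
  c2row <- which.max(sc$clusters$x)
  expect_lt(abs(sc$clusters$beta_mode[c2row] - 180), 5)

  # sparse uniform scatter below the density floor: no clusters
  set.seed(32)
  u <- cbind(runif(40, -1.4, 1.4), runif(40, -1.4, 1.4))
  cloud_u <- structure(list(points = data.frame(
    time = 1:40, ref = 1, neighbor = 2, x = u[, 1], y = u[, 2],
    distance = sqrt(rowSums(u^2)), alpha = 0, beta = NA)),
    class = "radial_cloud")
  sc_u <- cluster_spots(cloud_u, eps = 0.05, min_fraction = 0.2)
  expect_equal(nrow(sc_u$clusters), 0)

  # no points inside the first orbit: empty result, not an error
  far <- structure(list(points = data.frame(
    time = 1, ref = 1, neighbor = 2, x = 4, y = 0, distance = 4,
    alpha = 0, beta = NA)), class = "radial_cloud")
  expect_equal(nrow(cluster_spots(far)$clusters), 0)
})

test_that("Markov transitions are row-stochastic and track planted dynamics", {
  # static configuration: identity on the occupied state
  pts_static <- data.frame(time = rep(1:20, each = 1), ref = 1, neighbor = 2,
                           x = rnorm(20, 1, 0.02), y = rnorm(20, 0, 0.02))
  pts_static$distance <- sqrt(pts_static$x^2 + pts_static$y^2)
  pts_static$alpha <- 0; pts_static$beta <- 180
  cl_s <- structure(list(points = pts_static), class = "radial_cloud")
  sc_s <- cluster_spots(cl_s, min_fraction = 0.1)
  tm_s <- markov_transitions(cl_s, sc_s)
  occupied <- rowSums(tm_s$counts) > 0
  expect_true(all(abs(rowSums(tm_s$P[occupied, , drop = FALSE]) - 1) < 1e-9))
  expect_equal(unname(diag(tm_s$P)[occupied]), rep(1, sum(occupied)))

  # two-state flipper alternating every stride: pure off-diagonal rows
  sites <- rbind(c(1, 0), c(-1, 0))
  flip <- sites[rep(1:2, 30), ]
  set.seed(41)
  flip <- flip + rnorm(120, 0, 0.02)
  pts_f <- data.frame(time = rep(1:60), ref = 1, neighbor = 2,
                      x = flip[, 1], y = flip[, 2],
                      distance = sqrt(rowSums(flip^2)), alpha = 0, beta = NA)
  cl_f <- structure(list(points = pts_f), class = "radial_cloud")
  sc_f <- cluster_spots(cl_f, min_fraction = 0.1)
  expect_equal(nrow(sc_f$clusters), 2)
  tm_f <- markov_transitions(cl_f, sc_f)
  spots <- grep("^spot", tm_f$states)
  expect_equal(unname(diag(tm_f$P)[spots]), c(0, 0))
  expect_true(all(abs(rowSums(tm_f$P[spots, ]) - 1) < 1e-9))

  # total transitions conserved: pairs x (strides - 1)
  expect_equal(sum(tm_f$counts), 1 * (60 - 1))
})
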