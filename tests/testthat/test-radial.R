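test_that("helix centroid is the local bead mean and guards termini", {
  h <- helix_beads(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(helix_centroid(h, 2), c(1, 0, 0))
  expect_error(helix_centroid(h, 1), "outside the helix")

  set.seed(5)
  h5 <- helix_beads(matrix(rnorm(15), 5, 3))
  expect_equal(helix_centroid(h5, 3, halfwidth = 2), colMeans(h5$xyz))

  # triplet vs quintet centroid on a regular helix: both sit within the
  # helical radius of the axis, so they differ by well under the CG bead
  # scale. Closed form: offsets R(1+2cos t)/3 and R(1+2cos t+2cos 2t)/5
  # from the axis (t = 100 deg), 0.107 nm apart at R = 0.23 nm.
  hi <- ideal_helix(15)
  d_tq <- sqrt(sum((helix_centroid(hi, 8, 1) - helix_centroid(hi, 8, 2))^2))
  expect_equal(d_tq, 0.23 * abs((1 + 2 * cos(pi * 5 / 9)) / 3 -
                                  (1 + 2 * cos(pi * 5 / 9) + 2 * cos(pi * 10 / 9)) / 5),
               tolerance = 1e-9)
  expect_lt(d_tq, 0.11)
})

test_that("orientation bisector points inward and is Z-rotation equivariant", {
  h <- ideal_helix(21)
  for (i in c(5, 11, 16)) {
    ov <- orientation_vector(h, i)
    expect_true(ov$valid)
    expect_equal(sqrt(sum(ov$xy^2)), 1)
    res_az <- ((i - 1) * 100) %% 360
    got_az <- (atan2(ov$xy[2], ov$xy[1]) * 180 / pi) %% 360
    d <- abs(got_az - (res_az + 180) %% 360)
    expect_lt(min(d, 360 - d), 5)      # radially inward within 5 degrees
  }
  # rotating the helix rotates the orientation by exactly the same angle
  hr <- helix_beads(h$xyz %*% t(rot_z(90)))
  expect_equal(orientation_vector(hr, 11)$xy,
               rot_z(90)[1:2, 1:2] %*% orientation_vector(h, 11)$xy |> as.numeric())

  # beads collinear along Z have no in-plane direction
  hz <- helix_beads(cbind(0, 0, 1:5))
  expect_false(orientation_vector(hz, 3)$valid)
  expect_error(orientation_vector(h, 1), "neighbour")
})

test_that("body-frame mapping matches an explicit rotation-matrix oracle", {
  fr <- bundle_frame(list(ideal_helix(11, shift = c(4, 4, 3))), box = c(10, 10, 6))
  ref <- helix_descriptor(fr, 1, 6)
  # neighbour along the orientation vector lands on (+1, 0)
  nbr <- ref$centroid + c(ref$orientation_xy, 0)
  expect_equal(to_reference_frame(ref, nbr, fr$box), c(1, 0), tolerance = 1e-12)

  set.seed(17)
  for (k in seq_len(1000)) {
    ctr <- runif(3, 0, 10)
    th <- runif(1, 0, 2 * pi)
    desc <- list(helix_id = 1L, time = 0, centroid = ctr,
                 orientation_xy = c(cos(th), sin(th)), valid = TRUE)
    class(desc) <- "helix_descriptor"
    nb <- runif(3, -5, 15)
    expect_equal(to_reference_frame(desc, nb, c(10, 10, 6)),
                 bf_reference_frame(ctr, desc$orientation_xy, nb, c(10, 10, 6)),
                 tolerance = 1e-9)
  }
  bad <- structure(list(valid = FALSE), class = "helix_descriptor")
  expect_error(to_reference_frame(bad, c(0, 0, 0)), "invalid")
})

test_that("body-frame coordinates are invariant under global pose changes", {
  hs <- build_assembly("C3", center = c(6, 6, 3), phase = 20)
  fr <- bundle_frame(hs, box = c(12, 12, 6))
  d <- lapply(1:3, helix_descriptor, frame = fr, center_residue = 15)
  xy0 <- to_reference_frame(d[[1]], d[[2]]$centroid, fr$box)

  R <- rot_z(137)
  hs2 <- lapply(hs, function(h) helix_beads(h$xyz %*% t(R) + matrix(rep(c(1, 2, 0), each = 30), 30)))
  fr2 <- bundle_frame(hs2, box = c(12, 12, 6))
  d2 <- lapply(1:3, helix_descriptor, frame = fr2, center_residue = 15)
  expect_equal(to_reference_frame(d2[[1]], d2[[2]]$centroid, fr2$box), xy0,
               tolerance = 1e-9)
})

test_that("C3 trimer body-frame positions are related by exact 120-degree rotations", {
  hs <- build_assembly("C3", center = c(10, 10, 5), phase = 77)
  fr <- bundle_frame(hs)
  d <- lapply(1:3, helix_descriptor, frame = fr, center_residue = 15)
  # each reference sees its two neighbours at identical body-frame spots
  spots <- lapply(1:3, function(r) {
    nb <- setdiff(1:3, r)
    lapply(nb, function(k) to_reference_frame(d[[r]], d[[k]]$centroid, fr$box))
  })
  # cyclic correspondence: from helix 2 the +120 neighbour is helix 3,
  # from helix 3 it is helix 1
  expect_equal(spots[[2]][[2]], spots[[1]][[1]], tolerance = 1e-9)
  expect_equal(spots[[2]][[1]], spots[[1]][[2]], tolerance = 1e-9)
  expect_equal(spots[[3]][[1]], spots[[1]][[1]], tolerance = 1e-9)
  expect_equal(spots[[3]][[2]], spots[[1]][[2]], tolerance = 1e-9)
})

test_that("radial cloud accumulates ordered pairs with skip accounting", {
  sp <- synthetic_spec(n_helices = 9, n_residues = 12, planted = list(),
                       n_frames = 3, dt_ns = 1, seed = 2)
  traj <- generate_trajectory(sp)$trajectory
  cl <- radial_cloud(traj, 6, stride_ns = 1)
  expect_equal(nrow(cl$points) + cl$n_skipped, 3 * 9 * 8)
  expect_true(all(cl$points$distance >= 0))
  expect_true(all(cl$points$alpha >= 0 & cl$points$alpha < 360))

  # static planted dimer: that pair's points identical across frames
  sp2 <- synthetic_spec(n_helices = 6, n_residues = 12,
                        planted = list(list(type = "C2")),
                        n_frames = 4, dt_ns = 1, seed = 4)
  traj2 <- generate_trajectory(sp2)$trajectory
  cl2 <- radial_cloud(traj2, 6, stride_ns = 1)
  p12 <- cl2$points[cl2$points$ref == 1 & cl2$points$neighbor == 2, ]
  expect_equal(nrow(p12), 4)
  expect_lt(diff(range(p12$x)), 1e-12)
  expect_lt(diff(range(p12$y)), 1e-12)
})

test_that("grid-only bundles put all first-orbit points at the grid spacing", {
  sp <- synthetic_spec(planted = list(), n_frames = 1, seed = 6)
  traj <- generate_trajectory(sp)$trajectory
  cl <- radial_cloud(traj, 15, stride_ns = 100)
  expect_equal(nrow(cl$points), 36 * 35)
  expect_gt(min(cl$points$distance), 4.0)   # nearest grid orbit 25/6 nm
})

test_that("density map integrates to its point count and peaks at planted modes", {
  # single repeated point
  cl1 <- structure(list(points = data.frame(
    time = 0, ref = 1, neighbor = 2, x = rep(0.73, 50), y = rep(-0.21, 50),
    distance = 0.76, alpha = 0, beta = 180)), class = "radial_cloud")
  m1 <- density_map(cl1, bandwidth = 0.1, grid_step = 0.05)
  expect_lt(max(abs(map_argmax(m1) - c(0.73, -0.21))), 0.0501)

  set.seed(23)
  ctrs <- rbind(c(-0.5, 0.3), c(0.5, 0.3))
  pts <- do.call(rbind, lapply(1:2, function(k)
    cbind(ctrs[k, 1] + rnorm(500, 0, 0.05), ctrs[k, 2] + rnorm(500, 0, 0.05))))
  cl2 <- structure(list(points = data.frame(
    time = 0, ref = 1, neighbor = 2, x = pts[, 1], y = pts[, 2],
    distance = sqrt(rowSums(pts^2)), alpha = 0, beta = NA)),
    class = "radial_cloud")
  m2 <- density_map(cl2, bandwidth = 0.05)
  expect_equal(m2$total_mass, m2$n_points, tolerance = 0.01)
  # both planted modes appear as local maxima within 0.05 nm
  gx <- m2$x; gy <- m2$y
  for (k in 1:2) {
    win <- m2$grid[abs(gx - ctrs[k, 1]) <= 0.15, abs(gy - ctrs[k, 2]) <= 0.15]
    ij <- arrayInd(which.max(win), dim(win))
    peak <- c(gx[abs(gx - ctrs[k, 1]) <= 0.15][ij[1]],
              gy[abs(gy - ctrs[k, 2]) <= 0.15][ij[2]])
    expect_lt(max(abs(peak - ctrs[k, ])), 0.0501)
  }
  expect_error(density_map(structure(list(points = NULL), class = "radial_cloud")),
               "empty")
})
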