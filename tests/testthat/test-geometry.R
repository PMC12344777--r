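test_that("hull volume matches closed forms for cube and tetrahedron", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  set.seed(1)
  interior <- matrix(runif(9, 0.2, 0.8), 3)
  h <- convex_hull3(rbind(cube, interior))
  expect_equal(h$volume, 1.0, tolerance = 1e-10)
  expect_setequal(h$vertices, 1:8)

  a <- 2.5   # regular tetrahedron edge a: V = a^3 / (6 sqrt(2))
  tet <- a / (2 * sqrt(2)) * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                                   c(-1, -1, 1))
  ctr <- colMeans(tet)
  pad <- rbind(ctr, 0.5 * ctr + 0.5 * tet[1, ], 0.25 * ctr + 0.75 * tet[2, ])
  h2 <- convex_hull3(rbind(tet, pad))
  expect_equal(h2$volume, a^3 / (6 * sqrt(2)), tolerance = 1e-10)
})

test_that("hull volume agrees with qhull and Monte-Carlo rejection sampling", {
  set.seed(7)
  for (rep in 1:4) {
    pts <- matrix(rnorm(33, sd = 3), 11, 3)
    h <- convex_hull3(pts)
    ref <- scipy_hull_oracle(pts, mc_samples = 1e6)
    expect_equal(h$volume, ref$volume, tolerance = 1e-8)
    expect_equal(h$volume, ref$mc_volume, tolerance = 0.01)
  }
})

test_that("point-in-hull equals the simplex-decomposition oracle exactly", {
  set.seed(11)
  for (rep in 1:6) {
    pts <- matrix(rnorm(33, sd = 4), 11, 3)
    h <- convex_hull3(pts)
    qs <- matrix(rnorm(60, sd = 4), 20, 3)
    got <- points_in_hull(h, qs)
    want <- vapply(seq_len(nrow(qs)), function(i) {
      oracle_in_hull(pts, qs[i, ])
    }, logical(1))
    expect_identical(unname(got), want)
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(convex_hull3(matrix(rnorm(9), 3, 3)), "at least 4")
  flat <- cbind(matrix(runif(20), 10, 2), 0)
  expect_error(convex_hull3(flat), "coplanar")
})

test_that("boundary waters count as inside within tolerance", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  h <- convex_hull3(cube)
  on_face <- c(0.5, 0.5, 1)          # exactly on the top face
  expect_true(points_in_hull(h, rbind(on_face)))
  expect_true(points_in_hull(h, rbind(on_face + c(0, 0, 1e-10))))
  expect_false(points_in_hull(h, rbind(on_face + c(0, 0, 1e-6))))
})

test_that("cage volume is rigid-motion invariant and scales as s^3", {
  gen <- generate_trajectory(generator_params(n_frames = 1,
                                              noise_sigma = 0.2), seed = 21)
  fr <- trajectory_frame(gen$trajectory, 1)
  pk <- pocket_specs(gen$topology)[["b"]]
  v0 <- pocket_cage(fr, pk)$volume
  set.seed(5)
  rot <- random_rotation()
  fr2 <- fr
  fr2$xyz <- sweep(fr$xyz %*% t(rot), 2, c(11, -7, 3), "+")
  expect_equal(pocket_cage(fr2, pk)$volume, v0, tolerance = 1e-8)
  for (s in c(0.5, 2)) {
    frs <- fr
    frs$xyz <- fr$xyz * s
    expect_equal(pocket_cage(frs, pk)$volume, s^3 * v0, tolerance = 1e-8)
  }
})

test_that("water counting inside the pocket cage is exact", {
  gen <- generate_trajectory(generator_params(n_frames = 1,
                                              noise_sigma = 0), seed = 2)
  fr <- trajectory_frame(gen$trajectory, 1)
  pk <- pocket_specs(gen$topology)[["a"]]
  cage <- pocket_cage(fr, pk)
  # against the oracle on the actual water oxygens
  ox <- which(fr$atoms$role == "water" & fr$atoms$elem == "O")
  cage_pts <- fr$xyz[c(pk$ca_principal, pk$ca_complementary), ]
  want <- sum(vapply(ox, function(i) oracle_in_hull(cage_pts, fr$xyz[i, ]),
                     logical(1)))
  expect_equal(count_waters_in_cage(fr, cage), want)
  # a frame with all waters far away counts zero
  far <- fr
  wat <- fr$atoms$role == "water"
  far$xyz[wat, ] <- far$xyz[wat, ] + 500
  expect_equal(count_waters_in_cage(far, cage), 0L)
})

test_that("Loop C angle reproduces closed-form geometries", {
  gen <- generate_trajectory(generator_params(n_frames = 1,
                                              noise_sigma = 0), seed = 2)
  fr <- trajectory_frame(gen$trajectory, 1)
  pk <- pocket_specs(gen$topology)[["a"]]
  # orthogonal rays: C=(1,0,0), O=origin, G=(0,1,0), pairs split about each
  fr90 <- fr
  fr90$xyz[pk$ca_apex, ] <- rbind(c(1, 0, 0.3), c(1, 0, -0.3))
  fr90$xyz[pk$ca_hinge, ] <- rbind(c(0, 0, 0.2), c(0, 0, -0.2))
  fr90$xyz[pk$ca_reference, ] <- rbind(c(0, 1, 0.1), c(0, 1, -0.1))
  expect_equal(loopc_angle(fr90, pk), 90)
  # collinear with the hinge between: straight angle
  fr180 <- fr90
  fr180$xyz[pk$ca_apex, ] <- rbind(c(2, 0, 0), c(2, 0, 0))
  fr180$xyz[pk$ca_reference, ] <- rbind(c(-3, 0, 0), c(-3, 0, 0))
  expect_equal(loopc_angle(fr180, pk), 180)
  # coincident centroids are an error
  frbad <- fr90
  frbad$xyz[pk$ca_apex, ] <- fr90$xyz[pk$ca_hinge, ]
  expect_error(loopc_angle(frbad, pk), "coincident")
})

test_that("Loop C angle equals the arccos formula and is pair-symmetric", {
  gen <- generate_trajectory(generator_params(n_frames = 1,
                                              noise_sigma = 0), seed = 2)
  fr <- trajectory_frame(gen$trajectory, 1)
  pk <- pocket_specs(gen$topology)[["a"]]
  set.seed(33)
  for (rep in 1:20) {
    f <- fr
    f$xyz[pk$ca_apex, ] <- matrix(rnorm(6, sd = 5), 2)
    f$xyz[pk$ca_hinge, ] <- matrix(rnorm(6, sd = 5), 2)
    f$xyz[pk$ca_reference, ] <- matrix(rnorm(6, sd = 5), 2)
    C <- colMeans(f$xyz[pk$ca_apex, ]); O <- colMeans(f$xyz[pk$ca_hinge, ])
    G <- colMeans(f$xyz[pk$ca_reference, ])
    u <- C - O; v <- G - O
    want <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(loopc_angle(f, pk), want, tolerance = 1e-10)
    # swapping the residues within a pair leaves the angle unchanged
    f2 <- f
    f2$xyz[pk$ca_apex, ] <- f$xyz[rev(pk$ca_apex), ]
    f2$xyz[pk$ca_hinge, ] <- f$xyz[rev(pk$ca_hinge), ]
    expect_equal(loopc_angle(f2, pk), want, tolerance = 1e-10)
  }
})

test_that("pocket time series track constant schedules exactly", {
  p <- generator_params(n_frames = 8, noise_sigma = 0,
                        water_counts = c(1L, 1L, 1L, 1L, 1L),
                        bridge_rates = c(GLU173 = 0, SER174 = 0))
  gen <- generate_trajectory(p, seed = 3)
  ts <- pocket_timeseries(gen$trajectory, pocket_specs(gen$topology)[["d"]])
  expect_equal(ts$summary$water_mean, 1.0)
  expect_equal(ts$summary$water_sd, 0)
  expect_equal(nrow(ts$series), 8L)
  # display offset applies to reporting only, never to stored data
  ts2 <- pocket_timeseries(gen$trajectory,
                           pocket_specs(gen$topology)[["d"]],
                           display_offset = TRUE)
  expect_equal(ts2$summary$water_mean, 1.0)
  expect_equal(ts2$summary$water_mean_display, 6.0)
  expect_identical(ts2$series$water_count, ts$series$water_count)
})
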