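test_that("channel axis recovers the symmetry axis and follows rotations", {
  gen <- generate_trajectory(generator_params(n_frames = 1, noise_sigma = 0,
                                              loopc_phase = rep(0, 5),
                                              pushpull_amplitude = 0),
                             seed = 1)
  fr <- trajectory_frame(gen$trajectory, 1)
  topo <- gen$topology
  ax <- channel_axis(fr, topo)
  expect_equal(abs(sum(ax * c(0, 0, 1))), 1, tolerance = 1e-6)
  expect_gt(ax[3], 0)   # oriented from the restrained tail upward
  # rotating the frame rotates the axis accordingly
  set.seed(2)
  rot <- random_rotation()
  fr2 <- fr
  fr2$xyz <- fr$xyz %*% t(rot)
  ax2 <- channel_axis(fr2, topo)
  expect_equal(abs(sum(ax2 * (rot %*% ax))), 1, tolerance = 1e-6)
  # translation leaves it untouched
  fr3 <- fr
  fr3$xyz <- sweep(fr$xyz, 2, c(100, -40, 7), "+")
  expect_equal(channel_axis(fr3, topo), ax, tolerance = 1e-9)
})

test_that("backbone RMSD vanishes for identity and rigid copies, scales with noise", {
  gen <- generate_trajectory(generator_params(n_frames = 2,
                                              noise_sigma = 0), seed = 1)
  traj <- gen$trajectory
  topo <- gen$topology
  # identical frames: RMSD 0
  traj0 <- traj
  traj0$coords[, , 2] <- traj0$coords[, , 1]
  r <- backbone_rmsd(traj0, 0, topo)
  expect_equal(r, c(0, 0), tolerance = 1e-8)
  # rigidly moved copy superposes back to zero
  set.seed(3)
  rot <- random_rotation()
  trajr <- traj0
  trajr$coords[, , 2] <- sweep(traj0$coords[, , 1] %*% t(rot), 2,
                               c(20, 5, -9), "+")
  expect_equal(backbone_rmsd(trajr, 0, topo)[2], 0, tolerance = 1e-6)
  # Gaussian noise sigma per coordinate on many atoms: RMSD ~ sigma * sqrt(3)
  sigma <- 0.3
  n <- 1000L
  atoms <- data.frame(eleno = 1:n, elety = "CA", resid = "GLY",
                      resno = 1:n, chain = "A", elem = "C", role = "protein")
  set.seed(8)
  base <- matrix(rnorm(3 * n, sd = 10), n, 3)
  co <- array(NA_real_, c(n, 3, 2))
  co[, , 1] <- base
  co[, , 2] <- base + matrix(rnorm(3 * n, sd = sigma), n, 3)
  big <- pp_trajectory(atoms, co)
  topo1 <- topo; topo1$chains <- c("A", "B", "C", "D", "E")
  r2 <- backbone_rmsd(big, "A", topo1)
  expect_equal(r2[2], sigma * sqrt(3), tolerance = 0.05)
})

test_that("loop RMSF is zero for static input and localises injected jitter", {
  gen <- generate_trajectory(generator_params(
    n_frames = 40, noise_sigma = 0, loopc_amplitude = rep(0, 5),
    pushpull_amplitude = 0), seed = 1)
  traj <- gen$trajectory
  topo <- gen$topology
  r0 <- loop_rmsf(traj, 0, topo)
  expect_true(all(r0$rmsf < 1e-8))
  # jitter only Loop B residues of chain A
  at <- traj$atoms
  idx <- which(at$chain == "A" & at$elety == "CA" &
                 at$resno >= 173 & at$resno <= 176)
  sigma <- 0.25
  set.seed(12)
  traj2 <- traj
  for (k in seq_len(n_frames(traj))) {
    traj2$coords[idx, , k] <- traj2$coords[idx, , k] +
      matrix(rnorm(3 * length(idx), sd = sigma), length(idx), 3)
  }
  r1 <- loop_rmsf(traj2, 0, topo)
  loopb <- r1$rmsf[r1$loop %in% "B"]
  others <- r1$rmsf[!r1$loop %in% "B" | is.na(r1$loop)]
  expect_equal(mean(loopb), sigma * sqrt(3), tolerance = 0.25)
  expect_lt(max(others), 0.5 * min(loopb))
})

test_that("empty pockets show larger Loop C RMSF than bound pockets", {
  occ <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  gen <- generate_trajectory(generator_params(n_frames = 60, occupancy = occ,
                                              noise_sigma = 0.1), seed = 6)
  loopc_rmsf <- vapply(0:4, function(s) {
    r <- loop_rmsf(gen$trajectory, s, gen$topology)
    mean(r$rmsf[r$resno %in% c(219, 220)])
  }, numeric(1))
  expect_gt(min(loopc_rmsf[!occ]), max(loopc_rmsf[occ]))
})

test_that("contact maps equal brute-force thresholding and handle pinned pairs", {
  gen <- generate_trajectory(generator_params(n_frames = 10,
                                              noise_sigma = 0.3), seed = 4)
  traj <- gen$trajectory
  pk <- pocket_specs(gen$topology)[["c"]]
  cm <- contact_map(traj, pk)
  at <- traj$atoms
  ip <- which(at$role == "protein" & at$chain == pk$principal_chain &
                at$elety == "CA")
  ic <- which(at$role == "protein" & at$chain == pk$complementary_chain &
                at$elety == "CA")
  want <- oracle_contact_map(traj, ip, ic, cutoff = 11)
  expect_equal(unname(unclass(cm))[seq_along(ip), ], want)
  expect_true(all(cm >= 0 & cm <= 1))

  # two CAs pinned at fixed distances across all frames
  atoms <- data.frame(eleno = 1:2, elety = "CA", resid = "GLY",
                      resno = c(1L, 1L), chain = c("A", "B"), elem = "C",
                      role = "protein")
  co <- array(0, c(2, 3, 5))
  co[2, 1, ] <- 10
  tpin <- pp_trajectory(atoms, co)
  pk2 <- pk; pk2$principal_chain <- "A"; pk2$complementary_chain <- "B"
  expect_equal(as.numeric(contact_map(tpin, pk2)), 1.0)
  co[2, 1, ] <- 12
  tpin2 <- pp_trajectory(atoms, co)
  expect_equal(as.numeric(contact_map(tpin2, pk2)), 0.0)
})

test_that("C5-symmetric noise-free pockets give identical planar distances", {
  gen <- generate_trajectory(generator_params(
    n_frames = 3, noise_sigma = 0, contraction = rep(0, 5),
    loopc_phase = rep(0, 5), pushpull_amplitude = 0), seed = 1)
  res <- pocket_com_distances(gen$trajectory, gen$topology)
  expect_equal(diff(range(res$intrapocket$mean)), 0, tolerance = 1e-9)
  expect_equal(diff(range(res$interpocket$mean)), 0, tolerance = 1e-9)
  expect_identical(res$interpocket$label,
                   c("e-a", "a-b", "b-c", "c-d", "d-e"))
})

test_that("a scripted contraction shifts the intrapocket mean by its offset", {
  contr <- c(0, 0, 1, 0, 0)
  gen <- generate_trajectory(generator_params(
    n_frames = 300, occupancy = rep(FALSE, 5), contraction = contr,
    noise_sigma = 0.2), seed = 17)
  res <- pocket_com_distances(gen$trajectory, gen$topology)
  d <- res$intrapocket
  diffs <- d$mean[d$pocket == "a"] - d$mean[d$pocket == "c"]
  se <- sqrt(d$sd[d$pocket == "a"]^2 + d$sd[d$pocket == "c"]^2) /
    sqrt(n_frames(gen$trajectory))
  expect_lt(abs(diffs - 1), 3 * se)
})

test_that("between-means projection mode returns a single distance set", {
  gen <- generate_trajectory(generator_params(n_frames = 5,
                                              noise_sigma = 0.1), seed = 2)
  res <- pocket_com_distances(gen$trajectory, gen$topology,
                              between_means = TRUE)
  expect_equal(nrow(res$intrapocket), 5L)
  expect_true(all(is.na(res$intrapocket$sd)))
})

test_that("Loop C correlation behaves like a Pearson coefficient", {
  x <- sin(1:100)
  expect_equal(loopc_correlation(x, x), 1.0)
  expect_equal(loopc_correlation(x, -x), -1.0)
  expect_error(loopc_correlation(x, rep(1, 100)), "zero-variance")
  expect_error(loopc_correlation(x, x[1:50]), "equal length")
  # bivariate normal with rho = 0.5
  set.seed(10)
  n <- 1e4
  a <- rnorm(n)
  b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  expect_equal(loopc_correlation(a, b), 0.5, tolerance = 0.03)
})

test_that("push-pull correlation rises with the scripted coupling", {
  rs <- vapply(c(0, 0.5, 1), function(cc) {
    gen <- generate_trajectory(generator_params(
      n_frames = 300, pushpull_coupling = cc, noise_sigma = 0.1), seed = 23)
    mean(pushpull_analysis(gen$trajectory, gen$topology)$correlation)
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_lt(abs(rs[1]), 3 / sqrt(300))   # independent loops decorrelate
  expect_gt(rs[3], 0.9)
})

test_that("push-pull on a rigid static structure reports undefined correlation", {
  gen <- generate_trajectory(generator_params(
    n_frames = 4, noise_sigma = 0, pushpull_amplitude = 0,
    loopc_amplitude = rep(0, 5)), seed = 1)
  expect_warning(res <- pushpull_analysis(gen$trajectory, gen$topology),
                 "undefined")
  expect_true(all(is.na(res$correlation)))
})

test_that("conserved-pair occurrences follow engineered geometry", {
  gen <- generate_trajectory(generator_params(
    n_frames = 10, noise_sigma = 0,
    conserved_rates = c("GLU119-ARG147" = 1, "LYS49-ASP96" = 0,
                        "ASN219-ASN58" = 0.5, "THR220-ARG135" = 0,
                        "ASN219-LYS189" = 0)), seed = 2)
  occ <- conserved_pair_hbonds(gen$trajectory, gen$topology)
  p100 <- occ$occurrence_pct[occ$pair == "GLU119-ARG147"]
  p0 <- occ$occurrence_pct[occ$pair == "LYS49-ASP96"]
  expect_true(all(p100 == 100))
  expect_true(all(p0 == 0))
  led <- gen$ledger
  for (p in 1:5) {
    want <- 100 * mean(led$events[, p, "cons.ASN219-ASN58"])
    got <- occ$occurrence_pct[occ$pair == "ASN219-ASN58" &
                                occ$pocket == letters[p]]
    expect_equal(got, want)
  }
})
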