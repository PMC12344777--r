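# frame builder for hand-placed atoms
mini_frame <- function(names_, elems, roles, xyz, resno = NULL,
                       chain = "A", resid = "RES") {
  n <- length(names_)
  atoms <- data.frame(
    eleno = seq_len(n), elety = names_, resid = rep_len(resid, n),
    resno = resno %||% seq_len(n), chain = rep_len(chain, n),
    elem = elems, role = rep_len(roles, n)
  )
  pp_frame(atoms, xyz)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("hydrogen-bond detector honours the distance and angle cutoffs", {
  # collinear N-H...O at 2.9 A: one bond
  fr <- mini_frame(c("N", "H", "O"), c("N", "H", "O"), "protein",
                   rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0)),
                   resno = c(1, 1, 2))
  hb <- detect_hbonds(fr)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9)
  expect_equal(hb$angle, 180)
  # same at 3.1 A: distance fails
  fr2 <- mini_frame(c("N", "H", "O"), c("N", "H", "O"), "protein",
                    rbind(c(0, 0, 0), c(1, 0, 0), c(3.1, 0, 0)),
                    resno = c(1, 1, 2))
  expect_equal(nrow(detect_hbonds(fr2)), 0L)
  # bent geometry below 135 degrees fails
  fr3 <- mini_frame(c("N", "H", "O"), c("N", "H", "O"), "protein",
                    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2.4, 0)),
                    resno = c(1, 1, 2))
  expect_equal(nrow(detect_hbonds(fr3)), 0L)
})

test_that("hydrogen-bond detector matches the all-pairs oracle on random frames", {
  for (s in 1:25) {
    fr <- random_frame(n_groups = 15, seed = s)
    got <- detect_hbonds(fr)
    want <- oracle_hbonds(fr)
    key <- function(d) sort(paste(d$donor, d$h, d$acceptor))
    expect_identical(key(got), key(want))
  }
})

test_that("donors without hydrogens are skipped with a warning", {
  fr <- mini_frame(c("N", "O"), c("N", "O"), "protein",
                   rbind(c(0, 0, 0), c(2.9, 0, 0)), resno = c(1, 2))
  expect_warning(hb <- detect_hbonds(fr, donor_heavy = 1L), "skipped")
  expect_equal(nrow(hb), 0L)
})

test_that("cation-pi detector applies the axial angle window", {
  hexagon <- t(vapply(0:5, function(k) {
    1.39 * c(cos(k * pi / 3), sin(k * pi / 3), 0)
  }, numeric(3)))
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  build <- function(cation_pos) {
    mini_frame(c(ring_names, "N"), c(rep("C", 6), "N"),
               c(rep("protein", 6), "ligand"),
               rbind(hexagon, cation_pos),
               resno = c(rep(1L, 6), 2L), resid = c(rep("PHE", 6), "LIG"))
  }
  # 5 A along the normal: angle 0 -> interaction
  cp <- detect_cation_pi(build(c(0, 0, 5)))
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$angle, 0, tolerance = 1e-10)
  # in-plane at 5 A: angle 90 -> none
  expect_equal(nrow(detect_cation_pi(build(c(5, 0, 0)))), 0L)
  # 6.5 A along the normal: distance fails
  expect_equal(nrow(detect_cation_pi(build(c(0, 0, 6.5)))), 0L)
  # collinear "ring" is degenerate
  line <- cbind(1:6, 0, 0)
  fr_bad <- mini_frame(c(ring_names, "N"), c(rep("C", 6), "N"),
                       c(rep("protein", 6), "ligand"),
                       rbind(line, c(0, 0, 5)),
                       resno = c(rep(1L, 6), 2L),
                       resid = c(rep("PHE", 6), "LIG"))
  expect_error(detect_cation_pi(fr_bad), "degenerate")
})

test_that("cation-pi detector matches the direct-formula oracle for random placements", {
  hexagon <- t(vapply(0:5, function(k) {
    1.39 * c(cos(k * pi / 3), sin(k * pi / 3), 0)
  }, numeric(3)))
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  set.seed(42)
  hits_got <- hits_want <- logical(200)
  for (i in 1:200) {
    pos <- runif(3, -7, 7)
    fr <- mini_frame(c(ring_names, "N"), c(rep("C", 6), "N"),
                     c(rep("protein", 6), "ligand"),
                     rbind(hexagon, pos),
                     resno = c(rep(1L, 6), 2L),
                     resid = c(rep("PHE", 6), "LIG"))
    rings <- aromatic_rings(fr)
    hits_got[i] <- nrow(detect_cation_pi(fr)) == 1L
    hits_want[i] <- nrow(oracle_cation_pi(fr, cations = 7L, rings)) == 1L
  }
  expect_identical(hits_got, hits_want)
  expect_gt(sum(hits_got), 0)     # the sweep exercises both outcomes
  expect_lt(sum(hits_got), 200)
})

test_that("water bridges require simultaneous bonds to ligand and residue", {
  # ligand O ... water (donor both ways) ... residue O
  build <- function(res_x) {
    mini_frame(
      c("O1", "OH2", "H1", "H2", "OE1"),
      c("O", "O", "H", "H", "O"),
      c("ligand", "water", "water", "water", "protein"),
      rbind(c(0, 0, 0), c(2.8, 0, 0), c(1.8, 0, 0), c(3.8, 0, 0),
            c(res_x, 0, 0)),
      resno = c(1L, 2L, 2L, 2L, 3L),
      resid = c("LIG", "HOH", "HOH", "HOH", "GLU")
    )
  }
  wb <- detect_water_bridges(build(5.6))
  expect_equal(nrow(wb), 1L)
  expect_equal(wb$residue_resid, "GLU")
  # residue too far: water bonded to ligand only -> no bridge
  expect_equal(nrow(detect_water_bridges(build(9))), 0L)
})

test_that("water-bridge detection equals the composed hydrogen-bond oracle", {
  gen <- generate_trajectory(generator_params(n_frames = 30,
                                              noise_sigma = 0.2), seed = 9)
  at <- gen$trajectory$atoms
  for (k in seq(1, 30, by = 3)) {
    fr <- trajectory_frame(gen$trajectory, k)
    hb <- oracle_hbonds(fr)
    for (p in 1:5) {
      li <- which(at$role == "ligand" & at$resno == p)
      got <- detect_water_bridges(fr, ligand = li)
      # compose: waters bonded to this ligand AND to some protein residue
      wat_key <- function(i) paste(at$chain[i], at$resno[i], sep = ":")
      lig_w <- res_w <- character(0)
      pair <- list()
      for (r in seq_len(nrow(hb))) {
        d <- hb$donor[r]; a <- hb$acceptor[r]
        if (at$role[d] == "water" && a %in% li) lig_w <- c(lig_w, wat_key(d))
        if (at$role[a] == "water" && d %in% li) lig_w <- c(lig_w, wat_key(a))
        if (at$role[d] == "water" && at$role[a] == "protein") {
          pair[[length(pair) + 1L]] <- c(wat_key(d),
                                         paste(at$chain[a], at$resno[a],
                                               at$resid[a], sep = ":"))
        }
        if (at$role[a] == "water" && at$role[d] == "protein") {
          pair[[length(pair) + 1L]] <- c(wat_key(a),
                                         paste(at$chain[d], at$resno[d],
                                               at$resid[d], sep = ":"))
        }
      }
      want <- unique(do.call(rbind, c(pair, list(matrix(character(0), 0, 2)))))
      want <- want[want[, 1] %in% unique(lig_w), , drop = FALSE]
      expect_setequal(paste(got$water, got$residue),
                      unique(paste(want[, 1], want[, 2])))
    }
  }
})

test_that("occurrence summaries handle saturation, emptiness and multiplicity", {
  rec <- data.frame(kind = "hbond", frame = 0:9, pocket = "a",
                    residue_resid = "ARG", residue_resno = 81L)
  s <- occurrence_summary(rec, n_frames = 10)
  expect_equal(s$residues$occurrence_pct, 100)
  expect_equal(s$totals$mean_count, 1)
  expect_equal(s$totals$sd_count, 0)

  s0 <- occurrence_summary(NULL, n_frames = 10)
  expect_equal(nrow(s0$residues), 0L)

  # two simultaneous bonds in half the frames: occurrence 50, mean 1
  rec2 <- data.frame(kind = "hbond", frame = rep(0:4, each = 2),
                     pocket = "a", residue_resid = "ARG",
                     residue_resno = 81L)
  s2 <- occurrence_summary(rec2, n_frames = 10)
  expect_equal(s2$residues$occurrence_pct, 50)
  expect_equal(s2$totals$mean_count, 1)
  # idempotent under duplicate-free union
  expect_identical(occurrence_summary(rec2, 10), occurrence_summary(rec2, 10))
})

test_that("detectors are invariant under rigid motion", {
  gen <- generate_trajectory(generator_params(n_frames = 2,
                                              noise_sigma = 0.2), seed = 13)
  fr <- trajectory_frame(gen$trajectory, 1)
  set.seed(99)
  for (rep in 1:3) {
    rot <- random_rotation()
    trans <- runif(3, -50, 50)
    fr2 <- fr
    fr2$xyz <- sweep(fr$xyz %*% t(rot), 2, trans, "+")
    hb1 <- detect_hbonds(fr); hb2 <- detect_hbonds(fr2)
    expect_identical(hb1[c("donor", "h", "acceptor")],
                     hb2[c("donor", "h", "acceptor")])
    expect_equal(hb2$distance, hb1$distance, tolerance = 1e-8)
    expect_equal(hb2$angle, hb1$angle, tolerance = 1e-8)
    cp1 <- detect_cation_pi(fr); cp2 <- detect_cation_pi(fr2)
    expect_identical(cp1[c("cation", "ring")], cp2[c("cation", "ring")])
    expect_equal(cp2$distance, cp1$distance, tolerance = 1e-8)
  }
})

test_that("intersubunit totals count engineered interfacial bonds", {
  gen <- generate_trajectory(
    generator_params(n_frames = 6, noise_sigma = 0,
                     conserved_rates = c("GLU119-ARG147" = 1, "LYS49-ASP96" = 0,
                                         "ASN219-ASN58" = 0,
                                         "THR220-ARG135" = 0,
                                         "ASN219-LYS189" = 0),
                     hbond_rates = c(ARG81 = 0), bridge_rates = c(GLU173 = 0),
                     cationpi_rates = c(PHE175 = 0)),
    seed = 1)
  res <- intersubunit_hbond_total(gen$trajectory, gen$topology)
  expect_equal(res$total$mean, 5)  # one engineered bond per interface
  expect_equal(res$total$sd, 0)
  expect_equal(nrow(res$per_interface), 5L)
  expect_true(all(res$per_interface$mean_count == 1))
})
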