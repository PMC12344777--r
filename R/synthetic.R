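# C5 pseudo-pentamer generator with exact ground truth for every
# descriptor. Subunits are minimal residue scaffolds, not real protein
# geometry: the descriptors are purely geometric, so the generator scripts
# geometry directly and records what it scripted in a ledger.
#
# Layout (per pocket p = 0..4, azimuth 72 p + 36 degrees, local basis
# r = radial, t = tangential, z = channel axis):
#   pocket centre P at ring_radius * r + 10 z
#   principal CA cluster centre  C_P = P - (width/2) t   (7 binding residues)
#   complementary cluster centre C_C = P + (width/2) t   (4 binding residues)
#   ligand at P - 2.5 z; scheduled interior waters at P + 2.5 z
#   Loop C hinge centroid O = C_P + 8 z; reference centroid G = C_C + 8 z;
#   apex centroid C = O + 8 (cos(angle) t + sin(angle) z), so the measured
#   hinge-vertex angle equals the scripted angle exactly.
# Bernoulli-scripted interaction satellites ride rigidly with the thermal
# noise of their ligand anchor atom, so programmed rates stay exact under
# noise; every other atom gets independent isotropic Gaussian noise.

#' Parameters of the synthetic pentamer generator
#'
#' Defaults emulate the study conditions of a partially liganded glycine
#' receptor ECD: bound pockets are contracted by 0.8 angstrom, keep Loop C
#' capped (mean angle 24 deg, amplitude 2) and draw their interior water
#' from the scripted water bridges (~1.4 waters on average at the default
#' bridge rates); empty pockets hold 7 scheduled waters and swing Loop C
#' open (mean 33 deg, amplitude 4). Loop C swings carry a per-pocket phase
#' offset (72 deg steps around the ring by default) so that adjacent-pocket
#' angle fluctuations are only weakly correlated. Interaction rates follow
#' the magnitudes typical of bound pockets (hydrogen bonds ~0.5-0.93, water
#' bridges ~0.7, cation-pi 0.4-0.98, conserved interfacial pairs 0.5-0.9).
#'
#' @param n_frames number of frames (>= 1).
#' @param occupancy logical length-5 ligand occupancy of pockets a-e.
#' @param ring_radius pentamer ring radius, angstrom.
#' @param base_width uncontracted intrapocket centroid separation, angstrom.
#' @param contraction length-5 pocket contraction, angstrom; default 0.8 for
#'   occupied pockets, 0 for empty.
#' @param water_counts length-5 integer scheduled interior water counts, or
#'   an `n_frames` x 5 schedule matrix; default 0 (bound; bridge waters
#'   supply the hydration) / 7 (empty). Active bridge waters sit inside the
#'   cage and are included in the ledger's water count.
#' @param loopc_mean,loopc_amplitude length-5 Loop C angle schedule (deg);
#'   defaults 24/33 and 2/4 for bound/empty pockets.
#' @param loopc_period sinusoid period of the Loop C swing, frames.
#' @param loopc_phase length-5 phase offsets (radians) of the per-pocket
#'   swing; default `2 * pi * (0:4) / 5`.
#' @param hbond_rates named per-residue Bernoulli rates for scripted direct
#'   ligand hydrogen bonds (occupied pockets only).
#' @param bridge_rates named rates for scripted water-bridged interactions.
#' @param cationpi_rates named rates for scripted cation-pi interactions.
#' @param conserved_rates named rates for the conserved interfacial
#'   hydrogen-bond pairs (all pockets).
#' @param pushpull_amplitude scripted Loop B'/F' displacement amplitude,
#'   angstrom.
#' @param pushpull_coupling coupling coefficient c in \[0, 1\] between the
#'   Loop B' and Loop F' displacements.
#' @param noise_sigma isotropic thermal noise per coordinate, angstrom.
#' @param n_bulk_waters bulk waters parked far outside every pocket.
#' @return a `pp_generator_params` list.
#' @export
generator_params <- function(n_frames = 500L,
                             occupancy = rep(TRUE, 5),
                             ring_radius = 22,
                             base_width = 13.4,
                             contraction = NULL,
                             water_counts = NULL,
                             loopc_mean = NULL,
                             loopc_amplitude = NULL,
                             loopc_period = 100L,
                             loopc_phase = 2 * pi * (0:4) / 5,
                             hbond_rates = c(ARG81 = 0.93, SER145 = 0.93,
                                             THR220 = 0.80, PHE175 = 0.50),
                             bridge_rates = c(GLU173 = 0.70, SER174 = 0.70),
                             cationpi_rates = c(PHE175 = 0.98, TYR218 = 0.50,
                                                PHE223 = 0.40),
                             conserved_rates = c("GLU119-ARG147" = 0.90,
                                                 "LYS49-ASP96" = 0.70,
                                                 "ASN219-ASN58" = 0.80,
                                                 "THR220-ARG135" = 0.60,
                                                 "ASN219-LYS189" = 0.50),
                             pushpull_amplitude = 0.7,
                             pushpull_coupling = 0.5,
                             noise_sigma = 0.2,
                             n_bulk_waters = 10L) {
  stopifnot(n_frames >= 1L, length(occupancy) == 5L, is.logical(occupancy),
            noise_sigma >= 0, pushpull_coupling >= 0, pushpull_coupling <= 1,
            all(c(hbond_rates, bridge_rates, cationpi_rates,
                  conserved_rates) >= 0),
            all(c(hbond_rates, bridge_rates, cationpi_rates,
                  conserved_rates) <= 1))
  contraction <- contraction %||% ifelse(occupancy, 0.8, 0)
  water_counts <- water_counts %||% ifelse(occupancy, 0L, 7L)
  loopc_mean <- loopc_mean %||% ifelse(occupancy, 24, 33)
  loopc_amplitude <- loopc_amplitude %||% ifelse(occupancy, 2, 4)
  stopifnot(length(contraction) == 5L, length(loopc_mean) == 5L,
            length(loopc_amplitude) == 5L, length(loopc_phase) == 5L)
  if (is.matrix(water_counts)) {
    stopifnot(nrow(water_counts) == n_frames, ncol(water_counts) == 5L)
  } else {
    stopifnot(length(water_counts) == 5L)
    water_counts <- matrix(as.integer(water_counts), n_frames, 5L,
                           byrow = TRUE)
  }
  structure(list(
    n_frames = as.integer(n_frames), occupancy = occupancy,
    ring_radius = ring_radius, base_width = base_width,
    contraction = contraction, water_counts = water_counts,
    loopc_mean = loopc_mean, loopc_amplitude = loopc_amplitude,
    loopc_period = as.integer(loopc_period), loopc_phase = loopc_phase,
    hbond_rates = hbond_rates, bridge_rates = bridge_rates,
    cationpi_rates = cationpi_rates, conserved_rates = conserved_rates,
    pushpull_amplitude = pushpull_amplitude,
    pushpull_coupling = pushpull_coupling,
    noise_sigma = noise_sigma, n_bulk_waters = as.integer(n_bulk_waters)
  ), class = "pp_generator_params")
}

# ---- internal geometry constants (angstrom, pocket local basis r,t,z) ----

.gen <- list(
  pocket_z = 10,
  cluster_z = 5,
  hinge_height = 8,   # O and G sit this far above their cluster centres
  apex_radius = 8,    # |O -> C|
  apex_half = 2,      # apex/hinge pair half-separation along r
  ligand_dz = -2.5,
  water_dz = 2.5,
  q_dz = -10,         # conserved-pair slot depth below pocket centre
  q_spacing = 3.5,
  hb_on = 2.8, hb_off = 4.5, oh = 1.0,
  ring_on = 4.5, ring_off = 8.0, ring_r = 1.39
)

# centroid-zero CA offsets: 6 fixed principal binding residues (THR220, the
# 7th, is the moving Loop C apex) and the 4 complementary ones
.prin_off <- matrix(c(
   3,  1.5,  5,   # PHE115
  -3,  1.5,  5,   # GLU173
   3, -1.5, -5,   # SER174
  -3, -1.5, -5,   # PHE175
   4,  0,    0,   # TYR218
  -4,  0,    0),  # PHE223
  ncol = 3, byrow = TRUE,
  dimnames = list(c("PHE115", "GLU173", "SER174", "PHE175", "TYR218",
                    "PHE223"), NULL))
.comp_off <- matrix(c(
   3, 0,  5,   # PHE79
  -3, 0,  5,   # ARG81
   3, 0, -5,   # LEU133
  -3, 0, -5),  # SER145
  ncol = 3, byrow = TRUE,
  dimnames = list(c("PHE79", "ARG81", "LEU133", "SER145"), NULL))

# ligand atom offsets from the ligand origin (glycine-zwitterion-like)
.lig_off <- matrix(c(
  0, -0.8, 0,     # N (ammonium)
  0.5, -1.2, -0.8,  # H1
  -0.5, -1.2, -0.8, # H2
  0, -0.3, -0.9,  # H3
  0, 0.4, 0,      # CA
  0, 1.4, 0.4,    # C
  0.9, 2.0, 0.4,  # O1
  -0.9, 2.0, 0.4),# O2
  ncol = 3, byrow = TRUE,
  dimnames = list(c("N", "H1", "H2", "H3", "CA", "C", "O1", "O2"), NULL))

# scripted-slot geometry: satellite direction and ligand anchor atom
.hb_slots <- list(
  ARG81  = list(anchor = "O1", u = c( 0.94,  0.34, 0),    side = "comp"),
  SER145 = list(anchor = "O2", u = c(-0.94,  0.34, 0),    side = "comp"),
  THR220 = list(anchor = "O1", u = c( 0.50, -0.50, 0.71), side = "prin"),
  PHE175 = list(anchor = "O2", u = c(-0.50, -0.50, 0.71), side = "prin")
)
.bridge_slots <- list(
  GLU173 = list(anchor = "N", v = c( 0.77, -0.64, 0), side = "prin"),
  SER174 = list(anchor = "N", v = c(-0.77, -0.64, 0), side = "prin")
)
.cpi_slots <- list(
  PHE175 = list(anchor = "N", u = c( 0,     0, -1),    side = "prin"),
  TYR218 = list(anchor = "N", u = c(-0.64,  0, -0.77), side = "prin"),
  PHE223 = list(anchor = "N", u = c( 0.64,  0, -0.77), side = "prin")
)
.conserved_slots <- data.frame(
  label = c("GLU119-ARG147", "LYS49-ASP96", "ASN219-ASN58",
            "THR220-ARG135", "ASN219-LYS189"),
  prin_resno = c(119L, 49L, 219L, 220L, 219L),
  prin_resname = c("GLU", "LYS", "ASN", "THR", "ASN"),
  comp_resno = c(147L, 96L, 58L, 135L, 189L),
  comp_resname = c("ARG", "ASP", "ASN", "ARG", "LYS")
)

.resname_of <- c(PHE115 = "PHE", GLU173 = "GLU", SER174 = "SER",
                 PHE175 = "PHE", TYR218 = "TYR", THR220 = "THR",
                 PHE223 = "PHE", PHE79 = "PHE", ARG81 = "ARG",
                 LEU133 = "LEU", SER145 = "SER")

.resno_of <- function(key) as.integer(sub("^[A-Z]+", "", key))

# local pocket basis for pocket p (0-based)
pocket_basis <- function(p, ring_radius) {
  phi <- (72 * p + 36) * pi / 180
  r <- c(cos(phi), sin(phi), 0)
  t <- c(-sin(phi), cos(phi), 0)
  z <- c(0, 0, 1)
  P <- ring_radius * r + c(0, 0, .gen$pocket_z)
  list(r = r, t = t, z = z, P = P)
}

#' Exact ground truth for a generated trajectory
#'
#' Computes, from the parameters and seed alone, everything the generated
#' trajectory is scripted to contain: per-frame interior water counts and
#' Loop C angles per pocket, the Bernoulli event matrices for every scripted
#' interaction, the per-frame intersubunit hydrogen-bond count, the
#' programmed contraction offsets and the push-pull latent variables. The
#' generator consumes this ledger, so at zero noise the analysis pipeline
#' reproduces it exactly.
#'
#' @param params a [generator_params()] object.
#' @param seed integer master seed.
#' @return a `pp_ledger` list.
#' @export
ground_truth_ledger <- function(params, seed) {
  stopifnot(inherits(params, "pp_generator_params"))
  seeds <- derive_seeds(seed, 3L)  # events, pushpull, noise
  nf <- params$n_frames
  tt <- seq_len(nf) - 1L

  loopc <- sapply(1:5, function(p) {
    params$loopc_mean[p] +
      params$loopc_amplitude[p] * sin(2 * pi * tt / params$loopc_period +
                                        params$loopc_phase[p])
  })
  loopc <- matrix(loopc, nrow = nf)

  # event stream: fixed-shape uniform array over 14 canonical slots
  slot_names <- c(paste0("hb.", names(.hb_slots)),
                  paste0("br.", names(.bridge_slots)),
                  paste0("cp.", names(.cpi_slots)),
                  paste0("cons.", .conserved_slots$label))
  old <- globalenv()$.Random.seed
  set.seed(seeds[1L])
  u <- array(stats::runif(nf * 5L * length(slot_names)),
             dim = c(nf, 5L, length(slot_names)),
             dimnames = list(NULL, POCKET_LABELS, slot_names))
  set.seed(seeds[2L])
  pp_x <- matrix(stats::rnorm(nf * 5L), nf, 5L)
  pp_y <- matrix(stats::rnorm(nf * 5L), nf, 5L)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  rate_of <- function(slot) {
    kind <- sub("\\..*$", "", slot)
    key <- sub("^[a-z]+\\.", "", slot)
    switch(kind,
           hb = params$hbond_rates[key],
           br = params$bridge_rates[key],
           cp = params$cationpi_rates[key],
           cons = params$conserved_rates[key])
  }
  events <- array(FALSE, dim = dim(u), dimnames = dimnames(u))
  for (s in slot_names) {
    r <- rate_of(s)
    if (is.na(r)) r <- 0
    ligand_needed <- !startsWith(s, "cons.")
    for (p in 1:5) {
      if (ligand_needed && !params$occupancy[p]) next
      events[, p, s] <- u[, p, s] < r
    }
  }

  bridge_active <- apply(events[, , startsWith(slot_names, "br."),
                                drop = FALSE], c(1, 2), sum)
  water_count <- params$water_counts + bridge_active
  intersub <- rowSums(events[, , startsWith(slot_names, "cons."),
                             drop = FALSE])

  structure(list(
    n_frames = nf, occupancy = params$occupancy,
    water_count = unname(water_count),
    scheduled_water = params$water_counts,
    loopc_angle = loopc,
    events = events,
    intersubunit_count = as.numeric(intersub),
    contraction = params$contraction,
    pushpull = list(coupling = params$pushpull_coupling,
                    amplitude = params$pushpull_amplitude,
                    x = pp_x, y = pp_y,
                    correlation_noiseless =
                      if (params$pushpull_amplitude > 0)
                        params$pushpull_coupling else NA_real_),
    rates = list(hbond = params$hbond_rates,
                 water_bridge = params$bridge_rates,
                 cation_pi = params$cationpi_rates,
                 conserved = params$conserved_rates),
    seeds = seeds
  ), class = "pp_ledger")
}

#' Write a ground-truth ledger as JSON
#'
#' @param ledger a `pp_ledger`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ledger_json <- function(ledger, path) {
  out <- ledger
  out$events <- NULL   # 3D arrays serialize poorly; export the summaries
  out$event_rates_realised <- apply(ledger$events, c(2, 3), mean)
  out$seeds <- NULL
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# ---- blueprint: static atom table + base coordinates + dynamic indices ----

build_blueprint <- function(params) {
  R <- params$ring_radius
  width <- params$base_width - params$contraction
  atoms <- list(); xyz <- list(); anchor <- list()
  idx <- new.env(parent = emptyenv())
  counter <- 0L
  add_atom <- function(elety, resid, resno, chain, pos, anchor_to = NA_integer_) {
    counter <<- counter + 1L
    atoms[[counter]] <<- data.frame(
      eleno = counter, elety = elety, resid = resid, resno = as.integer(resno),
      chain = chain, elem = guess_element(elety), role = NA_character_,
      stringsAsFactors = FALSE
    )
    xyz[[counter]] <<- pos
    anchor[[counter]] <<- if (is.na(anchor_to)) counter else anchor_to
    counter
  }
  chains <- LETTERS[1:5]
  bases <- lapply(0:4, pocket_basis, ring_radius = R)
  loc <- function(p, v) {
    b <- bases[[p]]
    b$P + v[1] * b$r + v[2] * b$t + v[3] * b$z
  }
  CP <- lapply(1:5, function(p) loc(p, c(0, -width[p] / 2, 0)))
  CC <- lapply(1:5, function(p) loc(p, c(0, width[p] / 2, 0)))
  g <- .gen

  reg <- list()
  for (p in 1:5) {
    b <- bases[[p]]
    ch_p <- chains[p]                 # principal chain of pocket p
    ch_c <- chains[p %% 5L + 1L]      # complementary chain
    lv <- function(v) v[1] * b$r + v[2] * b$t + v[3] * b$z

    # 6 fixed principal binding residues
    for (nm in rownames(.prin_off)) {
      i <- add_atom("CA", .resname_of[nm], .resno_of(nm), ch_p,
                    CP[[p]] + lv(.prin_off[nm, ]))
      reg[[paste0("ca.", nm, ".", p)]] <- i
    }
    # 4 complementary binding residues (chain of pocket p's complementary)
    for (nm in rownames(.comp_off)) {
      i <- add_atom("CA", .resname_of[nm], .resno_of(nm), ch_c,
                    CC[[p]] + lv(.comp_off[nm, ]))
      reg[[paste0("ca.", nm, ".", p)]] <- i
    }
    # Loop C hinge (fixed) and apex (dynamic; base at schedule mean)
    O <- CP[[p]] + lv(c(0, 0, g$hinge_height))
    G <- CC[[p]] + lv(c(0, 0, g$hinge_height))
    reg[[paste0("O.", p)]] <- O
    reg[[paste0("G.", p)]] <- G
    reg[[paste0("ca.THR215.", p)]] <- add_atom("CA", "THR", 215L, ch_p,
                                               O - g$apex_half * b$r)
    reg[[paste0("ca.THR224.", p)]] <- add_atom("CA", "THR", 224L, ch_p,
                                               O + g$apex_half * b$r)
    a0 <- params$loopc_mean[p] * pi / 180
    Cap <- O + g$apex_radius * (cos(a0) * b$t + sin(a0) * b$z)
    reg[[paste0("ca.ASN219.", p)]] <- add_atom("CA", "ASN", 219L, ch_p,
                                               Cap - g$apex_half * b$r)
    reg[[paste0("ca.THR220.", p)]] <- add_atom("CA", "THR", 220L, ch_p,
                                               Cap + g$apex_half * b$r)
    # reference pair: ASN58 mirrors ARG81 about G so the centroid is exact
    arg81 <- xyz[[reg[[paste0("ca.ARG81.", p)]]]]
    reg[[paste0("ca.ASN58.", p)]] <- add_atom("CA", "ASN", 58L, ch_c,
                                              2 * G - arg81)
    # loop fillers (static)
    reg[[paste0("ca.GLY176.", p)]] <- add_atom("CA", "GLY", 176L, ch_p,
                                               CP[[p]] + lv(c(0, -3, 2)))
    add_atom("CA", "ALA", 68L, ch_p, CP[[p]] + lv(c(-1, -4, -2)))
    add_atom("CA", "THR", 70L, ch_p, CP[[p]] + lv(c(1, -4, -2)))
    # push-pull Loop F residue (dynamic), complementary side of pocket p
    reg[[paste0("ca.LYS189.", p)]] <- add_atom("CA", "LYS", 189L, ch_c,
                                               CC[[p]] + lv(c(0, 2, 7)))
    # conserved-pair slots: CA + satellite atoms per pair
    for (i in seq_len(nrow(.conserved_slots))) {
      cs <- .conserved_slots[i, ]
      Q <- loc(p, c((i - 3) * g$q_spacing, 0, g$q_dz))
      # principal-side CA only for residues not already present
      if (!cs$prin_resno %in% c(219L, 220L)) {
        add_atom("CA", cs$prin_resname, cs$prin_resno, ch_p,
                 Q - 1.5 * b$t + c(0, 0, -1))
      }
      if (!cs$comp_resno %in% c(58L, 189L)) {
        add_atom("CA", cs$comp_resname, cs$comp_resno, ch_c,
                 Q + 1.5 * b$t + c(0, 0, -1))
      }
      oc <- add_atom(paste0("OC", i), cs$prin_resname, cs$prin_resno, ch_p, Q)
      nc <- add_atom(paste0("NC", i), cs$comp_resname, cs$comp_resno, ch_c,
                     Q + g$hb_on * b$t, anchor_to = oc)
      hc <- add_atom(paste0("HC", i), cs$comp_resname, cs$comp_resno, ch_c,
                     Q + (g$hb_on - g$oh) * b$t, anchor_to = oc)
      reg[[paste0("cons.", i, ".", p)]] <- c(oc = oc, nc = nc, hc = hc)
    }
    # restrained C-terminal tail, inner radius, below the ring
    phi_ch <- (72 * (p - 1)) * pi / 180
    for (k in 0:4) {
      add_atom("CA", "GLY", 236L + k, ch_p,
               c(12 * cos(phi_ch), 12 * sin(phi_ch), -6 - 0.4 * k))
    }

    if (params$occupancy[p]) {
      # ligand
      L <- loc(p, c(0, 0, g$ligand_dz))
      lig_idx <- integer(0)
      for (nm in rownames(.lig_off)) {
        i <- add_atom(nm, "LIG", p, "L", L + lv(.lig_off[nm, ]))
        reg[[paste0("lig.", nm, ".", p)]] <- i
        lig_idx <- c(lig_idx, i)
      }
      reg[[paste0("lig.", p)]] <- lig_idx
      # scripted hydrogen-bond satellites (hydroxyl donor on the residue)
      for (nm in names(.hb_slots)) {
        sl <- .hb_slots[[nm]]
        ch <- if (sl$side == "prin") ch_p else ch_c
        A <- xyz[[reg[[paste0("lig.", sl$anchor, ".", p)]]]]
        anc <- reg[[paste0("lig.", sl$anchor, ".", p)]]
        u <- unit_vec(lv(sl$u))
        ox <- add_atom("OX", .resname_of[nm], .resno_of(nm), ch,
                       A + g$hb_on * u, anchor_to = anc)
        hx <- add_atom("HX", .resname_of[nm], .resno_of(nm), ch,
                       A + (g$hb_on - g$oh) * u, anchor_to = anc)
        reg[[paste0("hb.", nm, ".", p)]] <- c(ox = ox, hx = hx)
      }
      # scripted bridge units: water (OH2,H1,H2) + residue acceptor OB
      bi <- 0L
      for (nm in names(.bridge_slots)) {
        bi <- bi + 1L
        sl <- .bridge_slots[[nm]]
        ch <- if (sl$side == "prin") ch_p else ch_c
        Nl <- xyz[[reg[[paste0("lig.N.", p)]]]]
        anc <- reg[[paste0("lig.N.", p)]]
        v <- unit_vec(lv(sl$v))
        ob_pos <- Nl + g$hb_on * v
        wres <- 9000L + 10L * p + bi
        ow <- add_atom("OH2", "HOH", wres, "W", ob_pos, anchor_to = anc)
        h1 <- add_atom("H1", "HOH", wres, "W",
                       ob_pos + g$oh * unit_vec(Nl - ob_pos), anchor_to = anc)
        od_pos <- ob_pos + g$hb_on * v
        h2 <- add_atom("H2", "HOH", wres, "W", ob_pos + g$oh * v,
                       anchor_to = anc)
        ob <- add_atom("OB", .resname_of[nm], .resno_of(nm), ch, od_pos,
                       anchor_to = anc)
        reg[[paste0("br.", nm, ".", p)]] <- c(ow = ow, h1 = h1, h2 = h2,
                                              ob = ob)
      }
      # scripted cation-pi ring plates (standard ring atom names)
      for (nm in names(.cpi_slots)) {
        sl <- .cpi_slots[[nm]]
        ch <- if (sl$side == "prin") ch_p else ch_c
        Nl <- xyz[[reg[[paste0("lig.N.", p)]]]]
        anc <- reg[[paste0("lig.N.", p)]]
        u <- unit_vec(lv(sl$u))
        centre <- Nl + g$ring_on * u
        e1 <- unit_vec(cross3(u, if (abs(u[3]) < 0.9) c(0, 0, 1) else b$r))
        e2 <- cross3(u, e1)
        ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
        ridx <- integer(0)
        for (q in 0:5) {
          th <- q * pi / 3
          ridx <- c(ridx, add_atom(ring_names[q + 1L], .resname_of[nm],
                                   .resno_of(nm), ch,
                                   centre + .gen$ring_r * (cos(th) * e1 +
                                                             sin(th) * e2),
                                   anchor_to = anc))
        }
        reg[[paste0("cp.", nm, ".", p)]] <- ridx
      }
    }

    # scheduled interior waters (max over schedule), parked when unused
    wmax <- max(params$water_counts[, p])
    widx <- integer(0)
    for (w in seq_len(wmax)) {
      th <- 2.4 * w
      base <- loc(p, c(0.45 * cos(th), 0.45 * sin(th),
                       g$water_dz + 0.25 * ((w %% 3) - 1)))
      wres <- 8000L + 20L * p + w
      ow <- add_atom("OH2", "HOH", wres, "W", base)
      add_atom("H1", "HOH", wres, "W", base + c(0.96, 0, 0), anchor_to = ow)
      add_atom("H2", "HOH", wres, "W", base + c(-0.24, 0, 0.93),
               anchor_to = ow)
      widx <- c(widx, ow)
    }
    reg[[paste0("wat.", p)]] <- widx
  }
  # bulk waters on a far ring
  for (w in seq_len(params$n_bulk_waters)) {
    th <- 2 * pi * w / max(params$n_bulk_waters, 1L)
    base <- c(55 * cos(th), 55 * sin(th), 30)
    wres <- 7000L + w
    ow <- add_atom("OH2", "HOH", wres, "W", base)
    add_atom("H1", "HOH", wres, "W", base + c(0.96, 0, 0), anchor_to = ow)
    add_atom("H2", "HOH", wres, "W", base + c(-0.24, 0, 0.93), anchor_to = ow)
  }

  at <- do.call(rbind, atoms)
  at$role <- assign_roles(at$resid)
  base_xyz <- do.call(rbind, xyz)
  list(atoms = at, base = base_xyz, anchor = unlist(anchor), reg = reg,
       bases = bases, CP = CP, CC = CC, width = width)
}

#' Generate a synthetic pentamer trajectory with its ground-truth ledger
#'
#' @param params a [generator_params()] object.
#' @param seed integer master seed; the same (params, seed) pair always
#'   yields an identical trajectory and ledger.
#' @return list with elements `trajectory` (a `pp_trajectory`), `ledger`
#'   (the matching [ground_truth_ledger()]) and `topology` (a ready-built
#'   `pp_topology` for the generated structure).
#' @export
generate_trajectory <- function(params = generator_params(), seed = 1L) {
  ledger <- ground_truth_ledger(params, seed)
  bp <- build_blueprint(params)
  nf <- params$n_frames
  g <- .gen
  n_atoms <- nrow(bp$atoms)
  coords <- array(NA_real_, dim = c(n_atoms, 3L, nf))

  # far parking spots, reused per frame for unused scheduled waters and
  # switched-off satellite units
  park <- function(k) c(70 * cos(0.7 * k), 70 * sin(0.7 * k), 60 + 3 * k)

  old <- globalenv()$.Random.seed
  set.seed(ledger$seeds[3L])
  for (f in seq_len(nf)) {
    xyz <- bp$base
    for (p in 1:5) {
      b <- bp$bases[[p]]
      # Loop C apex follows the angle schedule exactly
      O <- bp$reg[[paste0("O.", p)]]
      a <- ledger$loopc_angle[f, p] * pi / 180
      Cap <- O + g$apex_radius * (cos(a) * b$t + sin(a) * b$z)
      xyz[bp$reg[[paste0("ca.ASN219.", p)]], ] <- Cap - g$apex_half * b$r
      xyz[bp$reg[[paste0("ca.THR220.", p)]], ] <- Cap + g$apex_half * b$r
      # push-pull: displace SER174 (pocket p's principal cluster) along the
      # line to SER145 of the next pocket, LYS189 along its own line, with
      # coupled latent variables; triplet s = principal subunit of pocket p
      s <- p - 1L
      p_next <- p %% 5L + 1L
      i174 <- bp$reg[[paste0("ca.SER174.", p_next)]]
      i145 <- bp$reg[[paste0("ca.SER145.", p_next)]]
      i189 <- bp$reg[[paste0("ca.LYS189.", p)]]
      e1 <- unit_vec(bp$base[i145, ] - bp$base[i174, ])
      e2 <- unit_vec(bp$base[i145, ] - bp$base[i189, ])
      amp <- params$pushpull_amplitude
      cc <- params$pushpull_coupling
      x <- ledger$pushpull$x[f, p]
      y <- ledger$pushpull$y[f, p]
      xyz[i174, ] <- bp$base[i174, ] + amp * x * e1
      xyz[i189, ] <- bp$base[i189, ] +
        amp * (cc * x + sqrt(1 - cc^2) * y) * e2
      # scripted satellites: park the unit when the event is off
      pk <- 0L
      for (sl in c(paste0("hb.", names(.hb_slots)),
                   paste0("br.", names(.bridge_slots)),
                   paste0("cp.", names(.cpi_slots)),
                   paste0("cons.", seq_len(nrow(.conserved_slots))))) {
        key <- paste0(sl, ".", p)
        ii <- bp$reg[[key]]
        if (is.null(ii)) next
        slot_name <- if (startsWith(sl, "cons.")) {
          paste0("cons.", .conserved_slots$label[as.integer(sub("cons\\.", "", sl))])
        } else sl
        on <- ledger$events[f, p, slot_name]
        if (!on) {
          pk <- pk + 1L
          # conserved pairs: park only the donor half (NC, HC) so the bond
          # breaks; ligand-anchored units are parked whole
          if (startsWith(sl, "cons.")) ii <- ii[c("nc", "hc")]
          shift <- park(20L * p + pk) - xyz[ii[1L], ]
          xyz[ii, ] <- sweep(matrix(xyz[ii, ], ncol = 3L), 2L, shift, "+")
        }
      }
      # scheduled waters: park those beyond this frame's count
      widx <- bp$reg[[paste0("wat.", p)]]
      want <- ledger$scheduled_water[f, p]
      if (length(widx) > want) {
        for (w in (want + 1L):length(widx)) {
          ow <- widx[w]
          trio <- ow:(ow + 2L)   # OH2, H1, H2 added consecutively
          shift <- park(200L + 20L * p + w) - xyz[ow, ]
          xyz[trio, ] <- sweep(xyz[trio, , drop = FALSE], 2L, shift, "+")
        }
      }
    }
    # thermal noise: independent draws per atom, satellites ride with their
    # anchor's draw
    if (params$noise_sigma > 0) {
      noise <- matrix(stats::rnorm(n_atoms * 3L, sd = params$noise_sigma),
                      n_atoms, 3L)
      xyz <- xyz + noise[bp$anchor, ]
    }
    coords[, , f] <- xyz
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  traj <- pp_trajectory(bp$atoms, coords)
  topo <- build_topology(trajectory_frame(traj, 1L),
                         default_topology_config(params$occupancy))
  list(trajectory = traj, ledger = ledger, topology = topo)
}

#' Generate a single synthetic pentamer structure
#'
#' The first frame of [generate_trajectory()] under the same parameters and
#' seed; writable as PDB via [write_frame_pdb()].
#'
#' @param params a [generator_params()] object.
#' @param seed integer master seed.
#' @return a `pp_frame`.
#' @export
generate_pentamer <- function(params = generator_params(), seed = 1L) {
  one <- params
  one$n_frames <- 1L
  one$water_counts <- params$water_counts[1L, , drop = FALSE]
  gen <- generate_trajectory(one, seed)
  trajectory_frame(gen$trajectory, 1L)
}
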