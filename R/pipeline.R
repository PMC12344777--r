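# Orchestration: run every descriptor over one model (occupancy pattern)
# and render publication-style summary tables.

#' Run the full pocket-dynamics pipeline
#'
#' Drives all descriptors over one trajectory: ligand-interaction occurrence
#' tables (hydrogen bonds, water bridges, cation-pi), per-pocket time series
#' (water count, hull volume, Loop C angle), planar intra-/interpocket
#' distances, contact maps, adjacent-pocket Loop C angle correlations,
#' push-pull analysis, conserved-pair occurrences, intersubunit
#' hydrogen-bond totals and collective-variable series for occupied pockets.
#'
#' @param config a list with elements:
#'   * `trajectory` (a `pp_trajectory`) and `topology` (a `pp_topology`), or
#'     `structure_path` + `trajectory_path` + `topology_config`;
#'   * `criteria` ([interaction_criteria()], optional);
#'   * `stride` (integer, applied when reading from file; default 1);
#'   * `model` (label, default "model");
#'   * `outdir` (optional; tables written there as CSV/JSON);
#'   * `contact_maps` (logical, default TRUE).
#' @return a `pp_bundle` list of result tables plus a manifest (package
#'   version, config hash, frame count).
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  criteria <- config$criteria %||% interaction_criteria()
  model <- config$model %||% "model"

  if (!is.null(config[["trajectory"]])) {
    traj <- config[["trajectory"]]
    topo <- config[["topology"]]
    if (is.null(topo)) stop("config$topology required with config$trajectory")
  } else {
    structure_frame <- stage("structure_io", {
      cfg <- config[["topology_config"]] %||% default_topology_config()
      read_structure(config[["structure_path"]], cfg)
    })
    traj <- stage("structure_io", {
      read_trajectory(structure_frame, config[["trajectory_path"]],
                      stride = config[["stride"]] %||% 1L)
    })
    topo <- stage("pentamer_model", {
      build_topology(structure_frame,
                     config[["topology_config"]] %||% default_topology_config())
    })
  }
  nf <- n_frames(traj)
  pockets <- pocket_specs(topo)

  # map each ligand molecule to its pocket via cage-centroid proximity
  lig_map <- stage("pentamer_model", ligand_pocket_map(traj, topo))

  interactions <- stage("interaction_analysis",
                        ligand_interaction_tables(traj, topo, lig_map,
                                                  criteria))
  series <- stage("pocket_geometry", lapply(pockets, function(pk) {
    pocket_timeseries(traj, pk)
  }))
  pocket_summary <- do.call(rbind, lapply(series, function(s) {
    as.data.frame(s$summary[c("pocket", "occupied", "water_mean", "water_sd",
                              "volume_mean", "volume_sd", "angle_mean",
                              "angle_sd")])
  }))
  rownames(pocket_summary) <- NULL

  assembly <- stage("assembly_analysis", pocket_com_distances(traj, topo))
  loopc_corr <- stage("assembly_analysis", {
    do.call(rbind, lapply(POCKET_LABELS, function(lb) {
      nb <- adjacent_pockets(lb)[2L]  # right neighbour; 5 unique pairs
      data.frame(pair = paste(lb, nb, sep = "-"),
                 r = loopc_correlation(series[[lb]]$series$loopc_angle,
                                       series[[nb]]$series$loopc_angle))
    }))
  })
  pushpull <- stage("assembly_analysis", pushpull_analysis(traj, topo))
  conserved <- stage("assembly_analysis",
                     conserved_pair_hbonds(traj, topo, criteria))
  intersub <- stage("interaction_analysis",
                    intersubunit_hbond_total(traj, topo, criteria))
  cmaps <- if (isTRUE(config$contact_maps %||% TRUE)) {
    stage("assembly_analysis", {
      out <- lapply(pockets, function(pk) contact_map(traj, pk))
      names(out) <- POCKET_LABELS
      out
    })
  } else NULL

  cvs <- stage("collective_variables", {
    out <- list()
    for (lb in names(lig_map)) {
      pk <- pockets[[lig_map[[lb]]]]
      lig_atoms <- attr(lig_map, "atoms")[[lb]]
      site <- c(pk$ca_principal, pk$ca_complementary)
      out[[lig_map[[lb]]]] <- cv_series(traj, site, lig_atoms)
    }
    out
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("pentapocket")),
    model = model,
    n_frames = nf,
    occupancy = topo$occupancy,
    config_hash = config_hash(config),
    criteria = unclass(criteria)
  )
  bundle <- structure(list(
    model = model,
    interactions = interactions,
    pocket_summary = pocket_summary,
    pocket_series = series,
    assembly = assembly,
    loopc_correlations = loopc_corr,
    pushpull = pushpull,
    conserved_pairs = conserved,
    intersubunit_hbonds = intersub,
    contact_maps = cmaps,
    cv_series = cvs,
    manifest = manifest
  ), class = "pp_bundle")

  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

# stable hash of the run configuration (file-backed md5 over a canonical
# serialization; coordinate payloads excluded)
config_hash <- function(config) {
  slim <- config
  slim$trajectory <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(slim, tf, version = 2)
  unname(tools::md5sum(tf))
}

# ligand residues -> pocket labels, by proximity to the first-frame cage
# centroid; attribute "atoms" carries the atom indices per ligand
ligand_pocket_map <- function(trajectory, topology) {
  at <- trajectory$atoms
  fr <- trajectory_frame(trajectory, 1L)
  lig <- which(at$role == "ligand")
  map <- list()
  atoms <- list()
  if (!length(lig)) {
    res <- character(0)
    attr(res, "atoms") <- list()
    return(res)
  }
  key <- paste(at$chain[lig], at$resno[lig], sep = ":")
  centres <- vapply(pocket_specs(topology), function(pk) {
    colMeans(fr$xyz[c(pk$ca_principal, pk$ca_complementary), , drop = FALSE])
  }, numeric(3))
  res <- character(0)
  for (k in unique(key)) {
    idx <- lig[key == k]
    com <- colMeans(fr$xyz[idx, , drop = FALSE])
    d <- sqrt(colSums((centres - com)^2))
    res[[k]] <- POCKET_LABELS[which.min(d)]
    atoms[[k]] <- idx
  }
  attr(res, "atoms") <- atoms
  res
}

# occurrence tables for direct hydrogen bonds, water bridges and cation-pi
# between each pocket's ligand and the protein
ligand_interaction_tables <- function(trajectory, topology, lig_map,
                                      criteria) {
  at <- trajectory$atoms
  nf <- n_frames(trajectory)
  donors0 <- polar_hydrogens(trajectory_frame(trajectory, 1L))
  lig_atoms <- attr(lig_map, "atoms")
  all_recs <- list(hbond = list(), water_bridge = list(), cation_pi = list())
  prot_sel <- which(at$role == "protein" & at$elem %in% c("N", "O"))
  res_sets <- split(prot_sel, paste(at$chain[prot_sel], at$resno[prot_sel],
                                    at$resid[prot_sel], sep = ":"))
  for (k in seq_len(nf)) {
    fr <- trajectory_frame(trajectory, k)
    hb <- detect_hbonds(fr, donors = donors0, criteria = criteria)
    cp <- detect_cation_pi(fr, criteria = criteria)
    for (lb in names(lig_map)) {
      pocket <- lig_map[[lb]]
      li <- lig_atoms[[lb]]
      wb <- detect_water_bridges(fr, ligand = li, residues = res_sets,
                                 criteria = criteria, hbonds = hb)
      # direct ligand-protein hydrogen bonds
      sel <- hb[(hb$donor %in% li & hb$acceptor_role == "protein") |
                  (hb$acceptor %in% li & hb$donor_role == "protein"), ,
                drop = FALSE]
      if (nrow(sel)) {
        sel$pocket <- pocket
        sel$residue_resid <- ifelse(sel$donor_role == "protein",
                                    sel$donor_resid, sel$acceptor_resid)
        sel$residue_resno <- ifelse(sel$donor_role == "protein",
                                    sel$donor_resno, sel$acceptor_resno)
        all_recs$hbond[[length(all_recs$hbond) + 1L]] <- sel
      }
      if (nrow(wb)) {
        wb2 <- wb
        wb2$pocket <- pocket
        all_recs$water_bridge[[length(all_recs$water_bridge) + 1L]] <- wb2
      }
      cpsel <- cp[cp$cation %in% li, , drop = FALSE]
      if (nrow(cpsel)) {
        cpsel$pocket <- pocket
        all_recs$cation_pi[[length(all_recs$cation_pi) + 1L]] <- cpsel
      }
    }
  }
  out <- list()
  for (kind in names(all_recs)) {
    recs <- if (length(all_recs[[kind]])) {
      unique(do.call(rbind, all_recs[[kind]]))
    } else NULL
    out[[kind]] <- occurrence_summary(recs, nf)
  }
  out
}

#' Write a result bundle to disk
#'
#' @param bundle a `pp_bundle` from [run_pipeline()].
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(
    hbond_occurrence = bundle$interactions$hbond$residues,
    hbond_totals = bundle$interactions$hbond$totals,
    water_bridge_occurrence = bundle$interactions$water_bridge$residues,
    water_bridge_totals = bundle$interactions$water_bridge$totals,
    cation_pi_occurrence = bundle$interactions$cation_pi$residues,
    cation_pi_totals = bundle$interactions$cation_pi$totals,
    pocket_summary = bundle$pocket_summary,
    intrapocket = bundle$assembly$intrapocket,
    interpocket = bundle$assembly$interpocket,
    loopc_correlations = bundle$loopc_correlations,
    pushpull = as.data.frame(bundle$pushpull),
    conserved_pairs = bundle$conserved_pairs,
    intersubunit_interfaces = bundle$intersubunit_hbonds$per_interface
  )
  paths <- write_summary_tables(tabs, dir, prefix = paste0(bundle$model,
                                                           "_summary"))
  for (lb in names(bundle$pocket_series)) {
    p <- file.path(dir, sprintf("pocket_%s_series.csv", lb))
    utils::write.csv(bundle$pocket_series[[lb]]$series, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(bundle$contact_maps)) {
    for (lb in names(bundle$contact_maps)) {
      p <- file.path(dir, sprintf("contact_map_%s.csv", lb))
      utils::write.csv(as.data.frame(bundle$contact_maps[[lb]]), p)
      paths <- c(paths, p)
    }
  }
  for (lb in names(bundle$cv_series)) {
    p <- file.path(dir, sprintf("cv_%s.csv", lb))
    utils::write.csv(bundle$cv_series[[lb]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(dir, "manifest.json")))
}

#' Render a human-readable report of a result bundle
#'
#' Mirrors the layout of the standard occurrence and distance tables:
#' occurrence % and mean +/- sd per pocket, bound pockets marked, and the
#' occupied-pocket water means additionally shown with the +5 display
#' offset (flagged display-only).
#'
#' @param bundle a `pp_bundle`.
#' @return character vector of report lines, invisibly; printed to console.
#' @export
render_report <- function(bundle) {
  ln <- character(0)
  say <- function(...) ln <<- c(ln, sprintf(...))
  say("== Model '%s': %d frames ==", bundle$model, bundle$manifest$n_frames)
  ps <- bundle$pocket_summary
  if (!nrow(ps)) {
    say("no pockets analyzed")
    cat(paste(ln, collapse = "\n"), "\n")
    return(invisible(ln))
  }
  say("-- Pocket descriptors (water / volume / Loop C) --")
  for (i in seq_len(nrow(ps))) {
    disp <- if (ps$occupied[i]) {
      sprintf(" [display +5: %.1f]", ps$water_mean[i] + 5)
    } else ""
    say("pocket (%s)%s: waters %.2f +/- %.2f%s, volume %.0f +/- %.0f A^3, Loop C %.1f +/- %.1f deg",
        ps$pocket[i], if (ps$occupied[i]) " [bound]" else "",
        ps$water_mean[i], ps$water_sd[i], disp,
        ps$volume_mean[i], ps$volume_sd[i],
        ps$angle_mean[i], ps$angle_sd[i])
  }
  for (kind in c("hbond", "water_bridge", "cation_pi")) {
    tab <- bundle$interactions[[kind]]$residues
    tot <- bundle$interactions[[kind]]$totals
    say("-- %s occurrence (%%) --", kind)
    if (!nrow(tab)) say("  none detected")
    for (i in seq_len(nrow(tab))) {
      say("  pocket (%s) %s: %.1f", tab$pocket[i], tab$residue[i],
          tab$occurrence_pct[i])
    }
    for (i in seq_len(nrow(tot))) {
      say("  pocket (%s) total: %.1f +/- %.1f", tot$pocket[i],
          tot$mean_count[i], tot$sd_count[i])
    }
  }
  say("-- Intrapocket / interpocket planar distances (A) --")
  ia <- bundle$assembly$intrapocket
  for (i in seq_len(nrow(ia))) {
    v <- sprintf("%.1f", ia$mean[i])
    if (ia$occupied[i]) v <- paste0("*", v, "*")  # bound pockets marked
    say("  (%s): %s +/- %.2f", ia$pocket[i], v, ia$sd[i])
  }
  ie <- bundle$assembly$interpocket
  for (i in seq_len(nrow(ie))) {
    say("  %s: %.1f +/- %.2f", ie$label[i], ie$mean[i], ie$sd[i])
  }
  say("-- Intersubunit hydrogen bonds: total %.1f +/- %.1f --",
      bundle$intersubunit_hbonds$total$mean,
      bundle$intersubunit_hbonds$total$sd)
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}

#' @export
print.pp_bundle <- function(x, ...) {
  cat(sprintf("Pipeline bundle '%s': %d frames, %d occupied pockets\n",
              x$model, x$manifest$n_frames, sum(x$manifest$occupancy)))
  invisible(x)
}
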