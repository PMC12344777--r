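# Pentamer topology: the five interfacial pockets and residue role
# assignments every downstream descriptor consumes.

POCKET_LABELS <- letters[1:5]

#' Reference to one residue of the pentamer
#'
#' @param subunit subunit index in 0..4 (ring order).
#' @param resno residue number (author/PDB numbering).
#' @param resname 3-letter residue name.
#' @param insert optional insertion code.
#' @return an object of class `residue_ref`.
#' @export
residue_ref <- function(subunit, resno, resname, insert = NA_character_) {
  stopifnot(subunit %in% 0:4, resno > 0)
  structure(
    list(subunit = as.integer(subunit), resno = as.integer(resno),
         resname = as.character(resname), insert = insert),
    class = "residue_ref"
  )
}

#' @export
format.residue_ref <- function(x, ...) {
  sprintf("%s%d/su%d", x$resname, x$resno, x$subunit)
}

#' @export
print.residue_ref <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Default pocket and loop definitions for the glycine receptor ECD
#'
#' Returns the shipped configuration: the 11 binding residues per interface
#' (7 on the principal subunit: PHE115, GLU173, SER174, PHE175, TYR218,
#' THR220, PHE223; 4 on the complementary subunit: PHE79, ARG81, LEU133,
#' SER145), the three Loop C angle anchor pairs (apex ASN219/THR220, hinge
#' THR215/THR224, complementary reference ASN58/ARG81), loop residue ranges,
#' the restrained C-terminal tail, push-pull residue roles, conserved
#' interfacial hydrogen-bond pairs, and solvent/ligand residue-name sets.
#'
#' Loop ranges are approximations bracketing the named residues and are meant
#' to be overridden for other numbering schemes.
#'
#' @param occupancy logical length-5 vector: ligand occupancy of pockets a-e.
#' @return a named list understood by [build_topology()].
#' @export
default_topology_config <- function(occupancy = rep(TRUE, 5)) {
  stopifnot(is.logical(occupancy), length(occupancy) == 5L)
  list(
    principal_binding = data.frame(
      resno = c(115L, 173L, 174L, 175L, 218L, 220L, 223L),
      resname = c("PHE", "GLU", "SER", "PHE", "TYR", "THR", "PHE")
    ),
    complementary_binding = data.frame(
      resno = c(79L, 81L, 133L, 145L),
      resname = c("PHE", "ARG", "LEU", "SER")
    ),
    loopc_apex = data.frame(resno = c(219L, 220L), resname = c("ASN", "THR")),
    loopc_hinge = data.frame(resno = c(215L, 224L), resname = c("THR", "THR")),
    complementary_reference = data.frame(
      resno = c(58L, 81L), resname = c("ASN", "ARG")
    ),
    loops = list(
      A = c(111L, 122L), B = c(173L, 176L), C = c(215L, 224L),
      D = c(77L, 83L), E = c(133L, 147L), F = c(185L, 195L),
      `2` = c(55L, 70L)
    ),
    restrained_tail = c(236L, 240L),
    pushpull = list(loopB_resno = 174L, loopF_resno = 189L, loopE_resno = 145L),
    conserved_pairs = data.frame(
      principal_resno = c(119L, 49L, 219L, 220L, 219L),
      complementary_resno = c(147L, 96L, 58L, 135L, 189L),
      label = c("GLU119-ARG147", "LYS49-ASP96", "ASN219-ASN58",
                "THR220-ARG135", "ASN219-LYS189")
    ),
    occupancy = occupancy,
    reverse_ring = FALSE,
    water_resnames = c("HOH", "WAT", "TIP3", "SOL"),
    ligand_resnames = c("LIG", "GLZ"),
    ion_resnames = c("NA", "CL", "SOD", "CLA", "K", "POT")
  )
}

#' Read a topology configuration from YAML or JSON
#'
#' Missing entries fall back to [default_topology_config()].
#'
#' @param path path to a YAML or JSON file.
#' @return configuration list.
#' @export
read_topology_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_topology_config()
  tab_fields <- c("principal_binding", "complementary_binding", "loopc_apex",
                  "loopc_hinge", "complementary_reference", "conserved_pairs")
  for (nm in names(raw)) {
    cfg[[nm]] <- if (nm %in% tab_fields) {
      as.data.frame(raw[[nm]], stringsAsFactors = FALSE)
    } else {
      raw[[nm]]
    }
  }
  cfg$occupancy <- as.logical(cfg$occupancy)
  cfg
}

#' Path to the shipped glycine-receptor ECD configuration
#'
#' @return path to the packaged YAML config reproducing the default
#'   [default_topology_config()] definitions.
#' @export
glyr_config_path <- function() {
  system.file("extdata", "glyr_ecd_config.yaml", package = "pentapocket",
              mustWork = TRUE)
}

# Resolve (chain, resno) -> CA atom row index; stop with the offender named.
resolve_ca <- function(atoms, chain, resno, resname = NULL) {
  hit <- which(atoms$chain == chain & atoms$resno == resno &
                 atoms$elety == "CA" & atoms$role == "protein")
  if (length(hit) != 1L) {
    stop(sprintf(
      "cannot resolve residue %s%d (chain %s) to exactly one CA atom (%d matches)",
      if (is.null(resname)) "" else resname, resno, chain, length(hit)
    ))
  }
  if (!is.null(resname) && atoms$resid[hit] != resname) {
    stop(sprintf("residue %d in chain %s is %s, expected %s",
                 resno, chain, atoms$resid[hit], resname))
  }
  hit
}

#' Build a validated pentamer topology from a structure
#'
#' Identifies the five protein chains (ring order = sorted chain ID), checks
#' that their residue sequences agree, and resolves every declared residue of
#' every pocket to a CA atom index for fast per-frame lookup. Pocket `i`
#' (label a..e) has principal subunit `i` and complementary subunit
#' `(i + 1) mod 5`; set `config$reverse_ring = TRUE` for structures with the
#' opposite handedness.
#'
#' @param frame a `pp_frame` as returned by [read_structure()] or the
#'   synthetic generator.
#' @param config configuration list, see [default_topology_config()].
#' @return an object of class `pp_topology`.
#' @export
build_topology <- function(frame, config = default_topology_config()) {
  stopifnot(inherits(frame, "pp_frame"))
  atoms <- frame$atoms
  chains <- sort(unique(atoms$chain[atoms$role == "protein"]))
  if (length(chains) != 5L) {
    stop("expected 5 protein chains, found ", length(chains),
         " (", paste(chains, collapse = ","), ")")
  }
  seqs <- lapply(chains, function(ch) {
    sub <- atoms[atoms$chain == ch & atoms$role == "protein" &
                   atoms$elety == "CA", c("resno", "resid")]
    sub[order(sub$resno), ]
  })
  for (k in 2:5) {
    if (!identical(seqs[[1]]$resno, seqs[[k]]$resno) ||
        !identical(seqs[[1]]$resid, seqs[[k]]$resid)) {
      stop("chains ", chains[1], " and ", chains[k],
           " do not share an identical residue sequence")
    }
  }
  occ <- as.logical(config$occupancy %||% rep(TRUE, 5))
  if (length(occ) != 5L || anyNA(occ)) {
    stop("occupancy pattern must be 5 logicals")
  }
  reverse <- isTRUE(config$reverse_ring)

  make_refs <- function(df, subunit) {
    lapply(seq_len(nrow(df)), function(i) {
      residue_ref(subunit, df$resno[i], df$resname[i])
    })
  }
  pockets <- vector("list", 5L)
  names(pockets) <- POCKET_LABELS
  for (i in 0:4) {
    prin <- i
    comp <- if (reverse) (i - 1L) %% 5L else (i + 1L) %% 5L
    ch_p <- chains[prin + 1L]
    ch_c <- chains[comp + 1L]
    res_idx <- function(df, ch) {
      vapply(seq_len(nrow(df)), function(k) {
        resolve_ca(atoms, ch, df$resno[k], df$resname[k])
      }, integer(1))
    }
    spec <- structure(list(
      label = POCKET_LABELS[i + 1L],
      principal_subunit = prin,
      complementary_subunit = comp,
      principal_chain = ch_p,
      complementary_chain = ch_c,
      principal_binding = make_refs(config$principal_binding, prin),
      complementary_binding = make_refs(config$complementary_binding, comp),
      ca_principal = res_idx(config$principal_binding, ch_p),
      ca_complementary = res_idx(config$complementary_binding, ch_c),
      ca_apex = res_idx(config$loopc_apex, ch_p),
      ca_hinge = res_idx(config$loopc_hinge, ch_p),
      ca_reference = res_idx(config$complementary_reference, ch_c),
      occupied = occ[i + 1L]
    ), class = "pp_pocket")
    if (length(spec$ca_principal) != 7L || length(spec$ca_complementary) != 4L) {
      stop("pocket ", spec$label, ": binding residue counts must be 7 + 4")
    }
    anchor_sets <- list(spec$ca_apex, spec$ca_hinge, spec$ca_reference)
    if (anyDuplicated(unlist(lapply(anchor_sets, sort))) &&
        any(duplicated(vapply(anchor_sets, paste, character(1), collapse = ",")))) {
      stop("pocket ", spec$label, ": angle anchor pairs must be disjoint pairs")
    }
    pockets[[i + 1L]] <- spec
  }
  topo <- structure(list(
    pockets = pockets,
    chains = chains,
    loops = config$loops,
    restrained_tail = config$restrained_tail,
    occupancy = occ,
    pushpull = config$pushpull,
    conserved_pairs = config$conserved_pairs,
    config = config
  ), class = "pp_topology")
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  labs <- unname(vapply(topo$pockets, `[[`, character(1), "label"))
  if (!identical(labs, POCKET_LABELS)) stop("pocket labels must be a..e in order")
  prin <- vapply(topo$pockets, `[[`, integer(1), "principal_subunit")
  comp <- vapply(topo$pockets, `[[`, integer(1), "complementary_subunit")
  if (!setequal(prin, 0:4) || !setequal(comp, 0:4)) {
    stop("each subunit must appear exactly once as principal and once as complementary")
  }
  if (any(prin == comp)) stop("principal and complementary subunits must differ")
  gap <- (comp - prin) %% 5L
  if (!all(gap == gap[1]) || !gap[1] %in% c(1L, 4L)) {
    stop("pocket subunit pairs must follow one cyclic adjacency convention")
  }
  invisible(topo)
}

#' Pocket specifications in ring order
#'
#' @param topology a `pp_topology`.
#' @return list of 5 `pp_pocket` objects, labels a..e.
#' @export
pocket_specs <- function(topology) {
  stopifnot(inherits(topology, "pp_topology"))
  topology$pockets
}

#' Cyclic neighbours of a pocket
#'
#' @param label one of `"a"`..`"e"`.
#' @return character vector `c(left, right)` of the two adjacent pocket labels.
#' @examples
#' adjacent_pockets("a") # "e" "b"
#' @export
adjacent_pockets <- function(label) {
  i <- match(label, POCKET_LABELS)
  if (is.na(i)) stop("unknown pocket label: ", label)
  c(POCKET_LABELS[(i - 2L) %% 5L + 1L], POCKET_LABELS[i %% 5L + 1L])
}

#' @export
print.pp_topology <- function(x, ...) {
  cat("Pentamer topology:", length(x$chains), "chains (",
      paste(x$chains, collapse = " "), ")\n")
  for (p in x$pockets) {
    cat(sprintf("  pocket (%s): principal su%d chain %s, complementary su%d chain %s, %s\n",
                p$label, p$principal_subunit, p$principal_chain,
                p$complementary_subunit, p$complementary_chain,
                if (p$occupied) "occupied" else "empty"))
  }
  invisible(x)
}

#' @export
print.pp_pocket <- function(x, ...) {
  cat(sprintf("Pocket (%s): su%d(+)/su%d(-), %d+%d binding residues, %s\n",
              x$label, x$principal_subunit, x$complementary_subunit,
              length(x$ca_principal), length(x$ca_complementary),
              if (x$occupied) "occupied" else "empty"))
  invisible(x)
}
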