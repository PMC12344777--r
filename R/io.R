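# Structure and trajectory I/O with role-annotated atoms.
#
# Internal containers:
#   pp_frame      list(atoms = data.frame, xyz = n x 3 matrix [angstrom],
#                      frame_index, time)
#   pp_trajectory list(atoms, coords = n x 3 x n_frames array, frame_index,
#                      time)
# Atom table columns: eleno, elety (atom name), resid (residue name), resno,
# chain, elem (element symbol), role in {protein, water, ligand, ion}.

#' Construct a single coordinate frame
#'
#' @param atoms data frame with columns `eleno`, `elety`, `resid`, `resno`,
#'   `chain`, `elem`, `role`.
#' @param xyz n x 3 numeric matrix of coordinates in angstrom.
#' @param frame_index integer frame index (0-based, file convention).
#' @param time time in ps, or `NA`.
#' @return object of class `pp_frame`.
#' @export
pp_frame <- function(atoms, xyz, frame_index = 0L, time = NA_real_) {
  xyz <- as.matrix(xyz)
  if (nrow(atoms) != nrow(xyz) || ncol(xyz) != 3L) {
    stop("coordinate count must equal atom count (n x 3)")
  }
  need <- c("eleno", "elety", "resid", "resno", "chain", "elem", "role")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(atoms$role), c("protein", "water", "ligand", "ion"))
  if (length(bad)) stop("unknown molecule roles: ", paste(bad, collapse = ", "))
  structure(list(atoms = atoms, xyz = xyz,
                 frame_index = as.integer(frame_index), time = time),
            class = "pp_frame")
}

#' @export
print.pp_frame <- function(x, ...) {
  cat(sprintf("Frame %d: %d atoms (%s)\n", x$frame_index, nrow(x$atoms),
              paste(sprintf("%s=%d", names(table(x$atoms$role)),
                            as.integer(table(x$atoms$role))), collapse = ", ")))
  invisible(x)
}

# Assign molecule roles from residue names. Ligands may also be declared by
# hetero record type (type == "HETATM") for non-standard residue names.
assign_roles <- function(resid, type = NULL,
                         water_resnames = c("HOH", "WAT", "TIP3", "SOL"),
                         ligand_resnames = c("LIG", "GLZ"),
                         ion_resnames = c("NA", "CL", "SOD", "CLA", "K", "POT")) {
  role <- rep("protein", length(resid))
  role[resid %in% water_resnames] <- "water"
  role[resid %in% ion_resnames] <- "ion"
  role[resid %in% ligand_resnames] <- "ligand"
  if (!is.null(type)) {
    het <- type == "HETATM" & role == "protein"
    role[het] <- "ligand"
  }
  role
}

# Element symbol from a PDB atom name when the element column is blank.
guess_element <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    elesy <- trimws(elesy)
    ok <- !is.na(elesy) & nzchar(elesy)
  } else {
    ok <- rep(FALSE, length(elety))
    elesy <- character(length(elety))
  }
  first <- sub("^[0-9]*", "", elety)
  guess <- toupper(substr(first, 1L, 1L))
  two <- toupper(substr(first, 1L, 2L))
  guess[two %in% c("CL", "NA", "MG", "ZN", "FE")] <- two[two %in% c("CL", "NA", "MG", "ZN", "FE")]
  ifelse(ok, toupper(elesy), guess)
}

#' Read a structure file (PDB) into a role-annotated frame
#'
#' @param path path to a PDB file.
#' @param config topology configuration carrying the `water_resnames`,
#'   `ligand_resnames` and `ion_resnames` sets (see
#'   [default_topology_config()]).
#' @return a `pp_frame` (first model if the file holds several).
#' @export
read_structure <- function(path, config = default_topology_config()) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path, "': ",
                                           conditionMessage(e)))
  atoms_from_pdb(pdb, config)
}

atoms_from_pdb <- function(pdb, config) {
  a <- pdb$atom
  atoms <- data.frame(
    eleno = a$eleno,
    elety = a$elety,
    resid = a$resid,
    resno = a$resno,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    elem = guess_element(a$elety, a$elesy),
    role = assign_roles(a$resid, a$type,
                        config$water_resnames, config$ligand_resnames,
                        config$ion_resnames),
    stringsAsFactors = FALSE
  )
  xyz <- matrix(pdb$xyz[1L, ], ncol = 3L, byrow = TRUE)
  if (anyNA(xyz) || anyNA(atoms$resno) || !nrow(atoms)) {
    stop("failed to parse PDB: malformed or truncated ATOM records")
  }
  pp_frame(atoms, xyz, frame_index = 0L)
}

#' Read a trajectory over a known structure
#'
#' Supports multi-model PDB and CHARMM/NAMD DCD files. XTC is not supported.
#' Coordinates are angstrom in both formats. A stride of `k` keeps file
#' frames 0, k, 2k, ... (0-based `frame_index` preserved from the file).
#'
#' @param structure a `pp_frame` describing the topology (atom order must
#'   match the trajectory).
#' @param path trajectory file path (`.pdb` multi-model, or `.dcd`).
#' @param stride positive integer stride.
#' @return object of class `pp_trajectory`.
#' @export
read_trajectory <- function(structure, path, stride = 1L) {
  stopifnot(inherits(structure, "pp_frame"), stride >= 1L)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  n_atoms <- nrow(structure$atoms)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else if (grepl("\\.xtc$", path, ignore.case = TRUE)) {
    stop("XTC trajectories are not supported; convert to DCD or multi-model PDB")
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
  }
  xyz <- rbind(xyz)
  if (ncol(xyz) != 3L * n_atoms) {
    stop(sprintf("atom count mismatch: structure has %d atoms, trajectory frames have %d",
                 n_atoms, ncol(xyz) / 3L))
  }
  keep <- seq(1L, nrow(xyz), by = stride)
  coords <- array(NA_real_, dim = c(n_atoms, 3L, length(keep)))
  for (k in seq_along(keep)) {
    coords[, , k] <- matrix(xyz[keep[k], ], ncol = 3L, byrow = TRUE)
  }
  pp_trajectory(structure$atoms, coords, frame_index = keep - 1L)
}

#' Construct a trajectory container
#'
#' @param atoms atom table (see [pp_frame()]).
#' @param coords n_atoms x 3 x n_frames array, angstrom.
#' @param frame_index integer vector of 0-based frame indices.
#' @param time optional times in ps.
#' @return object of class `pp_trajectory`.
#' @export
pp_trajectory <- function(atoms, coords, frame_index = NULL, time = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[1] == nrow(atoms))
  nf <- dim(coords)[3]
  structure(list(
    atoms = atoms, coords = coords,
    frame_index = as.integer(frame_index %||% (seq_len(nf) - 1L)),
    time = time
  ), class = "pp_trajectory")
}

#' Number of frames in a trajectory
#' @param trajectory a `pp_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Extract one frame from a trajectory
#'
#' @param trajectory a `pp_trajectory`.
#' @param i frame position (1-based within the trajectory).
#' @return a `pp_frame`.
#' @export
trajectory_frame <- function(trajectory, i) {
  stopifnot(i >= 1L, i <= n_frames(trajectory))
  pp_frame(trajectory$atoms, trajectory$coords[, , i],
           frame_index = trajectory$frame_index[i],
           time = if (is.null(trajectory$time)) NA_real_ else trajectory$time[i])
}

#' @export
print.pp_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n", n_frames(x), nrow(x$atoms)))
  invisible(x)
}

#' Write one frame as a PDB file
#'
#' @param frame a `pp_frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_pdb <- function(frame, path) {
  a <- frame$atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(frame$xyz)),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain, elesy = a$elem)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param trajectory a `pp_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(trajectory, path) {
  a <- trajectory$atoms
  nf <- n_frames(trajectory)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * nrow(a))
  for (k in seq_len(nf)) xyz[k, ] <- as.vector(t(trajectory$coords[, , k]))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resid,
                   eleno = a$eleno, elety = a$elety, chain = a$chain,
                   elesy = a$elem)
  invisible(path)
}

#' Write summary tables as CSV and JSON
#'
#' Each element of `tables` must be a data frame; `<name>.csv` and a single
#' `<prefix>.json` are produced. Rereading the CSVs yields identical values
#' to printed precision.
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix for the combined JSON.
#' @return character vector of written paths, invisibly.
#' @export
write_summary_tables <- function(tables, dir, prefix = "summary") {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    stopifnot(is.data.frame(tables[[nm]]))
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  pj <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(tables, pj, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, pj))
}
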