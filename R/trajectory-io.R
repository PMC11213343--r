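#' Read a structure from a PDB file
#'
#' Parses ATOM records of a (possibly multi-model) PDB file into an
#' `hs_structure`: an atom table plus a coordinate matrix. Multi-model files
#' return the requested MODEL block; single-model files ignore `model`.
#'
#' Residue indexing is 1-based and taken verbatim from the PDB residue
#' numbers, so residue identifiers printed by downstream reports match the
#' numbering of the input structure.
#'
#' @param path Path to a PDB-format text file.
#' @param model 1-based MODEL index for multi-model files.
#' @return An `hs_structure`: list with `atoms` (tibble: `residue_index`,
#'   `residue_name`, `atom_name`, `element`, `chain`) and `xyz`
#'   (numeric matrix, one row per atom, columns x/y/z in Angstrom).
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) {
    stop("structure file not found: ", path, call. = FALSE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("no ATOM records in '", path, "'", call. = FALSE)
  }
  n_models <- nrow(pdb$xyz)
  if (model < 1L || model > n_models) {
    stop("model index ", model, " out of range (file has ", n_models,
         " model", if (n_models > 1) "s", ")", call. = FALSE)
  }
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  colnames(xyz) <- c("x", "y", "z")
  if (!all(is.finite(xyz))) {
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  }
  element <- atoms$elesy
  missing_el <- is.na(element) | !nzchar(trimws(element))
  if (any(missing_el)) {
    element[missing_el] <- guess_element(atoms$elety[missing_el])
  }
  new_structure(
    tibble::tibble(
      residue_index = as.integer(atoms$resno),
      residue_name  = as.character(atoms$resid),
      atom_name     = trimws(as.character(atoms$elety)),
      element       = trimws(element),
      chain         = as.character(atoms$chain)
    ),
    xyz
  )
}

#' Build a structure from an atom table and coordinates
#'
#' @param atoms Tibble with `residue_index`, `residue_name`, `atom_name`,
#'   `element`, `chain`, one row per atom.
#' @param xyz Numeric matrix (atoms x 3), Angstrom.
#' @return An `hs_structure`.
#' @export
new_structure <- function(atoms, xyz) {
  stopifnot(nrow(atoms) == nrow(xyz))
  structure(list(atoms = atoms, xyz = xyz), class = "hs_structure")
}

# Element symbol from an atom name: strip digits/primes, take the leading
# letter (PDB convention puts H/C/N/O/S first for standard residues).
guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  toupper(substr(nm, 1L, 1L))
}

#' @export
print.hs_structure <- function(x, ...) {
  cat("<hs_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$residue_index)), " residues\n", sep = "")
  invisible(x)
}

#' Residue indices present in a structure
#' @param structure An `hs_structure`.
#' @return Sorted integer vector of residue indices.
#' @export
residue_indices <- function(structure) {
  sort(unique(structure$atoms$residue_index))
}

#' Read a trajectory from one or more multi-model PDB files
#'
#' Frames are the MODEL blocks in file order; multiple paths are
#' concatenated. Frame times are `frame_interval * (0, 1, 2, ...)` ns when an
#' interval is given, otherwise the 0-based frame index (so windows given in
#' "ns" degrade gracefully to frame counts).
#'
#' @param paths Character vector of multi-model PDB paths.
#' @param topology Optional `hs_structure` to validate atom counts against;
#'   defaults to the first model of the first file.
#' @param frame_interval Time between frames in ns, or `NULL` for index times.
#' @return An `hs_trajectory`: list with `topology` (`hs_structure`), `coords`
#'   (array atoms x 3 x frames, Angstrom) and `times` (ns, strictly
#'   increasing).
#' @export
read_trajectory <- function(paths, topology = NULL, frame_interval = NULL) {
  frames <- list()
  for (path in paths) {
    if (!file.exists(path)) {
      stop("trajectory file not found: ", path, call. = FALSE)
    }
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    if (is.null(topology)) topology <- read_structure(path, model = 1L)
    n_atoms <- nrow(topology$atoms)
    if (ncol(pdb$xyz) != 3L * n_atoms) {
      stop("atom count mismatch: topology has ", n_atoms, " atoms but '",
           path, "' has ", ncol(pdb$xyz) / 3, call. = FALSE)
    }
    for (m in seq_len(nrow(pdb$xyz))) {
      frames[[length(frames) + 1L]] <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    }
  }
  if (length(frames) == 0L) stop("zero frames read", call. = FALSE)
  new_trajectory(topology, frames, frame_interval = frame_interval)
}

#' Build a trajectory from in-memory frames
#'
#' @param topology An `hs_structure` providing the atom table.
#' @param frames List of coordinate matrices (atoms x 3) or an
#'   atoms x 3 x frames array.
#' @param times Frame times in ns (strictly increasing), or `NULL`.
#' @param frame_interval Spacing in ns used when `times` is `NULL`.
#' @return An `hs_trajectory`.
#' @export
new_trajectory <- function(topology, frames, times = NULL, frame_interval = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    coords <- frames
  } else {
    coords <- array(
      unlist(frames, use.names = FALSE),
      dim = c(nrow(frames[[1L]]), 3L, length(frames))
    )
  }
  n_atoms <- nrow(topology$atoms)
  if (dim(coords)[1L] != n_atoms) {
    stop("frame atom count (", dim(coords)[1L],
         ") does not match topology (", n_atoms, ")", call. = FALSE)
  }
  n_frames <- dim(coords)[3L]
  if (is.null(times)) {
    dt <- if (is.null(frame_interval)) 1 else frame_interval
    times <- dt * (seq_len(n_frames) - 1)
  }
  if (length(times) != n_frames) {
    stop("times length (", length(times), ") != frame count (", n_frames, ")",
         call. = FALSE)
  }
  if (n_frames > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(topology = topology, coords = coords, times = as.numeric(times)),
    class = "hs_trajectory"
  )
}

#' @export
print.hs_trajectory <- function(x, ...) {
  cat("<hs_trajectory> ", n_frames(x), " frames, ", dim(x$coords)[1L],
      " atoms, ", min(x$times), "-", max(x$times), " ns\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory An `hs_trajectory`.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3L]

#' Coordinates of one frame
#' @param trajectory An `hs_trajectory`.
#' @param frame 1-based frame number.
#' @return Numeric matrix (atoms x 3).
#' @export
frame_coords <- function(trajectory, frame) {
  trajectory$coords[, , frame, drop = TRUE]
}

#' Select atoms from a structure
#'
#' @param structure An `hs_structure`.
#' @param mode `"calpha"` (exactly the CA atom of every residue), `"heavy"`
#'   (everything that is not hydrogen, by element), or `"all"`.
#' @return Integer vector of atom indices with attributes `label` (the mode)
#'   and class `hs_selection`.
#' @export
select_atoms <- function(structure, mode = c("calpha", "heavy", "all")) {
  mode <- match.arg(mode)
  atoms <- structure$atoms
  idx <- switch(mode,
    all = seq_len(nrow(atoms)),
    heavy = which(toupper(atoms$element) != "H"),
    calpha = {
      ca <- which(atoms$atom_name == "CA")
      missing <- setdiff(unique(atoms$residue_index), atoms$residue_index[ca])
      if (length(missing) > 0L) {
        stop("residue(s) without a CA atom: ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      # one CA per residue: keep the first if altloc duplicates exist
      ca[!duplicated(atoms$residue_index[ca])]
    }
  )
  structure(as.integer(idx), label = mode, class = "hs_selection")
}

#' Write a structure as a single-model PDB file
#' @param structure An `hs_structure`.
#' @param path Output path.
#' @export
write_structure_pdb <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pdb_atom_lines(structure$atoms, structure$xyz), con)
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are printed with 3 decimals (the PDB text precision), so a
#' write/read round trip preserves them to 1e-3 Angstrom.
#'
#' @param trajectory An `hs_trajectory`.
#' @param path Output path.
#' @export
write_trajectory_pdb <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  atoms <- trajectory$topology$atoms
  for (f in seq_len(n_frames(trajectory))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(pdb_atom_lines(atoms, frame_coords(trajectory, f)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

pdb_atom_lines <- function(atoms, xyz) {
  name <- ifelse(
    nchar(atoms$atom_name) >= 4L,
    substr(atoms$atom_name, 1L, 4L),
    sprintf(" %-3s", atoms$atom_name)
  )
  chain <- ifelse(is.na(atoms$chain) | !nzchar(atoms$chain), "A", atoms$chain)
  sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)) %% 100000L, name, atoms$residue_name, chain,
    atoms$residue_index, xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0,
    atoms$element
  )
}
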