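# In-code fixtures: tiny structures and trajectories built at test time.

# A toy n-residue peptide with CA atoms on a gentle 3D helix, optionally
# with an extra hydrogen and sidecar heavy atom per residue.
make_peptide <- function(n_res = 5L, with_h = FALSE, with_cb = FALSE) {
  rows <- list(); xyz <- list()
  for (r in seq_len(n_res)) {
    ca <- c(3.8 * r, 1.5 * sin(r), 1.5 * cos(r))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      residue_index = r, residue_name = "ALA", atom_name = "CA",
      element = "C", chain = "A")
    xyz[[length(xyz) + 1L]] <- ca
    if (with_cb) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        residue_index = r, residue_name = "ALA", atom_name = "CB",
        element = "C", chain = "A")
      xyz[[length(xyz) + 1L]] <- ca + c(0, 1.5, 0)
    }
    if (with_h) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        residue_index = r, residue_name = "ALA", atom_name = "HA",
        element = "H", chain = "A")
      xyz[[length(xyz) + 1L]] <- ca + c(0, 0, 1.0)
    }
  }
  new_structure(dplyr::bind_rows(rows), do.call(rbind, xyz))
}

# Single-residue-per-atom structure from an explicit coordinate matrix.
make_ca_structure <- function(xyz, residue_index = seq_len(nrow(xyz))) {
  new_structure(
    tibble::tibble(
      residue_index = as.integer(residue_index), residue_name = "GLY",
      atom_name = "CA", element = "C", chain = "A"),
    as.matrix(xyz)
  )
}

# Four CA "residues" realising a chosen torsion angle (degrees) at residue 2.
make_torsion_structure <- function(angle_deg) {
  phi <- angle_deg * pi / 180
  make_ca_structure(rbind(
    c(0, 1, 0),
    c(0, 0, 0),
    c(1.5, 0, 0),
    c(1.5, cos(phi), sin(phi))
  ))
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

rigid_transform_trajectory <- function(traj) {
  frames <- lapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    r <- random_rotation()
    shift <- stats::rnorm(3, sd = 10)
    sweep(x %*% r, 2L, shift, "+")
  })
  new_trajectory(traj$topology, frames, times = traj$times)
}

# Hand-written multi-model PDB text (fixed-format), independent of the
# package's writer.
three_model_pdb <- function(path) {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       1.500   2.500   3.500  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.500   2.500   3.500  1.00  0.00           C",
    "ENDMDL",
    "MODEL        3",
    "ATOM      1  CA  GLY A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2      12.000   9.000   9.000  1.00  0.00           C",
    "ENDMDL",
    "END"
  )
  writeLines(lines, path)
  path
}

# Small noiseless hinge fixture shared across tests.
quiet_hinge <- function(seed = 1L, noise = 0) {
  generate_hinge_trajectory(hinge_spec(noise_sigma = noise, seed = seed))
}

ca_config <- function(...) {
  analysis_config(selection_mode = "calpha", ...)
}

# Plate truth table used by the assay recovery tests.
plate_truth <- function() {
  tibble::tibble(
    construct = rep(c("MBP_233-cpGFP", "MBP_170-cpGFP", "MBP_131-cpGFP"),
                    each = 2L),
    maltose_mM = rep(c(1, 100), 3L),
    dff0 = c(0.729, 0.741, 0.495, 0.523, 0.02, 0.05)
  )
}
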