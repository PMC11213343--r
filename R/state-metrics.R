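#' Optimal superposition of two point sets
#'
#' Least-squares rigid-body superposition (Kabsch, via SVD) of `mobile` onto
#' `reference`, with the post-fit RMSD.
#'
#' @param mobile,reference Numeric matrices (n x 3), same n >= 3.
#' @return List with `rotation` (3 x 3, applied on the right of centred
#'   coordinates), `translation` (length-3), `rmsd` (Angstrom) and `fitted`
#'   (the transformed mobile coordinates).
#' @export
superpose_rmsd <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference))) {
    stop("point sets differ in size", call. = FALSE)
  }
  if (nrow(mobile) < 3L) stop("need at least 3 points", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2L, cm); b <- sweep(reference, 2L, cr)
  if (max(abs(a)) < 1e-12 || qr(a)$rank < 2L) {
    stop("degenerate (coincident or collinear) point set", call. = FALSE)
  }
  s <- svd(crossprod(a, b))           # 3x3 covariance H = a' b
  d <- sign(det(s$u %*% t(s$v)))      # guard against improper rotation
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- a %*% rot
  fitted <- sweep(fitted, 2L, cr, "+")
  list(
    rotation = rot,
    translation = cr - as.vector(cm %*% rot),
    rmsd = point_rmsd(fitted, reference),
    fitted = fitted
  )
}

point_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD of a trajectory against a reference structure
#'
#' Each frame is (by default) optimally superposed onto the reference over
#' the selected atoms before the RMSD is taken; `fit = FALSE` gives the raw
#' coordinate RMSD (used for controlled single-atom checks).
#'
#' @param trajectory An `hs_trajectory`.
#' @param reference An `hs_structure`, or `NULL` for frame 1 of the
#'   trajectory (the starting conformation).
#' @param selection An `hs_selection`, or `NULL` for C-alpha atoms.
#' @param fit Superpose before measuring? Default `TRUE`.
#' @return Tibble with `frame`, `time_ns`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(trajectory, reference = NULL, selection = NULL,
                        fit = TRUE) {
  if (is.null(selection)) selection <- select_atoms(trajectory$topology, "calpha")
  if (length(selection) == 0L) stop("empty atom selection", call. = FALSE)
  ref_xyz <- if (is.null(reference)) {
    frame_coords(trajectory, 1L)[selection, , drop = FALSE]
  } else {
    reference$xyz[selection, , drop = FALSE]
  }
  vals <- vapply(seq_len(n_frames(trajectory)), function(f) {
    x <- frame_coords(trajectory, f)[selection, , drop = FALSE]
    if (fit) superpose_rmsd(x, ref_xyz)$rmsd else point_rmsd(x, ref_xyz)
  }, numeric(1L))
  tibble::tibble(
    frame = seq_along(vals),
    time_ns = trajectory$times,
    rmsd = vals
  )
}

#' Indices of the frames in the final time window
#'
#' @param times Frame times in ns.
#' @param window_ns Window length in ns; frames with
#'   `time > max(times) - window_ns` are kept.
#' @noRd
last_window_frames <- function(times, window_ns) {
  span <- max(times) - min(times)
  if (window_ns > span + 1e-9) {
    stop("trajectory (", span, " ns) shorter than window (", window_ns, " ns)",
         call. = FALSE)
  }
  which(times > max(times) - window_ns + 1e-9)
}

#' Classify a simulation as open or closed from its RMSD series
#'
#' A simulation is "closed" when the mean RMSD over the final window is
#' strictly below the threshold, and "open" otherwise (a mean exactly at the
#' threshold is called open, since the closed rule is a strict inequality).
#' Defaults: 2.5 Angstrom over the last 50 ns.
#'
#' @param rmsd A tibble from [rmsd_series()], or a numeric RMSD vector.
#' @param times Frame times in ns (ignored when `rmsd` is a tibble).
#' @param threshold RMSD threshold in Angstrom.
#' @param window_ns Averaging window in ns (the final stretch of the run).
#' @return One-row tibble: `label` ("open"/"closed"), `mean_last_window`,
#'   `window_ns`, `threshold`.
#' @export
classify_state <- function(rmsd, times = NULL, threshold = 2.5,
                           window_ns = 50) {
  if (is.data.frame(rmsd)) {
    times <- rmsd$time_ns
    rmsd <- rmsd$rmsd
  }
  if (is.null(times)) times <- seq_along(rmsd) - 1
  keep <- last_window_frames(times, window_ns)
  m <- mean(rmsd[keep])
  tibble::tibble(
    label = if (m < threshold) "closed" else "open",
    mean_last_window = m,
    window_ns = window_ns,
    threshold = threshold
  )
}

#' Four-point torsion angle in degrees
#'
#' Standard signed dihedral of points p1..p4 about the p2-p3 axis, in
#' (-180, 180]: 0 for planar cis, 180 for planar trans.
#' @param p1,p2,p3,p4 Length-3 numeric vectors.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12) {
    stop("degenerate (collinear) torsion geometry", call. = FALSE)
  }
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, sum(n1 * n2)) * 180 / pi
  # torsion convention: cis = 0; map -180 to +180 so the range is (-180, 180]
  if (ang <= -180 + 1e-12) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' C-alpha pseudo-dihedral of a residue
#'
#' The backbone-scale torsion assigned to residue i: the dihedral of the four
#' consecutive C-alpha atoms of residues i-1, i, i+1, i+2. Defined for the
#' 2nd through (n-2)th residues of a chain.
#'
#' @param structure An `hs_structure`.
#' @param i Residue index (matching the structure's numbering).
#' @return Angle in degrees, in (-180, 180].
#' @export
ca_pseudo_dihedral <- function(structure, i) {
  ca <- ca_coord_map(structure)
  res <- as.integer(rownames(ca))
  need <- (i - 1L):(i + 2L)
  if (!all(need %in% res)) {
    stop("pseudo-dihedral undefined at residue ", i,
         " (needs CA atoms of residues ", i - 1L, "..", i + 2L, ")",
         call. = FALSE)
  }
  rows <- match(need, res)
  torsion_angle(ca[rows[1L], ], ca[rows[2L], ], ca[rows[3L], ], ca[rows[4L], ])
}

# CA coordinates indexed by residue number, as a matrix with residue rownames
ca_coord_map <- function(structure) {
  sel <- select_atoms(structure, "calpha")
  xyz <- structure$xyz[sel, , drop = FALSE]
  rownames(xyz) <- structure$atoms$residue_index[sel]
  xyz
}

pseudo_dihedral_profile_xyz <- function(ca_xyz, residues) {
  ok <- residues[(residues - 1L) %in% residues &
                   (residues + 1L) %in% residues &
                   (residues + 2L) %in% residues]
  vals <- vapply(ok, function(i) {
    rows <- match((i - 1L):(i + 2L), residues)
    torsion_angle(ca_xyz[rows[1L], ], ca_xyz[rows[2L], ],
                  ca_xyz[rows[3L], ], ca_xyz[rows[4L], ])
  }, numeric(1L))
  tibble::tibble(residue_index = ok, value = vals)
}

#' Per-residue C-alpha pseudo-dihedrals of a structure
#'
#' @param structure An `hs_structure`.
#' @return Tibble `residue_index`, `value` (degrees); residues whose i-1..i+2
#'   neighbours are incomplete are omitted.
#' @export
pseudo_dihedral_profile <- function(structure) {
  ca <- ca_coord_map(structure)
  pseudo_dihedral_profile_xyz(ca, as.integer(rownames(ca)))
}

# wrap an angular difference into (-180, 180]
wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  ifelse(x <= -180 + 1e-12, x + 360, x)
}

#' Pseudo-dihedral change between two static structures
#'
#' Per-residue absolute difference of the C-alpha pseudo-dihedral between two
#' structures with identical residue numbering (e.g. a holo/apo crystal
#' pair), wrapped into \[0, 180\] degrees.
#'
#' @param struct_a,struct_b `hs_structure`s with matching residue numbering.
#' @return Tibble `residue_index`, `metric` (`"ddihe_crys"`), `value`
#'   (degrees).
#' @export
delta_dihe_structures <- function(struct_a, struct_b) {
  pa <- pseudo_dihedral_profile(struct_a)
  pb <- pseudo_dihedral_profile(struct_b)
  if (!identical(pa$residue_index, pb$residue_index)) {
    stop("residue numbering mismatch between structures", call. = FALSE)
  }
  tibble::tibble(
    residue_index = pa$residue_index,
    metric = "ddihe_crys",
    value = abs(wrap_angle(pa$value - pb$value))
  )
}

#' Per-residue RMSF over the final window of a trajectory
#'
#' Root-mean-square fluctuation of each selected C-alpha about its mean
#' position over the final `window_ns`. Frames are first superposed onto the
#' window-mean structure (one fit-to-first pass to build the mean, then a
#' refit onto it), so rigid-body drift does not register as fluctuation;
#' `fit = FALSE` skips superposition for controlled fixtures.
#'
#' @param trajectory An `hs_trajectory`.
#' @param window_ns Window in ns, or `NULL` for the whole run.
#' @param fit Superpose frames before measuring? Default `TRUE`.
#' @return Tibble `residue_index`, `metric` (`"rmsf"`), `value` (Angstrom).
#' @export
rmsf_profile <- function(trajectory, window_ns = NULL, fit = TRUE) {
  sel <- select_atoms(trajectory$topology, "calpha")
  residues <- trajectory$topology$atoms$residue_index[sel]
  frames <- if (is.null(window_ns)) {
    seq_len(n_frames(trajectory))
  } else {
    last_window_frames(trajectory$times, window_ns)
  }
  coords <- lapply(frames, function(f) {
    frame_coords(trajectory, f)[sel, , drop = FALSE]
  })
  if (fit) {
    coords <- lapply(coords, function(x) superpose_rmsd(x, coords[[1L]])$fitted)
    mean_xyz <- Reduce(`+`, coords) / length(coords)
    coords <- lapply(coords, function(x) superpose_rmsd(x, mean_xyz)$fitted)
  }
  mean_xyz <- Reduce(`+`, coords) / length(coords)
  sq <- lapply(coords, function(x) rowSums((x - mean_xyz)^2))
  tibble::tibble(
    residue_index = as.integer(residues),
    metric = "rmsf",
    value = sqrt(Reduce(`+`, sq) / length(sq))
  )
}

#' Window-averaged pseudo-dihedral profile of a trajectory
#'
#' Circular mean of each residue's C-alpha pseudo-dihedral over the frames of
#' the final window (arithmetic means of angles near +/-180 degrees are
#' meaningless, so the mean is taken on the unit circle).
#'
#' @param trajectory An `hs_trajectory`.
#' @param window_ns Window in ns, or `NULL` for the whole run.
#' @return Tibble `residue_index`, `value` (degrees, circular mean).
#' @export
dihedral_md_profile <- function(trajectory, window_ns = NULL) {
  sel <- select_atoms(trajectory$topology, "calpha")
  residues <- as.integer(trajectory$topology$atoms$residue_index[sel])
  frames <- if (is.null(window_ns)) {
    seq_len(n_frames(trajectory))
  } else {
    last_window_frames(trajectory$times, window_ns)
  }
  per_frame <- lapply(frames, function(f) {
    xyz <- frame_coords(trajectory, f)[sel, , drop = FALSE]
    pseudo_dihedral_profile_xyz(xyz, residues)$value
  })
  mat <- do.call(cbind, per_frame) * pi / 180
  idx <- pseudo_dihedral_profile_xyz(
    frame_coords(trajectory, frames[[1L]])[sel, , drop = FALSE], residues
  )$residue_index
  tibble::tibble(
    residue_index = idx,
    value = atan2(rowMeans(sin(mat)), rowMeans(cos(mat))) * 180 / pi
  )
}

circular_mean_deg <- function(x) {
  atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi
}

#' Closed-minus-open ensemble difference profile
#'
#' Combines per-simulation residue profiles into a closed-minus-open
#' difference. For linear metrics (RMSF) this is the difference of the
#' per-state arithmetic means. For angular metrics the per-state averages are
#' circular means and the difference is wrapped, with the absolute value
#' reported (in \[0, 180\] degrees).
#'
#' @param closed_profiles,open_profiles Lists of tibbles
#'   (`residue_index`, `value`), one per simulation in that state.
#' @param metric `"linear"` (e.g. RMSF, Angstrom) or `"angular"` (degrees).
#' @param tag Value for the output `metric` column.
#' @return Tibble `residue_index`, `metric`, `value`.
#' @export
ensemble_delta <- function(closed_profiles, open_profiles,
                           metric = c("linear", "angular"),
                           tag = NULL) {
  metric <- match.arg(metric)
  if (length(closed_profiles) == 0L || length(open_profiles) == 0L) {
    stop("need at least one profile per state", call. = FALSE)
  }
  idx <- closed_profiles[[1L]]$residue_index
  all_profiles <- c(closed_profiles, open_profiles)
  if (!all(vapply(all_profiles,
                  function(p) identical(p$residue_index, idx), logical(1L)))) {
    stop("profiles do not share a common residue set", call. = FALSE)
  }
  state_mean <- function(profiles) {
    mat <- vapply(profiles, function(p) p$value, numeric(length(idx)))
    mat <- matrix(mat, nrow = length(idx))
    if (metric == "angular") apply(mat, 1L, circular_mean_deg) else rowMeans(mat)
  }
  delta <- state_mean(closed_profiles) - state_mean(open_profiles)
  if (metric == "angular") delta <- abs(wrap_angle(delta))
  tibble::tibble(
    residue_index = idx,
    metric = if (is.null(tag)) paste0("delta_", metric) else tag,
    value = delta
  )
}
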