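#' Specification of a synthetic two-lobe hinge trajectory
#'
#' Describes a toy hinge protein of C-alpha pseudo-residues: two rigid
#' straight lobes joined at a hinge, plus a short static "latch" segment
#' placed just beyond the open position of the moving lobe. As the moving
#' lobe rotates open, contacts across the hinge separate monotonically
#' (closed-state contacts, expected positive time correlation) while the
#' lobe tip approaches the latch (open-state contacts, expected negative
#' correlation) — the minimal geometry reproducing both signs of the
#' contact-change matrix of a hinge-type binding protein.
#'
#' The defaults emulate one replicate of the study conditions at toy scale:
#' a 100 ns run sampled every 2.5 ns, an opening from 25 to 60 degrees, and
#' light positional jitter. The default schedule is spaced uniformly in
#' sin(angle/2), so the distance between equal-radius residues across the
#' hinge (2 r sin(angle/2)) grows exactly linearly in time: those
#' hinge-flank contacts carry a zero-noise time correlation of exactly +1
#' rather than merely close to it.
#'
#' @param residues_per_lobe Residues in each rigid lobe.
#' @param n_latch Residues in the static latch segment.
#' @param spacing Consecutive-residue spacing in Angstrom.
#' @param opening_schedule Lobe opening angle per frame (degrees, monotone
#'   non-decreasing), or `NULL` for the default 25-to-60 ramp (uniform in
#'   sin(angle/2)) over `n_frames`.
#' @param latch_angle Angular position of the latch (degrees), just beyond
#'   the final opening angle.
#' @param n_frames Frames when `opening_schedule` is `NULL`.
#' @param frame_interval Time between frames (ns).
#' @param noise_sigma Gaussian coordinate noise SD (Angstrom).
#' @param seed RNG seed for the noise.
#' @return A list of class `hinge_spec`.
#' @export
hinge_spec <- function(residues_per_lobe = 10L,
                       n_latch = 3L,
                       spacing = 3.8,
                       opening_schedule = NULL,
                       latch_angle = 64,
                       n_frames = 41L,
                       frame_interval = 2.5,
                       noise_sigma = 0.15,
                       seed = 1L) {
  if (is.null(opening_schedule)) {
    u <- seq(sin(25 / 2 * pi / 180), sin(60 / 2 * pi / 180),
             length.out = n_frames)
    opening_schedule <- 2 * asin(u) * 180 / pi
  }
  if (any(diff(opening_schedule) < 0)) {
    stop("opening schedule must be monotone non-decreasing", call. = FALSE)
  }
  structure(
    list(
      residues_per_lobe = as.integer(residues_per_lobe),
      n_latch = as.integer(n_latch),
      spacing = spacing,
      opening_schedule = opening_schedule,
      latch_angle = latch_angle,
      n_frames = length(opening_schedule),
      frame_interval = frame_interval,
      noise_sigma = noise_sigma,
      seed = seed
    ),
    class = "hinge_spec"
  )
}

# Residue layout:
#   1..n_latch                      static latch (at latch_angle)
#   next nA                         lobe A along angle 0, tip -> hinge
#   next 2                          hinge residues near the origin
#   next nB                         moving lobe B, hinge -> tip
hinge_layout <- function(spec) {
  nA <- spec$residues_per_lobe; nB <- spec$residues_per_lobe
  nL <- spec$n_latch; s <- spec$spacing
  latch <- seq_len(nL)
  lobe_a <- nL + seq_len(nA)
  hinge <- nL + nA + 1:2
  lobe_b <- nL + nA + 2L + seq_len(nB)
  th_l <- spec$latch_angle * pi / 180
  # static part (latch + lobe A + hinge); everything but one hinge atom is
  # coplanar so equal-radius cross-hinge distances are pure chords
  latch_r <- s * (nB - nL + seq_len(nL))           # radii near the B tip
  static_xyz <- rbind(
    cbind(latch_r * cos(th_l), latch_r * sin(th_l), 0),
    cbind(s * (nA:1), 0, 0),                       # lobe A, tip -> hinge
    rbind(c(0, 0, 0), c(0, 0, 1.9))                # hinge
  )
  list(nA = nA, nB = nB, nL = nL,
       latch = latch, lobe_a = lobe_a, hinge = hinge, lobe_b = lobe_b,
       static_xyz = static_xyz,
       lobe_b_radii = s * seq_len(nB))
}

hinge_frame_xyz <- function(layout, angle_deg) {
  th <- angle_deg * pi / 180
  rbind(
    layout$static_xyz,
    cbind(layout$lobe_b_radii * cos(th), layout$lobe_b_radii * sin(th), 0)
  )
}

#' Generate a synthetic hinge trajectory with ground truth
#'
#' Builds the trajectory described by a [hinge_spec()] and, from the
#' noiseless geometry alone (plain distance arithmetic, independent of the
#' contact/correlation machinery), the expected contact-change ground
#' truth: which residue pairs ever come within `r_start`, the sign of
#' their distance trend, and which of them are "perfect" pairs — distance
#' affine in time and never beyond `r_end`, so their zero-noise time
#' correlation is exactly +/-1.
#'
#' @param spec A [hinge_spec()].
#' @param r_start,r_end Contact cutoffs used for the ground truth
#'   (Angstrom); keep equal to the analysis configuration.
#' @param neighbor_exclusion Sequence-neighbour band excluded from the
#'   truth, matching the analysis default.
#' @return List of class `hinge_fixture`: `trajectory` (`hs_trajectory`),
#'   `spec`, and `truth` with `pairs` (tibble `i`, `j`, `sign`,
#'   `perfect`), `hinge_flank` (residues of the perfect separating pairs)
#'   and `lobes` (residue index lists).
#' @export
generate_hinge_trajectory <- function(spec = hinge_spec(),
                                      r_start = 5.0, r_end = 8.0,
                                      neighbor_exclusion = 2L) {
  layout <- hinge_layout(spec)
  n_res <- layout$nL + layout$nA + 2L + layout$nB
  frames_clean <- lapply(spec$opening_schedule, function(a) {
    hinge_frame_xyz(layout, a)
  })
  # frame-0 sanity: the lobes must not interpenetrate
  d0 <- as.matrix(stats::dist(frames_clean[[1L]]))
  diag(d0) <- Inf
  if (min(d0) < 0.5) {
    stop("invalid geometry: residues overlap at frame 0", call. = FALSE)
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  frames <- lapply(frames_clean, function(x) {
    if (spec$noise_sigma > 0) {
      x + matrix(stats::rnorm(length(x), sd = spec$noise_sigma), nrow(x), 3L)
    } else x
  })
  topology <- new_structure(
    tibble::tibble(
      residue_index = seq_len(n_res),
      residue_name = "GLY",
      atom_name = "CA",
      element = "C",
      chain = "A"
    ),
    frames[[1L]]
  )
  trajectory <- new_trajectory(topology, frames,
                               frame_interval = spec$frame_interval)
  truth <- hinge_truth(frames_clean, r_start, r_end, neighbor_exclusion)
  truth$lobes <- layout[c("latch", "lobe_a", "hinge", "lobe_b")]
  structure(list(trajectory = trajectory, spec = spec, truth = truth),
            class = "hinge_fixture")
}

# Expected nonzero contact-change pixels from noiseless coordinates:
# plain per-pair distance series, threshold crossing, and trend sign.
hinge_truth <- function(frames_clean, r_start, r_end, neighbor_exclusion) {
  n_res <- nrow(frames_clean[[1L]])
  dmats <- lapply(frames_clean, function(x) as.matrix(stats::dist(x)))
  rows <- list()
  for (i in seq_len(n_res - 1L)) {
    for (j in (i + 1L):n_res) {
      if (j - i <= neighbor_exclusion) next
      d <- vapply(dmats, function(m) m[i, j], numeric(1L))
      if (!any(d < r_start)) next
      trunc_d <- pmin(d, r_end)
      if (max(trunc_d) - min(trunc_d) < 1e-9) next    # constant: zero pixel
      mono <- all(diff(d) > 0) || all(diff(d) < 0)
      # affine in frame index (frames are equally spaced in time)
      n <- length(d)
      line <- d[1L] + (d[n] - d[1L]) * (seq_len(n) - 1L) / (n - 1L)
      affine <- max(abs(d - line)) < 1e-6
      rows[[length(rows) + 1L]] <- tibble::tibble(
        i = i, j = j,
        sign = as.integer(sign(d[length(d)] - d[1L])),
        perfect = mono && affine && max(d) <= r_end
      )
    }
  }
  pairs <- if (length(rows) > 0L) dplyr::bind_rows(rows) else {
    tibble::tibble(i = integer(), j = integer(), sign = integer(),
                   perfect = logical())
  }
  list(
    pairs = pairs,
    hinge_flank = sort(unique(unlist(
      pairs[pairs$perfect & pairs$sign > 0, c("i", "j")], use.names = FALSE
    )))
  )
}

#' Simulate a plate-reader fluorescence assay
#'
#' Generates a replicate-structured plate table with known true dF/F0:
#' `fluorescence = background + f0_level * (1 + dff0) + noise` per well,
#' plus a background-control series (the empty-vector lysate) of
#' `background + noise`. The defaults mirror the standard assay layout:
#' 3 biological x 3 technical replicates at 0, 1 and 100 mM ligand.
#'
#' @param true_dff0 Tibble `construct`, `maltose_mM`, `dff0` giving the true
#'   relative change at each nonzero concentration (0 mM is the baseline,
#'   dff0 = 0 by definition).
#' @param f0_level True background-free baseline fluorescence (a.u.).
#' @param background True background fluorescence (a.u.).
#' @param noise_sigma Gaussian well noise SD (a.u.).
#' @param n_bio,n_tech Biological / technical replicates.
#' @param concentrations Ligand concentrations (mM); must include 0.
#' @param control Label of the background-control series.
#' @param seed RNG seed.
#' @return Plate tibble (see [read_plate_csv()] for the schema).
#' @export
generate_plate_assay <- function(true_dff0,
                                 f0_level = 1000,
                                 background = 50,
                                 noise_sigma = 10,
                                 n_bio = 3L,
                                 n_tech = 3L,
                                 concentrations = c(0, 1, 100),
                                 control = "pET28a",
                                 seed = 1L) {
  stopifnot(f0_level > 0, 0 %in% concentrations)
  if (!is.null(seed)) set.seed(seed)
  constructs <- unique(true_dff0$construct)
  grid <- tidyr::expand_grid(
    construct = c(constructs, control),
    maltose_mM = concentrations,
    biological_rep = seq_len(n_bio),
    technical_rep = seq_len(n_tech)
  )
  truth_of <- function(construct, conc) {
    if (construct == control) return(NA_real_)
    if (conc == 0) return(0)
    hit <- true_dff0$dff0[true_dff0$construct == construct &
                            true_dff0$maltose_mM == conc]
    if (length(hit) == 0L) 0 else hit[1L]
  }
  signal <- purrr::map2_dbl(grid$construct, grid$maltose_mM, function(cs, cc) {
    t <- truth_of(cs, cc)
    if (is.na(t)) background else background + f0_level * (1 + t)
  })
  grid$fluorescence <- signal +
    if (noise_sigma > 0) stats::rnorm(nrow(grid), sd = noise_sigma) else 0
  grid
}
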