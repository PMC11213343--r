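#' Default analysis configuration
#'
#' Bundles the tunable parameters of the contact-hotspot pipeline. Distances
#' are in Angstrom, times in ns. The contact definition is hysteretic: a
#' contact begins when the closest-atom distance drops below `r_start`
#' (5 Angstrom) and only ends when it exceeds `r_end` (8 Angstrom), so
#' momentary flicker across a single cutoff is not over-interpreted.
#'
#' @param rmsd_threshold Open/closed RMSD boundary (Angstrom).
#' @param window_ns Averaging window for state calls and Delta-profiles (ns).
#' @param r_start Contact formation cutoff (Angstrom).
#' @param r_end Contact termination cutoff (Angstrom); also the truncation
#'   level for the distance series entering the time correlation.
#' @param percentile Cluster filter percentile (peaks and valleys ranked
#'   separately on mean, median and max-abs simultaneously).
#' @param insertion_stride Spacing of enumerated insertion sites (residues).
#' @param viability_threshold Absolute dF/F0 above which a sensor is called
#'   viable.
#' @param neighbor_exclusion Pairs with `|i - j| <=` this are skipped
#'   (sequence neighbours are permanently in contact and carry no signal).
#' @param selection_mode Atoms used for minimum distances: `"heavy"`
#'   (default), `"calpha"` or `"all"`.
#' @param cor_method `"distance"` correlates the truncated closest-atom
#'   distance with time (positive pixel = contact present early, i.e. in the
#'   closed state); `"indicator"` correlates the binary in-contact flag,
#'   sign-flipped to keep the same convention.
#' @return A list of class `hs_config`.
#' @export
analysis_config <- function(rmsd_threshold = 2.5,
                            window_ns = 50,
                            r_start = 5.0,
                            r_end = 8.0,
                            percentile = 99,
                            insertion_stride = 3L,
                            viability_threshold = 0.25,
                            neighbor_exclusion = 2L,
                            selection_mode = "heavy",
                            cor_method = c("distance", "indicator")) {
  stopifnot(r_start > 0, r_start < r_end, percentile > 0, percentile < 100,
            insertion_stride >= 1, neighbor_exclusion >= 0)
  structure(
    list(
      rmsd_threshold = rmsd_threshold, window_ns = window_ns,
      r_start = r_start, r_end = r_end, percentile = percentile,
      insertion_stride = as.integer(insertion_stride),
      viability_threshold = viability_threshold,
      neighbor_exclusion = as.integer(neighbor_exclusion),
      selection_mode = selection_mode,
      cor_method = match.arg(cor_method)
    ),
    class = "hs_config"
  )
}

#' Per-frame closest-atom distance between two residues
#'
#' @param trajectory An `hs_trajectory`.
#' @param i,j Residue indices (structure numbering), `i != j`.
#' @param selection_mode Atoms considered: `"heavy"`, `"calpha"` or `"all"`.
#' @return Numeric vector, one minimum inter-residue atom distance (Angstrom)
#'   per frame.
#' @export
pair_min_distance_series <- function(trajectory, i, j,
                                     selection_mode = "heavy") {
  if (i == j) stop("i and j must differ", call. = FALSE)
  sel <- select_atoms(trajectory$topology, selection_mode)
  res <- trajectory$topology$atoms$residue_index[sel]
  ai <- sel[res == i]; aj <- sel[res == j]
  if (length(ai) == 0L || length(aj) == 0L) {
    stop("no selected atoms for residue ", if (length(ai) == 0L) i else j,
         call. = FALSE)
  }
  vapply(seq_len(n_frames(trajectory)), function(f) {
    x <- frame_coords(trajectory, f)
    min(pair_dists(x[ai, , drop = FALSE], x[aj, , drop = FALSE]))
  }, numeric(1L))
}

pair_dists <- function(a, b) {
  # all pairwise Euclidean distances between rows of a and rows of b
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0))
}

#' Hysteresis contact state series
#'
#' Two-threshold state machine over a distance series: out of contact
#' initially; a contact begins at the first frame with distance `< r_start`
#' and ends at the first later frame with distance `> r_end`; re-entry
#' requires dropping below `r_start` again. Distances in between leave the
#' state unchanged.
#'
#' @param distances Numeric vector of per-frame distances (Angstrom).
#' @param r_start,r_end Formation / termination cutoffs, `r_start < r_end`.
#' @return Logical vector of in-contact flags with attribute
#'   `ever_in_contact`.
#' @export
hysteresis_contact_series <- function(distances, r_start = 5.0, r_end = 8.0) {
  stopifnot(r_start < r_end)
  in_contact <- logical(length(distances))
  state <- FALSE
  for (t in seq_along(distances)) {
    if (!state && distances[t] < r_start) state <- TRUE
    else if (state && distances[t] > r_end) state <- FALSE
    in_contact[t] <- state
  }
  structure(in_contact, ever_in_contact = any(in_contact))
}

#' Correlation of a contact distance series with time
#'
#' Pearson correlation between the truncated distance `min(d, r_end)` and
#' frame time. Truncation stops far-apart excursions (where the exact
#' distance is uninformative) from dominating the correlation. A series (or
#' time vector) with zero variance returns 0 by convention. Under the
#' adopted sign convention a positive value marks a contact present early in
#' the run — the closed state — and a negative value one that forms late,
#' in the open state.
#'
#' @param distances Per-frame distances (Angstrom).
#' @param times Frame times (ns), same length.
#' @param r_end Truncation level (Angstrom).
#' @param method `"distance"` (default) or `"indicator"`; the latter
#'   correlates the hysteresis in-contact flag with time, negated so the
#'   sign convention matches.
#' @param r_start Formation cutoff, used by the indicator method.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_vs_time <- function(distances, times, r_end = 8.0,
                            method = c("distance", "indicator"),
                            r_start = 5.0) {
  method <- match.arg(method)
  if (length(distances) < 2L) stop("need at least 2 frames", call. = FALSE)
  x <- switch(method,
    distance = pmin(distances, r_end),
    indicator = -as.numeric(hysteresis_contact_series(distances, r_start, r_end))
  )
  if (stats::sd(x) == 0 || stats::sd(times) == 0) return(0)
  stats::cor(x, times)
}

# Per-frame residue-by-residue minimum-distance matrices.
# Returns an n_res x n_res x n_frames array (residues in sorted order).
residue_distance_array <- function(trajectory, selection_mode = "heavy") {
  sel <- select_atoms(trajectory$topology, selection_mode)
  res_of_atom <- trajectory$topology$atoms$residue_index[sel]
  residues <- sort(unique(res_of_atom))
  n_res <- length(residues)
  one_atom <- !anyDuplicated(res_of_atom)
  groups <- if (!one_atom) split(seq_along(sel), res_of_atom) else NULL
  out <- array(0, dim = c(n_res, n_res, n_frames(trajectory)))
  for (f in seq_len(n_frames(trajectory))) {
    x <- frame_coords(trajectory, f)[sel, , drop = FALSE]
    if (one_atom) {
      ord <- match(residues, res_of_atom)
      out[, , f] <- as.matrix(stats::dist(x[ord, , drop = FALSE]))
    } else {
      d_atoms <- as.matrix(stats::dist(x))
      m <- matrix(0, n_res, n_res)
      for (a in seq_len(n_res - 1L)) {
        ia <- groups[[as.character(residues[a])]]
        for (b in (a + 1L):n_res) {
          ib <- groups[[as.character(residues[b])]]
          m[a, b] <- m[b, a] <- min(d_atoms[ia, ib])
        }
      }
      out[, , f] <- m
    }
  }
  attr(out, "residues") <- residues
  out
}

#' Pearson contact-change matrix of one trajectory
#'
#' For every residue pair further apart in sequence than the neighbour
#' exclusion and ever in (hysteresis-defined) contact during the run, the
#' pixel is the time correlation of the pair's truncated closest-atom
#' distance; every other pixel is 0. The matrix is symmetric with a zero
#' diagonal. Positive pixels mark contacts present early (closed state),
#' negative pixels contacts that form late (open state).
#'
#' @param trajectory An `hs_trajectory` with >= 2 frames.
#' @param config An [analysis_config()].
#' @return An `n x n` matrix of class `pearson_matrix` with residue indices
#'   as dimnames and attribute `residues`.
#' @export
build_pearson_matrix <- function(trajectory, config = analysis_config()) {
  if (n_frames(trajectory) < 2L) stop("need at least 2 frames", call. = FALSE)
  darr <- residue_distance_array(trajectory, config$selection_mode)
  residues <- attr(darr, "residues")
  n_res <- length(residues)
  m <- matrix(0, n_res, n_res)
  times <- trajectory$times
  for (a in seq_len(n_res - 1L)) {
    for (b in (a + 1L):n_res) {
      if (abs(residues[a] - residues[b]) <= config$neighbor_exclusion) next
      d <- darr[a, b, ]
      contact <- hysteresis_contact_series(d, config$r_start, config$r_end)
      if (!attr(contact, "ever_in_contact")) next
      m[a, b] <- m[b, a] <- pearson_vs_time(
        d, times, r_end = config$r_end,
        method = config$cor_method, r_start = config$r_start
      )
    }
  }
  new_pearson_matrix(m, residues)
}

new_pearson_matrix <- function(m, residues) {
  dimnames(m) <- list(residues, residues)
  structure(m, residues = as.integer(residues), class = "pearson_matrix")
}

#' Mean of Pearson matrices across simulations
#'
#' Pixel-wise arithmetic mean of per-simulation matrices (identical shapes
#' and residue sets required).
#'
#' @param matrices List of `pearson_matrix` objects.
#' @return A `pearson_matrix`.
#' @export
mean_pearson_matrix <- function(matrices) {
  if (length(matrices) == 0L) stop("empty matrix list", call. = FALSE)
  residues <- attr(matrices[[1L]], "residues")
  dims <- dim(matrices[[1L]])
  for (m in matrices) {
    if (!identical(dim(m), dims)) stop("matrix shape mismatch", call. = FALSE)
  }
  out <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  new_pearson_matrix(out, residues)
}

#' Contact-change matrix from a pair of static structures
#'
#' Treats the two structures as a 2-frame trajectory (times 0 and 1), so
#' every pixel is +1, -1 or 0 by construction: the crystal-pair analogue of
#' the trajectory matrix, useful to show what static end-points alone can
#' (and cannot) resolve.
#'
#' @param struct_a,struct_b `hs_structure`s with identical residue numbering
#'   (a goes first in time, e.g. the closed/holo structure).
#' @param config An [analysis_config()].
#' @return A `pearson_matrix` with values in \{-1, 0, +1\}.
#' @export
two_structure_matrix <- function(struct_a, struct_b,
                                 config = analysis_config()) {
  if (!identical(residue_indices(struct_a), residue_indices(struct_b))) {
    stop("residue numbering mismatch between structures", call. = FALSE)
  }
  traj <- new_trajectory(struct_a, list(struct_a$xyz, struct_b$xyz),
                         times = c(0, 1))
  build_pearson_matrix(traj, config)
}

#' @export
print.pearson_matrix <- function(x, ...) {
  nz <- sum(x[upper.tri(x)] != 0)
  cat("<pearson_matrix> ", nrow(x), " residues, ", nz,
      " nonzero contact pixels\n", sep = "")
  invisible(x)
}

#' Long-format view of a Pearson matrix
#'
#' @param x A `pearson_matrix`.
#' @param ... Unused.
#' @return Tibble `i`, `j`, `value` over the strict upper triangle
#'   (`i < j`, residue numbering).
#' @method tidy pearson_matrix
#' @export
tidy.pearson_matrix <- function(x, ...) {
  residues <- attr(x, "residues")
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    i = residues[ut[, 1L]],
    j = residues[ut[, 2L]],
    value = x[ut]
  )
}

#' Write / read a Pearson matrix as TSV
#'
#' `format = "long"` writes the nonzero upper-triangle pixels as
#' `i`, `j`, `value`; `"dense"` writes the full matrix with residue-index
#' column names. Both carry a `# residues:` header comment so the matrix can
#' be reconstructed.
#'
#' @param matrix A `pearson_matrix`.
#' @param path Output path.
#' @param format `"long"` or `"dense"`.
#' @export
write_pearson_matrix <- function(matrix, path, format = c("long", "dense")) {
  format <- match.arg(format)
  residues <- attr(matrix, "residues")
  header <- paste0("# residues: ", paste(residues, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (format == "long") {
    df <- dplyr::filter(tidy.pearson_matrix(matrix), .data$value != 0)
    writeLines("i\tj\tvalue", con)
    if (nrow(df) > 0L) {
      writeLines(sprintf("%d\t%d\t%.10g", df$i, df$j, df$value), con)
    }
  } else {
    writeLines(paste(residues, collapse = "\t"), con)
    for (r in seq_len(nrow(matrix))) {
      writeLines(paste(sprintf("%.10g", matrix[r, ]), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_pearson_matrix
#' @param path Path written by [write_pearson_matrix()] (long format).
#' @return `read_pearson_matrix()`: the reconstructed `pearson_matrix`.
#' @export
read_pearson_matrix <- function(path) {
  lines <- readLines(path)
  residues <- as.integer(strsplit(sub("^# residues: ", "", lines[1L]), ",")[[1L]])
  n <- length(residues)
  m <- matrix(0, n, n)
  body <- lines[-(1:2)]
  if (length(body) > 0L) {
    parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    i <- match(as.integer(parts[, 1L]), residues)
    j <- match(as.integer(parts[, 2L]), residues)
    v <- as.numeric(parts[, 3L])
    m[cbind(i, j)] <- v
    m[cbind(j, i)] <- v
  }
  new_pearson_matrix(m, residues)
}
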