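#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

write_manifest <- function(out_dir, subcommand, inputs, config, seed = NULL) {
  manifest <- list(
    subcommand = subcommand,
    inputs = inputs,
    config = unclass(config),
    seed = seed,
    package = "hingescan",
    version = as.character(utils::packageVersion("hingescan")),
    r_version = as.character(getRversion())
  )
  path <- file.path(out_dir, paste0(subcommand, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

write_profile_tsv <- function(profile, path) {
  readr::write_tsv(profile[, c("residue_index", "metric", "value")], path)
  invisible(path)
}

#' Load an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; absent keys keep their
#' defaults, and explicit `overrides` (e.g. command-line flags) win over the
#' file.
#'
#' @param path YAML path, or `NULL` for pure defaults.
#' @param overrides Named list of values taking precedence over the file.
#' @return An [analysis_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals <- utils::modifyList(vals, overrides)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

#' State classification and difference profiles for a trajectory ensemble
#'
#' Classifies each replicate trajectory open/closed from its RMSD series
#' (against frame 1, or `reference` when given), then forms the
#' closed-minus-open ensemble profiles over the final window: the
#' pseudo-dihedral difference and the RMSF difference. With a structure
#' pair, the static pseudo-dihedral difference profile is computed too.
#' Profiles are skipped with a warning when either state is unpopulated.
#'
#' @param trajectories List of `hs_trajectory` objects (the replicates).
#' @param out_dir Output directory (created if needed); TSV profiles, the
#'   state table and a run manifest are written there.
#' @param reference Optional `hs_structure` RMSD reference.
#' @param structure_pair Optional list of two `hs_structure`s (closed,
#'   open) for the static-pair dihedral profile.
#' @param config An [analysis_config()].
#' @return List: `states` (tibble, one row per trajectory), `profiles`
#'   (named list of tibbles; possibly empty).
#' @export
run_metrics <- function(trajectories, out_dir,
                        reference = NULL, structure_pair = NULL,
                        config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  states <- purrr::imap_dfr(trajectories, function(traj, idx) {
    rs <- rmsd_series(traj, reference = reference)
    st <- classify_state(rs, threshold = config$rmsd_threshold,
                         window_ns = config$window_ns)
    dplyr::mutate(st, trajectory = idx, .before = 1L)
  })
  message("state labels: ",
          paste(states$trajectory, states$label, sep = "=", collapse = ", "))
  profiles <- list()
  if (!is.null(structure_pair)) {
    profiles$ddihe_crys <- delta_dihe_structures(structure_pair[[1L]],
                                                 structure_pair[[2L]])
  }
  closed <- which(states$label == "closed")
  open <- which(states$label == "open")
  if (length(closed) > 0L && length(open) > 0L) {
    dihe <- lapply(trajectories, dihedral_md_profile,
                   window_ns = config$window_ns)
    rmsf <- lapply(trajectories, rmsf_profile, window_ns = config$window_ns)
    profiles$ddihe_md <- ensemble_delta(dihe[closed], dihe[open],
                                        metric = "angular", tag = "ddihe_md")
    profiles$drmsf <- ensemble_delta(rmsf[closed], rmsf[open],
                                     metric = "linear", tag = "drmsf")
  } else {
    warning("need both open and closed replicates for difference profiles; ",
            "skipping", call. = FALSE)
  }
  readr::write_tsv(states, file.path(out_dir, "states.tsv"))
  for (nm in names(profiles)) {
    write_profile_tsv(profiles[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  write_manifest(out_dir, "metrics",
                 list(n_trajectories = length(trajectories)), config)
  list(states = states, profiles = profiles)
}

#' Contact-change hotspot pipeline for a trajectory ensemble
#'
#' Keeps the replicates that undergo the closed-to-open transition (label
#' "open"), builds each one's Pearson contact-change matrix, averages them
#' pixel-wise, clusters, percentile-filters and enumerates insertion
#' sites.
#'
#' @inheritParams run_metrics
#' @return List: `states`, `mean_matrix` (`pearson_matrix`), `report`
#'   (`hotspot_report`).
#' @export
run_hotspots <- function(trajectories, out_dir, reference = NULL,
                         config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  states <- purrr::imap_dfr(trajectories, function(traj, idx) {
    rs <- rmsd_series(traj, reference = reference)
    st <- classify_state(rs, threshold = config$rmsd_threshold,
                         window_ns = config$window_ns)
    dplyr::mutate(st, trajectory = idx, .before = 1L)
  })
  open <- which(states$label == "open")
  if (length(open) == 0L) {
    stop("no open-state trajectories: nothing to analyse", call. = FALSE)
  }
  message(length(open), "/", length(trajectories),
          " replicates show the opening transition")
  matrices <- lapply(trajectories[open], build_pearson_matrix, config = config)
  mean_matrix <- mean_pearson_matrix(matrices)
  report <- hotspot_report(mean_matrix, config)
  message("clusters: ", nrow(report$clusters), "; retained at the ",
          config$percentile, "th percentile: ", nrow(report$retained))
  write_pearson_matrix(mean_matrix, file.path(out_dir, "mean_pearson.tsv"))
  write_hotspot_report(report, file.path(out_dir, "hotspots.json"))
  readr::write_tsv(states, file.path(out_dir, "states.tsv"))
  write_manifest(out_dir, "hotspots",
                 list(n_trajectories = length(trajectories),
                      n_open = length(open)), config)
  list(states = states, mean_matrix = mean_matrix, report = report)
}

#' Design constructs for a set of insertion sites
#'
#' Sites may be given explicitly or pulled from a hotspot report (JSON file
#' or `hotspot_report` object: the union of the retained clusters'
#' enumerated sites). Sites beyond the scaffold are reported per site and
#' skipped; the rest proceed.
#'
#' @param scaffold,effector Named amino-acid sequences (see
#'   [read_fasta_seq()]) or plain strings.
#' @param sites Integer sites, or `NULL` to use `report`.
#' @param report A `hotspot_report` or path to its JSON.
#' @param out_dir Output directory.
#' @param config An [analysis_config()] (echoed into the run manifest).
#' @return Tibble of constructs (see [batch_design()]).
#' @export
run_design <- function(scaffold, effector, sites = NULL, report = NULL,
                       out_dir = NULL, config = analysis_config()) {
  scaffold_id <- if (!is.null(names(scaffold))) names(scaffold)[1L] else "MBP"
  effector_id <- if (!is.null(names(effector))) names(effector)[1L] else "cpGFP"
  if (is.null(sites)) {
    if (is.null(report)) stop("give either sites or a hotspot report",
                              call. = FALSE)
    if (is.character(report)) {
      parsed <- jsonlite::read_json(report, simplifyVector = TRUE)
      sites <- sort(unique(unlist(parsed$retained$insertion_sites)))
    } else {
      sites <- sort(unique(unlist(report$retained$sites)))
    }
  }
  sites <- as.integer(sites)
  ok <- sites >= 1L & sites <= nchar(scaffold[[1L]]) - 1L
  for (bad in sites[!ok]) {
    warning("site ", bad, " outside scaffold range 1..",
            nchar(scaffold[[1L]]) - 1L, "; skipped", call. = FALSE)
  }
  designs <- batch_design(scaffold[[1L]], effector[[1L]], sites[ok],
                          scaffold_id = scaffold_id, effector_id = effector_id)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_constructs_fasta(designs, file.path(out_dir, "constructs.fasta"))
    readr::write_tsv(dplyr::select(designs, -"full_seq"),
                     file.path(out_dir, "constructs.tsv"))
    write_manifest(out_dir, "design",
                   list(scaffold = scaffold_id, effector = effector_id,
                        sites = sites[ok]), config)
  }
  designs
}

#' Score a plate assay and write sensor metrics
#'
#' @param plate Plate tibble or CSV path.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param config An [analysis_config()]; uses `viability_threshold`.
#' @param method dF/F0 computation order, see [sensor_metrics()].
#' @return A `sensor_metrics` object.
#' @export
run_assay <- function(plate, out_dir = NULL, config = analysis_config(),
                      method = "replicate") {
  if (is.character(plate)) plate <- read_plate_csv(plate)
  metrics <- sensor_metrics(plate, threshold = config$viability_threshold,
                            method = method)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(tibble::as_tibble(metrics),
                     file.path(out_dir, "sensor_metrics.tsv"))
    jsonlite::write_json(
      list(threshold = attr(metrics, "threshold"),
           method = attr(metrics, "method"),
           viability = attr(metrics, "viability")),
      file.path(out_dir, "sensor_metrics.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    write_manifest(out_dir, "assay", list(n_rows = nrow(plate)), config)
  }
  metrics
}

#' Write synthetic fixtures to disk
#'
#' Generates a hinge-trajectory replicate set (multi-model PDB, exercising
#' the real readers) and a simulated plate CSV.
#'
#' @param out_dir Output directory.
#' @param n_replicates Number of hinge trajectories.
#' @param seed Base seed; replicate k uses `seed + k - 1`.
#' @param noise_sigma Coordinate noise (Angstrom).
#' @param config An [analysis_config()]; contact cutoffs feed the ground
#'   truth and the manifest.
#' @return Invisible list of written paths.
#' @export
run_fixture <- function(out_dir, n_replicates = 3L, seed = 1L,
                        noise_sigma = 0.15, config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in seq_len(n_replicates)) {
    fx <- generate_hinge_trajectory(
      hinge_spec(noise_sigma = noise_sigma, seed = seed + k - 1L),
      r_start = config$r_start, r_end = config$r_end,
      neighbor_exclusion = config$neighbor_exclusion
    )
    p <- file.path(out_dir, sprintf("hinge_rep%02d.pdb", k))
    write_trajectory_pdb(fx$trajectory, p)
    paths <- c(paths, p)
  }
  truth <- tibble::tibble(
    construct = c("MBP_233-cpGFP", "MBP_233-cpGFP",
                  "MBP_131-cpGFP", "MBP_131-cpGFP"),
    maltose_mM = c(1, 100, 1, 100),
    dff0 = c(0.729, 0.741, 0.05, 0.05)
  )
  plate <- generate_plate_assay(truth, seed = seed)
  pp <- file.path(out_dir, "plate.csv")
  readr::write_csv(plate, pp)
  write_manifest(out_dir, "fixture",
                 list(n_replicates = n_replicates, noise_sigma = noise_sigma),
                 config, seed = seed)
  invisible(c(paths, pp))
}
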