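#' Read a plate-reader assay table
#'
#' Expects a CSV with the header columns `construct`, `maltose_mM`,
#' `biological_rep`, `technical_rep`, `fluorescence` (arbitrary units).
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_plate_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_plate(df)
}

validate_plate <- function(df) {
  need <- c("construct", "maltose_mM", "biological_rep", "technical_rep",
            "fluorescence")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("plate table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(df$fluorescence))) {
    stop("non-finite fluorescence values", call. = FALSE)
  }
  if (any(df$biological_rep < 1L) || any(df$technical_rep < 1L)) {
    stop("replicate indices must be positive", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Mean over technical replicates
#'
#' Collapses technical replicates to their arithmetic mean within each
#' construct x concentration x biological replicate condition.
#'
#' @param assay Plate tibble (see [read_plate_csv()]).
#' @return Tibble `construct`, `maltose_mM`, `biological_rep`,
#'   `fluorescence` (technical mean), `n_tech`.
#' @export
aggregate_technical <- function(assay) {
  assay <- validate_plate(assay)
  dplyr::summarise(
    dplyr::group_by(assay, .data$construct, .data$maltose_mM,
                    .data$biological_rep),
    n_tech = dplyr::n(),
    fluorescence = mean(.data$fluorescence),
    .groups = "drop"
  )
}

#' Subtract the background control
#'
#' Subtracts, per maltose concentration, the mean fluorescence of the
#' background control rows (empty-vector lysate, `pET28a` by default) from
#' every other condition. Errors if a concentration has no control rows.
#'
#' @param aggregated Output of [aggregate_technical()].
#' @param control Construct label of the background control.
#' @return `aggregated` without the control rows and with `fluorescence`
#'   background-subtracted.
#' @export
background_subtract <- function(aggregated, control = "pET28a") {
  ctrl <- dplyr::filter(aggregated, .data$construct == control)
  if (nrow(ctrl) == 0L) {
    stop("no background control rows labelled '", control, "'", call. = FALSE)
  }
  ctrl_means <- dplyr::summarise(
    dplyr::group_by(ctrl, .data$maltose_mM),
    background = mean(.data$fluorescence), .groups = "drop"
  )
  rest <- dplyr::filter(aggregated, .data$construct != control)
  missing <- setdiff(unique(rest$maltose_mM), ctrl_means$maltose_mM)
  if (length(missing) > 0L) {
    stop("no background control at maltose concentration(s): ",
         paste(missing, collapse = ", "), " mM", call. = FALSE)
  }
  out <- dplyr::left_join(rest, ctrl_means, by = "maltose_mM")
  out$fluorescence <- out$fluorescence - out$background
  dplyr::select(out, -"background")
}

#' Relative fluorescence change dF/F0
#'
#' `(F_X - F_0) / F_0`, the standard figure of merit for fluorescent
#' sensors. `F_0 = 0` is undefined: returned as `NA` with a warning (a
#' near-zero baseline inflates the ratio arbitrarily).
#'
#' @param f0 Baseline fluorescence at 0 mM ligand.
#' @param fx Fluorescence at the test concentration.
#' @return Numeric, sign preserved.
#' @export
delta_f_over_f0 <- function(f0, fx) {
  out <- (fx - f0) / f0
  if (any(f0 == 0)) {
    warning("F0 = 0: dF/F0 undefined, reported as NA", call. = FALSE)
    out[f0 == 0] <- NA_real_
  }
  out
}

#' Mean and SD across biological replicates
#'
#' @param x Numeric per-replicate values.
#' @return One-row tibble `mean`, `sd` (sample SD, `NA` for a single
#'   replicate), `n`.
#' @export
summarize_biological <- function(x) {
  tibble::tibble(
    mean = mean(x, na.rm = TRUE),
    sd = if (sum(!is.na(x)) >= 2L) stats::sd(x, na.rm = TRUE) else NA_real_,
    n = sum(!is.na(x))
  )
}

#' Full assay pipeline: plate table to sensor metrics
#'
#' Technical-replicate means, background subtraction, dF/F0 against the
#' 0 mM baseline, aggregation across biological replicates, and a viability
#' call (`|dF/F0| >` threshold at any concentration).
#'
#' `method = "replicate"` (default) computes dF/F0 within each biological
#' replicate and then averages, so the reported SD reflects true replicate
#' scatter. `method = "pooled"` first averages the background-subtracted
#' fluorescence across biological replicates and takes the ratio of the
#' means — the convention behind published single-number dF/F0 tables.
#'
#' @param assay Plate tibble (see [read_plate_csv()]).
#' @param control Background-control construct label.
#' @param threshold Viability threshold on |dF/F0|.
#' @param method `"replicate"` or `"pooled"`.
#' @return A `sensor_metrics` object: tibble `construct`, `maltose_mM`,
#'   `dff0_mean`, `dff0_sd`, `n_bio`, `viable_at` plus attribute
#'   `viability` (per-construct tibble).
#' @export
sensor_metrics <- function(assay, control = "pET28a", threshold = 0.25,
                           method = c("replicate", "pooled")) {
  method <- match.arg(method)
  corrected <- background_subtract(aggregate_technical(assay), control)
  baseline_of <- function(df) {
    f0 <- df$fluorescence[df$maltose_mM == 0]
    if (length(f0) == 0L) {
      stop("no 0 mM baseline for construct ", df$construct[1L], call. = FALSE)
    }
    mean(f0)
  }
  if (method == "replicate") {
    per_rep <- dplyr::group_modify(
      dplyr::group_by(corrected, .data$construct, .data$biological_rep),
      function(df, key) {
        f0 <- baseline_of(df)
        df <- df[df$maltose_mM != 0, , drop = FALSE]
        tibble::tibble(
          maltose_mM = df$maltose_mM,
          dff0 = delta_f_over_f0(f0, df$fluorescence)
        )
      }
    )
    per_rep <- dplyr::ungroup(per_rep)
    out <- dplyr::group_modify(
      dplyr::group_by(per_rep, .data$construct, .data$maltose_mM),
      function(df, key) summarize_biological(df$dff0)
    )
    out <- dplyr::rename(dplyr::ungroup(out),
                         dff0_mean = "mean", dff0_sd = "sd", n_bio = "n")
  } else {
    pooled <- dplyr::summarise(
      dplyr::group_by(corrected, .data$construct, .data$maltose_mM),
      fluorescence = mean(.data$fluorescence),
      n_bio = dplyr::n(), .groups = "drop"
    )
    out <- dplyr::group_modify(
      dplyr::group_by(pooled, .data$construct),
      function(df, key) {
        f0 <- baseline_of(df)
        df <- df[df$maltose_mM != 0, , drop = FALSE]
        tibble::tibble(
          maltose_mM = df$maltose_mM,
          dff0_mean = delta_f_over_f0(f0, df$fluorescence),
          dff0_sd = NA_real_,
          n_bio = df$n_bio
        )
      }
    )
    out <- dplyr::ungroup(out)
  }
  out$viable_at <- !is.na(out$dff0_mean) & abs(out$dff0_mean) > threshold
  viability <- dplyr::summarise(
    dplyr::group_by(out, .data$construct),
    max_abs_dff0 = max(abs(.data$dff0_mean), na.rm = TRUE),
    viable = any(.data$viable_at),
    .groups = "drop"
  )
  structure(out,
            class = c("sensor_metrics", class(out)),
            viability = viability, threshold = threshold, method = method)
}

#' Per-construct viability calls
#'
#' A sensor is viable when any concentration's |dF/F0| exceeds the
#' threshold (0.25 by default).
#'
#' @param metrics A `sensor_metrics` object, or a tibble with `construct`
#'   and `dff0_mean`.
#' @param threshold Absolute dF/F0 cutoff.
#' @return Tibble `construct`, `max_abs_dff0`, `viable`.
#' @export
classify_viability <- function(metrics, threshold = 0.25) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(metrics), .data$construct),
    max_abs_dff0 = max(abs(.data$dff0_mean), na.rm = TRUE),
    viable = .data$max_abs_dff0 > threshold,
    .groups = "drop"
  )
}

#' @method glance sensor_metrics
#' @export
glance.sensor_metrics <- function(x, ...) {
  v <- attr(x, "viability")
  tibble::tibble(
    n_constructs = nrow(v),
    n_viable = sum(v$viable),
    threshold = attr(x, "threshold"),
    method = attr(x, "method")
  )
}
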