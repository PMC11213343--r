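#' Heatmap of a Pearson contact-change matrix
#'
#' Diverging heatmap over residue pairs: blue pixels are contacts present
#' early (closed state), red pixels contacts that form late (open state).
#'
#' @param object A `pearson_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pearson_matrix
#' @export
autoplot.pearson_matrix <- function(object, ...) {
  df <- tidy.pearson_matrix(object)
  df <- dplyr::bind_rows(df, dplyr::rename(df, i = "j", j = "i"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy", limits = c(-1, 1),
                                  name = "r") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue i", y = "residue j") +
    ggplot2::theme_minimal()
}

#' Per-residue profile plot
#'
#' @param profile Tibble with `residue_index`, `metric`, `value` (one or
#'   more metrics; facetted when several).
#' @return A ggplot.
#' @export
plot_residue_profile <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$residue_index,
                                             y = .data$value)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::labs(x = "residue", y = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(profile$metric)) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$metric), ncol = 1L,
                                 scales = "free_y")
  }
  p
}

#' RMSD traces of a trajectory ensemble
#'
#' @param series_list Named list of tibbles from [rmsd_series()].
#' @param threshold Horizontal guide (Angstrom); `NULL` to omit.
#' @return A ggplot.
#' @export
plot_rmsd_traces <- function(series_list, threshold = 2.5) {
  df <- purrr::imap_dfr(series_list, function(s, nm) {
    dplyr::mutate(s, replicate = as.character(nm))
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ns, y = .data$rmsd,
                                        colour = .data$replicate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "RMSD (Å)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Bar plot of sensor dF/F0 with replicate SD
#'
#' @param object A `sensor_metrics` object.
#' @param ... Unused.
#' @return A ggplot with the viability threshold marked.
#' @method autoplot sensor_metrics
#' @export
autoplot.sensor_metrics <- function(object, ...) {
  df <- tibble::as_tibble(object)
  thr <- attr(object, "threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$construct, y = .data$dff0_mean,
                                   fill = factor(.data$maltose_mM))) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$dff0_mean - .data$dff0_sd,
                   ymax = .data$dff0_mean + .data$dff0_sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(Delta * F / F[0]),
                  fill = "maltose (mM)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
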