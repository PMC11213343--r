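#' Extract contiguous same-sign clusters from a Pearson matrix
#'
#' Nonzero pixels of the strict upper triangle are grouped into connected
#' components of like sign under 8-connectivity (diagonal adjacency joins
#' pixels, matching how blobs group visually on a heatmap). Positive
#' clusters are "peaks" (contacts of the closed state), negative clusters
#' "valleys" (contacts of the open state); zero pixels separate clusters.
#'
#' @param matrix A `pearson_matrix` (or plain symmetric numeric matrix).
#' @return Tibble, one row per cluster: `cluster`, `sign` (+1/-1),
#'   `n_pixels`, the summary statistics `mean`, `median`, `max_abs`, the
#'   inclusive residue spans `span_i_start`, `span_i_end`, `span_j_start`,
#'   `span_j_end`, and list-columns `pixels` (tibble `i`, `j`, `value`) and
#'   `residue_union` (sorted residues touched on either axis).
#' @export
extract_clusters <- function(matrix) {
  if (nrow(matrix) != ncol(matrix)) stop("matrix must be square", call. = FALSE)
  residues <- attr(matrix, "residues")
  if (is.null(residues)) residues <- seq_len(nrow(matrix))
  ut <- which(upper.tri(matrix) & matrix != 0, arr.ind = TRUE)
  empty <- tibble::tibble(
    cluster = integer(), sign = integer(), n_pixels = integer(),
    mean = numeric(), median = numeric(), max_abs = numeric(),
    span_i_start = integer(), span_i_end = integer(),
    span_j_start = integer(), span_j_end = integer(),
    pixels = list(), residue_union = list()
  )
  if (nrow(ut) == 0L) return(empty)
  vals <- matrix[ut]
  sgn <- sign(vals)
  # 8-connectivity graph over same-sign pixels; components = clusters
  key <- function(r, c) paste(r, c)
  id_of <- stats::setNames(seq_len(nrow(ut)), key(ut[, 1L], ut[, 2L]))
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  edges <- integer(0)
  for (k in seq_len(nrow(offsets))) {
    nb <- key(ut[, 1L] + offsets$dr[k], ut[, 2L] + offsets$dc[k])
    hit <- !is.na(id_of[nb])
    from <- which(hit)
    to <- unname(id_of[nb[hit]])
    same <- sgn[from] == sgn[to]
    edges <- c(edges, rbind(from[same], to[same]))
  }
  g <- igraph::make_graph(edges, n = nrow(ut), directed = FALSE)
  comp <- igraph::components(g)$membership
  purrr::map_dfr(sort(unique(comp)), function(cl) {
    rows <- which(comp == cl)
    px <- tibble::tibble(
      i = residues[ut[rows, 1L]],
      j = residues[ut[rows, 2L]],
      value = vals[rows]
    )
    tibble::tibble(
      cluster = cl,
      sign = as.integer(sgn[rows[1L]]),
      n_pixels = length(rows),
      mean = mean(px$value),
      median = stats::median(px$value),
      max_abs = max(abs(px$value)),
      span_i_start = min(px$i), span_i_end = max(px$i),
      span_j_start = min(px$j), span_j_end = max(px$j),
      pixels = list(px),
      residue_union = list(sort(unique(c(px$i, px$j))))
    )
  })
}

#' Summary statistics of a set of cluster pixel values
#'
#' @param values Numeric vector of pixel values (all one sign).
#' @return One-row tibble `mean`, `median`, `max_abs`.
#' @export
cluster_statistics <- function(values) {
  if (length(values) == 0L) stop("empty cluster", call. = FALSE)
  tibble::tibble(
    mean = mean(values),
    median = stats::median(values),
    max_abs = max(abs(values))
  )
}

#' Percentile filter of clusters
#'
#' Peaks and valleys are ranked separately. Within each sign group the
#' interpolated `percentile`-th percentile of the cluster means, medians and
#' max-abs values is taken (valleys on |mean| and |median| so "top" means
#' most extreme for both signs), and a cluster is retained only when it
#' meets or exceeds all three thresholds simultaneously. With the
#' interpolated quantile a singleton group retains its only cluster.
#' Raising the percentile never adds clusters.
#'
#' @param clusters Tibble from [extract_clusters()].
#' @param percentile In (0, 100); default 99.
#' @return The retained subset of `clusters`.
#' @export
percentile_filter <- function(clusters, percentile = 99) {
  stopifnot(percentile > 0, percentile < 100)
  if (nrow(clusters) == 0L) return(clusters)
  p <- percentile / 100
  keep_group <- function(df) {
    m <- abs(df$mean); md <- abs(df$median); mx <- df$max_abs
    df[m >= stats::quantile(m, p) &
         md >= stats::quantile(md, p) &
         mx >= stats::quantile(mx, p), , drop = FALSE]
  }
  out <- dplyr::group_by(clusters, .data$sign)
  out <- dplyr::group_modify(out, function(df, key) keep_group(df))
  dplyr::arrange(dplyr::ungroup(out), .data$cluster)
}

#' Residue ranges of a cluster
#'
#' @param cluster One row of an [extract_clusters()] tibble.
#' @return List with `span_i`, `span_j` (inclusive `c(start, end)` ranges)
#'   and `residue_union` (sorted union of both axes' residues).
#' @export
hotspot_residues <- function(cluster) {
  if (nrow(cluster) != 1L) stop("pass exactly one cluster row", call. = FALSE)
  list(
    span_i = c(cluster$span_i_start, cluster$span_i_end),
    span_j = c(cluster$span_j_start, cluster$span_j_end),
    residue_union = cluster$residue_union[[1L]]
  )
}

#' Enumerate insertion sites across a residue range
#'
#' Arithmetic sequence from `start` in steps of `stride`, always including
#' `end` (so e.g. 205-217 at stride 3 gives 205, 208, 211, 214, 217 and
#' 224-233 gives 224, 227, 230, 233).
#'
#' @param start,end Inclusive residue range, `start <= end`.
#' @param stride Step in residues, >= 1.
#' @return Integer vector of sites.
#' @export
enumerate_insertion_sites <- function(start, end, stride = 3L) {
  if (start > end) stop("invalid range: start > end", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  sites <- seq(as.integer(start), as.integer(end), by = as.integer(stride))
  if (sites[length(sites)] != end) sites <- c(sites, as.integer(end))
  sites
}

#' Full hotspot report of a mean Pearson matrix
#'
#' Clusters the matrix, applies the percentile filter, and enumerates
#' candidate insertion sites across each retained cluster's residue union
#' (split into runs of consecutive residues).
#'
#' @param matrix A `pearson_matrix` (typically the ensemble mean).
#' @param config An [analysis_config()]; uses `percentile` and
#'   `insertion_stride`.
#' @return A `hotspot_report`: list with `clusters` (all), `retained`
#'   (filtered, plus a `sites` list-column), `percentile`, `stride`.
#' @export
hotspot_report <- function(matrix, config = analysis_config()) {
  clusters <- extract_clusters(matrix)
  retained <- percentile_filter(clusters, config$percentile)
  if (nrow(retained) > 0L) {
    retained$sites <- purrr::map(retained$residue_union, function(u) {
      runs <- split(u, cumsum(c(1L, diff(u) != 1L)))
      sort(unique(unlist(purrr::map(runs, function(r) {
        enumerate_insertion_sites(min(r), max(r), config$insertion_stride)
      }), use.names = FALSE)))
    })
  } else {
    retained$sites <- list()
  }
  structure(
    list(clusters = clusters, retained = retained,
         percentile = config$percentile, stride = config$insertion_stride),
    class = "hotspot_report"
  )
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat("<hotspot_report> ", nrow(x$clusters), " clusters (",
      sum(x$clusters$sign > 0), " peaks, ", sum(x$clusters$sign < 0),
      " valleys); ", nrow(x$retained), " retained at the ", x$percentile,
      "th percentile\n", sep = "")
  invisible(x)
}

#' Retained clusters of a hotspot report as a flat tibble
#' @param x A `hotspot_report`.
#' @param ... Unused.
#' @method tidy hotspot_report
#' @export
tidy.hotspot_report <- function(x, ...) {
  dplyr::select(x$retained, -"pixels")
}

#' One-row summary of a hotspot report
#' @param x A `hotspot_report`.
#' @param ... Unused.
#' @method glance hotspot_report
#' @export
glance.hotspot_report <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_peaks = sum(x$clusters$sign > 0),
    n_valleys = sum(x$clusters$sign < 0),
    n_retained = nrow(x$retained),
    percentile = x$percentile
  )
}

#' Write a hotspot report as JSON
#'
#' @param report A `hotspot_report`.
#' @param path Output path.
#' @export
write_hotspot_report <- function(report, path) {
  ret <- report$retained
  clusters <- purrr::pmap(ret, function(...) {
    row <- list(...)
    list(
      sign = row$sign,
      n_pixels = row$n_pixels,
      stats = list(mean = row$mean, median = row$median,
                   max_abs = row$max_abs),
      span_i = c(row$span_i_start, row$span_i_end),
      span_j = c(row$span_j_start, row$span_j_end),
      residue_union = row$residue_union,
      insertion_sites = row$sites
    )
  })
  jsonlite::write_json(
    list(percentile = report$percentile, stride = report$stride,
         n_clusters_total = nrow(report$clusters), retained = clusters),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
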