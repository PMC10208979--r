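#' Clustering parameters for DNA-PAINT localizations
#'
#' @param r Lateral clustering radius, nm. A good starting value is about
#'   twice the localization precision of the underlying measurement.
#' @param n_min Minimum localizations per cluster: clusters with
#'   `<= n_min` members are dissolved (the threshold is strict).
#' @param r_z Axial radius, nm (3D data; localizations in z spread about
#'   twofold wider than laterally, so typically `r_z = 2 r`).
#' @param edge_fraction Excluded mean-frame band at the start and end of
#'   the acquisition (default 0.20: clusters whose mean frame falls in
#'   the first or last 20% of frames are rejected).
#' @param n_windows Number of equal temporal windows (default 20, i.e.
#'   5% of frames each).
#' @param window_max_fraction Maximum fraction of a cluster's
#'   localizations allowed in any one window (default 0.80).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(r, n_min, r_z = NULL, edge_fraction = 0.20,
                           n_windows = 20, window_max_fraction = 0.80) {
  if (r <= 0) stop("r must be > 0")
  if (!is.null(r_z) && r_z <= 0) stop("r_z must be > 0")
  if (n_min < 1) stop("n_min must be >= 1")
  if (edge_fraction < 0 || edge_fraction >= 0.5)
    stop("edge_fraction must be in [0, 0.5)")
  if (n_windows < 1) stop("n_windows must be >= 1")
  if (window_max_fraction <= 0 || window_max_fraction > 1)
    stop("window_max_fraction must be in (0, 1]")
  structure(list(r = r, r_z = r_z, n_min = as.integer(n_min),
                 edge_fraction = edge_fraction,
                 n_windows = as.integer(n_windows),
                 window_max_fraction = window_max_fraction),
            class = "cluster_params")
}

check_dim_params <- function(table, params) {
  if (is_3d(table) && is.null(params$r_z))
    stop("3D table requires r_z")
}

#' Neighbour counts within the clustering radius
#'
#' For each localization, the number of other localizations within
#' distance `r` (2D) or within the ellipsoid defined by the scaled norm
#' `sqrt(dx^2 + dy^2 + (dz * r / r_z)^2) <= r` (3D).
#'
#' @param table A [loc_table()] (single channel).
#' @param params A [cluster_params()].
#' @return Integer vector of neighbour counts.
#' @export
neighbor_counts <- function(table, params) {
  stopifnot(inherits(table, "loc_table"), inherits(params, "cluster_params"))
  if (nrow(table) == 0) stop("table is empty")
  check_dim_params(table, params)
  z <- if (is_3d(table)) table$z else numeric(0)
  cpp_neighbor_counts(table$x, table$y, z, is_3d(table),
                      params$r, if (is.null(params$r_z)) params$r else params$r_z)
}

#' Local maxima of the neighbour-count field
#'
#' A localization is a local maximum when no localization within its `r`
#' neighbourhood has a larger neighbour count; exact ties are broken in
#' favour of the lowest index, so a flat-topped cloud still yields
#' exactly one maximum.
#'
#' @inheritParams neighbor_counts
#' @param counts Neighbour counts from [neighbor_counts()] (computed if
#'   missing).
#' @return Sorted integer vector of localization indices (1-based).
#' @export
find_local_maxima <- function(table, params, counts = NULL) {
  stopifnot(inherits(table, "loc_table"), inherits(params, "cluster_params"))
  check_dim_params(table, params)
  if (is.null(counts)) counts <- neighbor_counts(table, params)
  z <- if (is_3d(table)) table$z else numeric(0)
  cpp_local_maxima(table$x, table$y, z, is_3d(table),
                   params$r, if (is.null(params$r_z)) params$r else params$r_z,
                   counts)
}

#' Cluster DNA-PAINT localizations into per-target groups
#'
#' Implements the density-peak clusterer used for RESI: neighbour counts
#' within radius `r`, local maxima of the count field, radius-`r`
#' assignment around each maximum (maxima processed in decreasing count
#' order; localizations are never shared between clusters), dissolution
#' of clusters with `<= n_min` members, and two temporal artifact
#' filters. The mean-frame filter rejects clusters whose mean frame lies
#' in the first or last `edge_fraction` of the acquisition (boundary
#' inclusive): genuine repetitive blinking centres the mean frame near
#' half the acquisition. The window filter partitions the acquisition
#' into `n_windows` equal windows and rejects clusters with more than
#' `window_max_fraction` of their localizations in any single window —
#' the signature of a long-lived sticking event.
#'
#' @inheritParams neighbor_counts
#' @return A `cluster_result`: list with `assignment` (integer per
#'   localization, 0 = unassigned, negative = member of a rejected
#'   cluster) and `clusters` (data frame: id, n, centroid x/y(/z),
#'   mean_frame, max_window_fraction, status in
#'   `kept | rejected_mean_frame | rejected_window`).
#' @export
cluster_locs <- function(table, params) {
  stopifnot(inherits(table, "loc_table"), inherits(params, "cluster_params"))
  if (nrow(table) == 0) stop("table is empty")
  check_dim_params(table, params)
  meta <- loc_meta(table)
  if (is.null(meta$n_frames)) stop("n_frames metadata required for temporal filters")
  n_frames <- meta$n_frames

  counts <- neighbor_counts(table, params)
  maxima <- find_local_maxima(table, params, counts)
  z <- if (is_3d(table)) table$z else numeric(0)
  rz <- if (is.null(params$r_z)) params$r else params$r_z
  assign <- cpp_assign_clusters(table$x, table$y, z, is_3d(table),
                                params$r, rz, counts, maxima)

  # dissolve clusters not exceeding n_min members (strict threshold)
  sizes <- tabulate(assign, nbins = max(assign, 0L))
  small <- which(sizes <= params$n_min)
  if (length(small)) assign[assign %in% small] <- 0L

  ids <- sort(unique(assign[assign > 0L]))
  if (length(ids) == 0) {
    return(structure(list(assignment = assign,
                          clusters = empty_cluster_df(is_3d(table)),
                          params = params, n_frames = n_frames),
                     class = "cluster_result"))
  }

  win_len <- n_frames / params$n_windows
  rows <- lapply(seq_along(ids), function(j) {
    sel <- assign == ids[j]
    fr <- table$frame[sel]
    mf <- mean(fr)
    wi <- pmin(floor(fr / win_len), params$n_windows - 1L)
    mwf <- max(tabulate(wi + 1L, nbins = params$n_windows)) / length(fr)
    status <- if (mf <= params$edge_fraction * n_frames ||
                  mf >= (1 - params$edge_fraction) * n_frames)
      "rejected_mean_frame"
    else if (mwf > params$window_max_fraction) "rejected_window"
    else "kept"
    data.frame(id = j, n = sum(sel),
               x = mean(table$x[sel]), y = mean(table$y[sel]),
               z = if (is_3d(table)) mean(table$z[sel]) else NA_real_,
               mean_frame = mf, max_window_fraction = mwf,
               status = status)
  })
  clusters <- do.call(rbind, rows)
  if (!is_3d(table)) clusters$z <- NULL

  # renumber assignment to 1..k and mark rejected clusters negative
  new_id <- integer(max(assign))
  new_id[ids] <- seq_along(ids)
  remapped <- ifelse(assign > 0L, new_id[pmax(assign, 1L)], 0L)
  rejected <- clusters$id[clusters$status != "kept"]
  remapped[remapped %in% rejected] <- -remapped[remapped %in% rejected]

  structure(list(assignment = remapped, clusters = clusters,
                 params = params, n_frames = n_frames),
            class = "cluster_result")
}

empty_cluster_df <- function(three_d) {
  df <- data.frame(id = integer(0), n = integer(0), x = numeric(0),
                   y = numeric(0), z = numeric(0), mean_frame = numeric(0),
                   max_window_fraction = numeric(0), status = character(0))
  if (!three_d) df$z <- NULL
  df
}

#' @export
print.cluster_result <- function(x, ...) {
  k <- table(factor(x$clusters$status,
                    levels = c("kept", "rejected_mean_frame", "rejected_window")))
  cat(sprintf("Cluster result: %d clusters (%d kept, %d rejected mean-frame, %d rejected window)\n",
              nrow(x$clusters), k[["kept"]], k[["rejected_mean_frame"]],
              k[["rejected_window"]]))
  cat(sprintf("  unassigned localizations: %d\n", sum(x$assignment == 0L)))
  invisible(x)
}

#' Suggest a minimum-cluster-size threshold from pick statistics
#'
#' Given per-pick localization counts from manually picked clouds, finds
#' the antimode separating the background mode from the single-target
#' mode of the (bimodal) count histogram; that value is a suitable
#' `n_min`. Unimodal or insufficient input is flagged instead.
#'
#' @param pick_counts Integer vector of localizations per pick.
#' @return List with `bimodal` (logical), `threshold` (suggested n_min,
#'   NA when not bimodal), `flag` (`"ok"`, `"unimodal"` or
#'   `"insufficient"`), and the histogram (`hist` object).
#' @export
suggest_n_min <- function(pick_counts) {
  if (length(pick_counts) == 0) stop("pick_counts is empty")
  h <- graphics::hist(pick_counts,
                      breaks = if (length(pick_counts) >= 10) "FD" else "Sturges",
                      plot = FALSE)
  if (length(pick_counts) < 10)
    return(list(bimodal = FALSE, threshold = NA_real_,
                flag = "insufficient", hist = h))
  d <- tryCatch(stats::density(pick_counts, bw = "SJ", n = 512),
                error = function(e) stats::density(pick_counts, n = 512))
  y <- d$y
  is_peak <- which(diff(sign(diff(y))) == -2) + 1L
  # keep substantial peaks only (>= 5% of the main peak)
  is_peak <- is_peak[y[is_peak] >= 0.05 * max(y)]
  if (length(is_peak) < 2)
    return(list(bimodal = FALSE, threshold = NA_real_,
                flag = "unimodal", hist = h))
  top2 <- is_peak[order(y[is_peak], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  antimode <- d$x[lo + which.min(y[lo:hi]) - 1L]
  list(bimodal = TRUE, threshold = antimode, flag = "ok", hist = h)
}
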