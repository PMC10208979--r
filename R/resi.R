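#' Inverse-variance weighted centre of a localization group
#'
#' The centre of a group of localizations is the weighted mean with
#' weights `w_i = 1 / lp_i^2` (the maximum-likelihood estimator of a
#' common mean under independent Gaussian errors):
#' \deqn{\bar{x}_{wtd} = \sum w_i x_i / \sum w_i.}
#' Its precision is the weighted s.e.m.
#' \deqn{(s_{\bar{x}})_{wtd} = \sqrt{Var(x)_{wtd} / N}, \quad
#'       Var(x)_{wtd} = \frac{N}{N-1}
#'       \frac{\sum w_i (x_i - \bar{x}_{wtd})^2}{\sum w_i}.}
#' With equal weights this reduces to the arithmetic mean and the
#' ordinary Bessel-corrected s.e.m.
#'
#' @param xs Coordinate values (nm).
#' @param lps Localization precisions (nm), same length, all > 0.
#' @return List with `mean` and `sem` (`sem` is `NA` for a single value).
#' @examples
#' weighted_center(c(0, 3), c(1, sqrt(2)))  # mean 1
#' @export
weighted_center <- function(xs, lps) {
  n <- length(xs)
  if (n == 0) stop("empty input")
  if (length(lps) != n) stop("xs and lps lengths differ")
  if (any(!is.finite(lps)) || any(lps <= 0))
    stop("localization precisions must be positive")
  w <- 1 / lps^2
  m <- sum(w * xs) / sum(w)
  if (n == 1) return(list(mean = m, sem = NA_real_))
  var_wtd <- n / (n - 1) * sum(w * (xs - m)^2) / sum(w)
  list(mean = m, sem = sqrt(var_wtd / n))
}

#' Collapse kept clusters into RESI super-localizations
#'
#' One output localization per kept cluster: x and y are inverse-variance
#' weighted means of the member localizations, z (3D) the unweighted
#' mean. The reported precision is the average of the x and y weighted
#' s.e.m.; axial precision is taken as twice the lateral precision. The
#' result is itself a localization table (with `lp` set to the RESI
#' precision), so downstream SMLM renderers treat it as any other
#' localization file.
#'
#' @param table The clustered [loc_table()].
#' @param clusters The matching [cluster_locs()] result.
#' @return A `resi_table`: a [loc_table()] with extra columns `K`
#'   (grouped localizations), `cluster_id`, and for 3D data `lp_z`.
#' @export
collapse_clusters <- function(table, clusters) {
  stopifnot(inherits(table, "loc_table"), inherits(clusters, "cluster_result"))
  if (length(clusters$assignment) != nrow(table))
    stop("cluster assignment does not match table")
  three_d <- is_3d(table)
  kept <- clusters$clusters$id[clusters$clusters$status == "kept"]
  rows <- lapply(kept, function(id) {
    sel <- clusters$assignment == id
    wx <- weighted_center(table$x[sel], table$lp[sel])
    wy <- weighted_center(table$y[sel], table$lp[sel])
    prec <- (wx$sem + wy$sem) / 2
    data.frame(x = wx$mean, y = wy$mean,
               z = if (three_d) mean(table$z[sel]) else NA_real_,
               frame = floor(mean(table$frame[sel])),
               lp = prec,
               channel = table$channel[which(sel)[1]],
               K = sum(sel), cluster_id = id)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        frame = integer(0), lp = numeric(0),
                        channel = integer(0), K = integer(0),
                        cluster_id = integer(0))
  if (!three_d) df$z <- NULL
  out <- relaxed_loc_table(df, loc_meta(table))
  out$K <- df$K
  out$cluster_id <- df$cluster_id
  if (three_d) out$lp_z <- 2 * df$lp
  class(out) <- c("resi_table", class(out))
  out
}

# like loc_table() but permits lp == 0: a degenerate cluster of identical
# points legitimately collapses to zero reported precision
relaxed_loc_table <- function(df, meta) {
  if (nrow(df) > 0 && any(df$lp == 0)) {
    eps <- df$lp == 0
    df$lp[eps] <- 1
    out <- loc_table(df, meta)
    out$lp[eps] <- 0
  } else {
    out <- loc_table(df, meta)
  }
  out
}

#' @export
print.resi_table <- function(x, ...) {
  cat(sprintf("RESI table: %d super-localizations (%s)\n",
              nrow(x), if (is_3d(x)) "3D" else "2D"))
  if (nrow(x) > 0)
    cat(sprintf("  K: mean %.1f [%d, %d]; precision: mean %.3g nm\n",
                mean(x$K), min(x$K), max(x$K), mean(x$lp)))
  invisible(x)
}

#' Merge RESI tables from aligned imaging rounds
#'
#' Concatenates per-round RESI tables (already aligned to a common
#' coordinate frame) preserving channel provenance; no re-averaging
#' happens across channels. Duplicate channel ids are allowed and
#' flagged in the `"provenance"` attribute.
#'
#' @param tables List of `resi_table` objects of equal dimensionality.
#' @return A single `resi_table`.
#' @export
merge_rounds <- function(tables) {
  if (length(tables) == 0) {
    out <- loc_table(data.frame(x = numeric(0), y = numeric(0),
                                frame = integer(0), lp = numeric(0)),
                     acquisition_meta(1))
    out$K <- integer(0); out$cluster_id <- integer(0)
    class(out) <- c("resi_table", class(out))
    return(out)
  }
  dims <- vapply(tables, is_3d, logical(1))
  if (length(unique(dims)) > 1) stop("cannot merge 2D and 3D tables")
  chans <- unlist(lapply(tables, function(t) unique(t$channel)))
  df <- do.call(rbind, lapply(tables, as.data.frame))
  out <- relaxed_loc_table(df, loc_meta(tables[[1]]))
  out$K <- df$K
  out$cluster_id <- df$cluster_id
  if (dims[1] && !is.null(df$lp_z)) out$lp_z <- df$lp_z
  class(out) <- c("resi_table", class(out))
  attr(out, "provenance") <- list(n_rounds = length(tables),
                                  duplicate_channels = anyDuplicated(chans) > 0)
  out
}

#' Render super-localizations as an image
#'
#' Each record splats a unit-mass 2D Gaussian of s.d. equal to its own
#' precision (`blur = "gaussian_individual"`), truncated at 5 s.d., or a
#' plain 2D histogram (`blur = "none"`). Total image mass equals the
#' record count up to discretization.
#'
#' @param resi A `resi_table` (or any [loc_table()]; `lp` is the blur).
#' @param bin_size Pixel size of the rendered grid, nm.
#' @param blur `"gaussian_individual"` or `"none"`.
#' @param pad Extra margin around the data extent, nm.
#' @return Numeric matrix (rows = x bins, cols = y bins) with attributes
#'   `xlim`/`ylim` in nm.
#' @export
render_resi <- function(resi, bin_size = 0.5,
                        blur = c("gaussian_individual", "none"), pad = NULL) {
  stopifnot(inherits(resi, "loc_table"))
  blur <- match.arg(blur)
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (nrow(resi) == 0) stop("nothing to render")
  if (is.null(pad)) pad <- max(5 * max(resi$lp), 2 * bin_size)
  x0 <- min(resi$x) - pad; x1 <- max(resi$x) + pad
  y0 <- min(resi$y) - pad; y1 <- max(resi$y) + pad
  nx <- ceiling((x1 - x0) / bin_size); ny <- ceiling((y1 - y0) / bin_size)
  img <- matrix(0, nx, ny)
  centers_x <- x0 + (seq_len(nx) - 0.5) * bin_size
  centers_y <- y0 + (seq_len(ny) - 0.5) * bin_size
  for (i in seq_len(nrow(resi))) {
    if (blur == "none") {
      ix <- min(max(1L, 1L + floor((resi$x[i] - x0) / bin_size)), nx)
      iy <- min(max(1L, 1L + floor((resi$y[i] - y0) / bin_size)), ny)
      img[ix, iy] <- img[ix, iy] + 1
    } else {
      s <- resi$lp[i]
      if (!is.finite(s) || s <= 0) s <- bin_size / 2
      half <- 5 * s
      ix <- which(abs(centers_x - resi$x[i]) <= half + bin_size)
      iy <- which(abs(centers_y - resi$y[i]) <= half + bin_size)
      # separable Gaussian integrated over pixel edges
      gx <- diff(stats::pnorm(c(centers_x[ix] - bin_size / 2,
                                centers_x[max(ix)] + bin_size / 2),
                              resi$x[i], s))
      gy <- diff(stats::pnorm(c(centers_y[iy] - bin_size / 2,
                                centers_y[max(iy)] + bin_size / 2),
                              resi$y[i], s))
      img[ix, iy] <- img[ix, iy] + outer(gx, gy)
    }
  }
  attr(img, "xlim") <- c(x0, x1)
  attr(img, "ylim") <- c(y0, y1)
  attr(img, "bin_size") <- bin_size
  img
}
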