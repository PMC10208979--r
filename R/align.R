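#' In-plane rigid transform
#'
#' A rotation by `rotation` radians about `pivot` followed by a
#' translation: `p' = R (p - pivot) + pivot + translation`. Rotation is
#' in-plane only; z coordinates pass through unchanged.
#'
#' @param rotation Angle in radians, in (-pi, pi].
#' @param translation Length-2 numeric, (dx, dy) in nm.
#' @param pivot Length-2 numeric, rotation centre in nm.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = 0, translation = c(0, 0),
                            pivot = c(0, 0)) {
  if (!is.finite(rotation) || rotation <= -pi || rotation > pi)
    stop("rotation must be in (-pi, pi]")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 pivot = as.numeric(pivot)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: theta = %.4f rad, t = (%.3f, %.3f) nm, pivot = (%.1f, %.1f)\n",
              x$rotation, x$translation[1], x$translation[2],
              x$pivot[1], x$pivot[2]))
  if (!is.null(attr(x, "rms")))
    cat(sprintf("  fiducial residual RMS: %.4g nm\n", attr(x, "rms")))
  invisible(x)
}

transform_points <- function(xy, t) {
  ct <- cos(t$rotation); st <- sin(t$rotation)
  dx <- xy[, 1] - t$pivot[1]; dy <- xy[, 2] - t$pivot[2]
  cbind(ct * dx - st * dy + t$pivot[1] + t$translation[1],
        st * dx + ct * dy + t$pivot[2] + t$translation[2])
}

#' Invert a rigid transform
#' @param t A [rigid_transform()].
#' @return The inverse transform (same pivot).
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  ct <- cos(-t$rotation); st <- sin(-t$rotation)
  d <- -t$translation
  rigid_transform(rotation = -t$rotation,
                  translation = c(ct * d[1] - st * d[2], st * d[1] + ct * d[2]),
                  pivot = t$pivot)
}

#' Coarse channel alignment by image cross-correlation
#'
#' Estimates the translation between two imaging rounds by binning both
#' localization tables into 2D histograms on a common grid, computing the
#' cross-correlation via FFT, and refining the correlation peak to
#' sub-bin precision by quadratic interpolation. Rotation is not
#' estimated at this stage.
#'
#' @param reference,moving [loc_table()]s covering overlapping fields.
#' @param bin_size Histogram bin size, nm.
#' @return A [rigid_transform()] with zero rotation that maps `moving`
#'   onto `reference`. If no correlation peak rises above background a
#'   warning is given and the zero shift returned.
#' @export
coarse_translate <- function(reference, moving, bin_size = 5) {
  stopifnot(inherits(reference, "loc_table"), inherits(moving, "loc_table"))
  if (nrow(reference) == 0 || nrow(moving) == 0)
    stop("cannot align empty tables")
  if (bin_size <= 0) stop("bin_size must be > 0")

  xr <- range(c(reference$x, moving$x)); yr <- range(c(reference$y, moving$y))
  nx <- max(4L, ceiling(diff(xr) / bin_size) + 1L)
  ny <- max(4L, ceiling(diff(yr) / bin_size) + 1L)
  binned <- function(tb) {
    ix <- pmin(pmax(floor((tb$x - xr[1]) / bin_size), 0), nx - 1)
    iy <- pmin(pmax(floor((tb$y - yr[1]) / bin_size), 0), ny - 1)
    m <- matrix(0, nx, ny)
    tab <- table(iy * nx + ix)  # column-major linear index
    m[as.integer(names(tab)) + 1L] <- as.integer(tab)
    m
  }
  A <- binned(reference); B <- binned(moving)

  # zero-padded circular cross-correlation C(s) = sum_t A(t) B(t - s)
  px <- 2L * nx; py <- 2L * ny
  Ap <- matrix(0, px, py); Ap[1:nx, 1:ny] <- A
  Bp <- matrix(0, px, py); Bp[1:nx, 1:ny] <- B
  cc <- Re(stats::fft(stats::fft(Ap) * Conj(stats::fft(Bp)), inverse = TRUE)) / (px * py)

  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # a genuine alignment peak stands far above the correlation plateau;
  # reference level = top-0.1% order statistic away from the peak itself
  v <- sort(cc, decreasing = TRUE)
  ref <- v[min(length(v), max(10L, ceiling(0.001 * length(v))))]
  if (max(cc) <= 0 || max(cc) < 2 * max(ref, .Machine$double.eps)) {
    warning("no correlation peak above background; returning zero shift")
    return(rigid_transform())
  }
  # wrap indices to signed shifts
  sx <- peak[1] - 1L; if (sx > px / 2) sx <- sx - px
  sy <- peak[2] - 1L; if (sy > py / 2) sy <- sy - py

  # sub-bin refinement: 1D quadratic through the peak and its neighbours
  sub <- function(im1, i0, ip1) {
    den <- im1 - 2 * i0 + ip1
    if (den >= 0) return(0)  # not a proper maximum
    max(min(0.5 * (im1 - ip1) / den, 0.5), -0.5)
  }
  wrap <- function(i, n) ((i %% n) + n) %% n + 1L
  dx <- sub(cc[wrap(peak[1] - 2L, px), peak[2]], cc[peak[1], peak[2]],
            cc[wrap(peak[1], px), peak[2]])
  dy <- sub(cc[peak[1], wrap(peak[2] - 2L, py)], cc[peak[1], peak[2]],
            cc[peak[1], wrap(peak[2], py)])
  rigid_transform(translation = c((sx + dx) * bin_size, (sy + dy) * bin_size))
}

#' Rigid refinement from fiducial correspondences
#'
#' Least-squares optimal rotation plus translation (orthogonal Procrustes
#' without scaling, solved by SVD) mapping `fiducials_mov` onto
#' `fiducials_ref`, given row-wise correspondence. The rotation pivot is
#' the moving-set centroid, which decouples the rotation and translation
#' estimates. The residual RMS is attached as attribute `"rms"`.
#'
#' @param fiducials_ref,fiducials_mov Matrices (n x 2, nm) of
#'   corresponding fiducial coordinates, n >= 2.
#' @return A [rigid_transform()].
#' @export
rigid_refine <- function(fiducials_ref, fiducials_mov) {
  A <- as.matrix(fiducials_ref)[, 1:2, drop = FALSE]
  B <- as.matrix(fiducials_mov)[, 1:2, drop = FALSE]
  if (nrow(A) != nrow(B)) stop("fiducial sets must correspond row-wise")
  if (nrow(A) < 2) stop("need at least 2 fiducial pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (max(abs(B0)) < 1e-12 || max(abs(A0)) < 1e-12)
    warning("degenerate (coincident) fiducial configuration")
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  if (nrow(A) > 2 && sv$d[2] / max(sv$d[1], 1e-300) < 1e-8)
    warning("near-collinear fiducials: rotation poorly conditioned")
  theta <- atan2(R[2, 1], R[1, 1])
  out <- rigid_transform(rotation = theta, translation = ca - cb, pivot = cb)
  fit <- transform_points(B, out)
  attr(out, "rms") <- sqrt(mean(rowSums((fit - A)^2)))
  out
}

#' Match fiducials between rounds by nearest neighbour
#'
#' After coarse translation, pairs each reference fiducial with the
#' nearest moving fiducial within `r`; ambiguous matches (two moving
#' fiducials within `r` of one reference, or one moving fiducial claimed
#' twice) are dropped with a warning.
#'
#' @param ref,mov Fiducial coordinate matrices (n x 2, nm).
#' @param r Matching radius, nm.
#' @return List with matrices `ref` and `mov` of corresponding rows.
#' @export
match_fiducials <- function(ref, mov, r) {
  ref <- as.matrix(ref)[, 1:2, drop = FALSE]
  mov <- as.matrix(mov)[, 1:2, drop = FALSE]
  keep_r <- integer(0); keep_m <- integer(0); ambiguous <- FALSE
  for (i in seq_len(nrow(ref))) {
    d <- sqrt((mov[, 1] - ref[i, 1])^2 + (mov[, 2] - ref[i, 2])^2)
    hits <- which(d <= r)
    if (length(hits) == 1) {
      keep_r <- c(keep_r, i); keep_m <- c(keep_m, hits)
    } else if (length(hits) > 1) ambiguous <- TRUE
  }
  dup <- duplicated(keep_m) | duplicated(keep_m, fromLast = TRUE)
  if (ambiguous || any(dup))
    warning("ambiguous fiducial matches dropped")
  list(ref = ref[keep_r[!dup], , drop = FALSE],
       mov = mov[keep_m[!dup], , drop = FALSE])
}

#' Apply a rigid transform to a localization table
#'
#' Transforms x/y coordinates; `frame`, `lp`, `z` and `channel` are
#' untouched (the rotation is in-plane).
#'
#' @param table A [loc_table()].
#' @param t A [rigid_transform()].
#' @return The transformed [loc_table()].
#' @export
apply_transform <- function(table, t) {
  stopifnot(inherits(table, "loc_table"), inherits(t, "rigid_transform"))
  if (nrow(table) == 0) return(table)
  xy <- transform_points(cbind(table$x, table$y), t)
  table$x <- xy[, 1]
  table$y <- xy[, 2]
  table
}

#' Align a list of rounds onto the first
#'
#' Convenience wrapper: coarse cross-correlation translation of each
#' round onto the reference, then, when fiducial coordinates are given,
#' nearest-neighbour correspondence and rigid Procrustes refinement.
#'
#' @param tables List of [loc_table()]s; the first is the reference.
#' @param fiducials Optional list of fiducial matrices, same length.
#' @param bin_size Histogram bin for the coarse stage, nm.
#' @param match_radius Fiducial matching radius, nm.
#' @return List with `tables` (aligned) and `transforms` (one per round;
#'   identity for the reference).
#' @export
align_rounds <- function(tables, fiducials = NULL, bin_size = 5,
                         match_radius = 20) {
  stopifnot(length(tables) >= 1)
  transforms <- vector("list", length(tables))
  transforms[[1]] <- rigid_transform()
  out <- tables
  for (i in seq_along(tables)[-1]) {
    tr <- coarse_translate(tables[[1]], tables[[i]], bin_size = bin_size)
    aligned <- apply_transform(tables[[i]], tr)
    if (!is.null(fiducials)) {
      fm <- transform_points(as.matrix(fiducials[[i]])[, 1:2, drop = FALSE], tr)
      pairs <- match_fiducials(as.matrix(fiducials[[1]]), fm, r = match_radius)
      if (nrow(pairs$ref) >= 2) {
        tr2 <- rigid_refine(pairs$ref, pairs$mov)
        aligned <- apply_transform(aligned, tr2)
        tr <- structure(list(coarse = tr, refine = tr2),
                        class = "composed_transform")
      }
    }
    out[[i]] <- aligned
    transforms[[i]] <- tr
  }
  list(tables = out, transforms = transforms)
}
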