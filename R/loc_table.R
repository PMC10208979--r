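#' Acquisition metadata for a localization table
#'
#' Carries the camera/acquisition context that downstream stages need:
#' the total frame count (used by the temporal cluster filters), the
#' effective camera pixel pitch (used to convert pixel-unit Picasso files
#' to nanometres), and the field extent.
#'
#' @param n_frames Total number of acquisition frames (>= 1).
#' @param pixel_size Effective camera pixel pitch in nm/pixel (> 0).
#' @param field_width,field_height Field of view extent in nm (optional).
#' @return An object of class `acquisition_meta` (a named list).
#' @examples
#' acquisition_meta(n_frames = 10000, pixel_size = 130)
#' @export
acquisition_meta <- function(n_frames, pixel_size = 130,
                             field_width = NA_real_, field_height = NA_real_) {
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L)
    stop("n_frames must be an integer >= 1")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(n_frames = n_frames, pixel_size = as.numeric(pixel_size),
                 field_width = as.numeric(field_width),
                 field_height = as.numeric(field_height)),
            class = "acquisition_meta")
}

#' Construct a localization table
#'
#' The universal currency of the pipeline: one row per localization with
#' lateral coordinates `x`, `y` (nm), optional axial coordinate `z` (nm),
#' the 0-based acquisition frame index, the lateral localization precision
#' `lp` (nm, one isotropic scalar per localization), and an integer
#' imaging-round/channel identifier.
#'
#' @param df A data frame with columns `x`, `y`, `frame`, `lp`, and
#'   optionally `z` and `channel` (default channel 0).
#' @param meta An [acquisition_meta()] object.
#' @return A `loc_table`: a validated data frame with columns
#'   `x, y, (z,) frame, lp, channel` and the metadata attached.
#' @examples
#' tb <- loc_table(data.frame(x = c(0, 5), y = c(0, 1),
#'                            frame = c(0, 10), lp = 2),
#'                 acquisition_meta(n_frames = 100))
#' is_3d(tb)
#' @export
loc_table <- function(df, meta) {
  if (!inherits(meta, "acquisition_meta")) stop("meta must be an acquisition_meta")
  df <- as.data.frame(df)
  for (col in c("x", "y", "frame", "lp"))
    if (is.null(df[[col]]))
      stop(sprintf("missing mandatory column '%s'", col))
  if (is.null(df$channel)) df$channel <- rep(0L, nrow(df))
  has_z <- !is.null(df$z)
  if (has_z && anyNA(df$z))
    stop("z must be present for all rows or none")
  n <- nrow(df)
  if (n > 0) {
    bad <- which(!is.finite(df$lp) | df$lp <= 0)
    if (length(bad))
      stop(sprintf("non-positive localization precision at row %d", bad[1]))
    fr <- df$frame
    bad <- which(!is.finite(fr) | fr < 0 | fr >= meta$n_frames | fr != floor(fr))
    if (length(bad))
      stop(sprintf("frame index outside [0, n_frames) at row %d", bad[1]))
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
      stop("non-finite coordinates")
  }
  cols <- c("x", "y", if (has_z) "z", "frame", "lp", "channel")
  out <- df[, cols, drop = FALSE]
  out$frame <- as.integer(out$frame)
  out$channel <- as.integer(out$channel)
  rownames(out) <- NULL
  structure(out, meta = meta, class = c("loc_table", "data.frame"))
}

#' @rdname loc_table
#' @param x A `loc_table`.
#' @export
is_3d <- function(x) "z" %in% names(x)

#' @rdname loc_table
#' @export
loc_meta <- function(x) attr(x, "meta")

#' @export
print.loc_table <- function(x, ...) {
  m <- loc_meta(x)
  cat(sprintf("Localization table: %d localizations (%s), %d channel(s)\n",
              nrow(x), if (is_3d(x)) "3D" else "2D",
              length(unique(x$channel))))
  cat(sprintf("  n_frames = %d, pixel_size = %g nm\n", m$n_frames, m$pixel_size))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

# retain loc_table class + meta through [.data.frame when all cols survive
#' @export
`[.loc_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("x", "y", "frame", "lp") %in% names(out)))
    out <- structure(out, meta = loc_meta(x), class = c("loc_table", "data.frame"))
  out
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".yaml")
}

write_sidecar <- function(meta, path) {
  yaml::write_yaml(list(n_frames = meta$n_frames, pixel_size = meta$pixel_size,
                        field_width = meta$field_width,
                        field_height = meta$field_height),
                   sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  y <- yaml::read_yaml(sp)
  acquisition_meta(n_frames = y$n_frames, pixel_size = y$pixel_size,
                   field_width = if (is.null(y$field_width)) NA else y$field_width,
                   field_height = if (is.null(y$field_height)) NA else y$field_height)
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         csv = "csv", h5 = , hdf5 = "hdf5",
         stop("cannot infer format from extension; pass format explicitly"))
}

picasso_py <- function() {
  script <- system.file("python", "picasso_h5.py", package = "resikit")
  if (script == "") stop("bundled picasso_h5.py helper not found")
  script
}

run_picasso_py <- function(args) {
  python <- Sys.which("python")
  if (python == "") stop("HDF5 I/O requires a 'python' interpreter with h5py on the PATH")
  out <- suppressWarnings(system2(python, c(shQuote(picasso_py()), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("HDF5 helper failed: ", paste(out, collapse = "\n"))
  invisible(out)
}

#' Read a localization table
#'
#' Reads a CSV (canonical header `frame,x,y,z,lp,channel`, coordinates in
#' nm) or a Picasso-dialect HDF5 file (record dataset `locs` with fields
#' `frame, x, y, (z,) lpx, lpy, (channel)`, lateral fields in camera
#' pixels, `z` in nm). A YAML sidecar next to the file supplies
#' acquisition metadata; `pixel_size` overrides the sidecar and is
#' mandatory for pixel-unit HDF5 input without one. When both `lpx` and
#' `lpy` are stored, `lp` is their mean.
#'
#' @param path Input file path.
#' @param format `"auto"` (from extension), `"csv"` or `"hdf5"`.
#' @param pixel_size nm per pixel, for pixel-unit input.
#' @param n_frames Total frame count if no sidecar is present
#'   (default: max frame + 1).
#' @return A [loc_table()].
#' @seealso [write_locs()]
#' @export
read_locs <- function(path, format = c("auto", "csv", "hdf5"),
                      pixel_size = NULL, n_frames = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_sidecar(path)

  if (format == "csv") {
    df <- utils::read.csv(path)
    for (col in c("frame", "x", "y", "lp"))
      if (is.null(df[[col]]))
        stop(sprintf("missing mandatory column '%s'", col))
    if (!is.null(df$z) && all(is.na(df$z))) df$z <- NULL
    if (!is.null(pixel_size)) {
      df$x <- df$x * pixel_size
      df$y <- df$y * pixel_size
      df$lp <- df$lp * pixel_size
    }
  } else {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    run_picasso_py(c("read", shQuote(path), shQuote(tmp)))
    raw <- utils::read.csv(tmp)
    for (col in c("frame", "x", "y", "lpx", "lpy"))
      if (is.null(raw[[col]]))
        stop(sprintf("missing mandatory column '%s'", col))
    px <- if (!is.null(pixel_size)) pixel_size
          else if (!is.null(meta)) meta$pixel_size
          else stop("pixel_size required to read pixel-unit HDF5 without a sidecar")
    df <- data.frame(x = raw$x * px, y = raw$y * px,
                     frame = raw$frame,
                     lp = (raw$lpx + raw$lpy) / 2 * px)
    if (!is.null(raw$z) && !all(is.na(raw$z))) df$z <- raw$z  # z stored in nm
    if (!is.null(raw$channel)) df$channel <- raw$channel
  }

  if (is.null(meta)) {
    nf <- if (!is.null(n_frames)) n_frames
          else if (nrow(df) > 0) max(df$frame) + 1L else 1L
    meta <- acquisition_meta(n_frames = nf,
                             pixel_size = if (is.null(pixel_size)) 130 else pixel_size)
  } else if (!is.null(pixel_size)) {
    meta$pixel_size <- pixel_size
  }
  loc_table(df, meta)
}

#' Write a localization table
#'
#' Writes CSV (nm units, header `frame,x,y,z,lp,channel`) or the Picasso
#' HDF5 dialect (dataset `locs`; `x`, `y`, `lpx`, `lpy` in camera pixels,
#' `z` in nm, all float64 so the round trip through [read_locs()] is
#' lossless). A YAML metadata sidecar is written next to the file in both
#' cases so downstream SMLM tools can recover the acquisition context.
#'
#' @param table A [loc_table()].
#' @param path Output path.
#' @param format `"auto"`, `"csv"` or `"hdf5"`.
#' @return `path`, invisibly.
#' @export
write_locs <- function(table, path, format = c("auto", "csv", "hdf5")) {
  stopifnot(inherits(table, "loc_table"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  meta <- loc_meta(table)

  if (format == "csv") {
    df <- as.data.frame(table)
    df <- df[, c("frame", "x", "y", if (is_3d(table)) "z", "lp", "channel"),
             drop = FALSE]
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    px <- meta$pixel_size
    raw <- data.frame(frame = table$frame,
                      x = table$x / px, y = table$y / px,
                      z = if (is_3d(table)) table$z else NA_real_,
                      lpx = table$lp / px, lpy = table$lp / px,
                      channel = table$channel)
    if (!is_3d(table)) raw$z <- NULL
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    utils::write.csv(raw, tmp, row.names = FALSE)
    run_picasso_py(c("write", shQuote(tmp), shQuote(path)))
  }
  write_sidecar(meta, path)
  invisible(path)
}
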