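#' 2D dose map on a regular grid
#'
#' Container for a calibrated planar dose distribution, the film-derived
#' surrogate used throughout the package. Grid coordinates refer to pixel
#' centers; the physical coordinate of grid element `[1, 1]` is `origin`
#' (mm). By default the origin is placed so that (0, 0) is the geometric
#' center of the grid. Rows index y (in-line), columns index x (cross-line).
#' All lengths are millimetres; field sizes are exposed in cm only at API
#' boundaries.
#'
#' @param values numeric matrix of dose (Gy); finite and non-negative.
#' @param spacing_x,spacing_y pixel pitch (mm), > 0.
#' @param origin length-2 numeric, physical (x, y) of the center of grid
#'   element `[1, 1]` (mm). Default centers the grid on (0, 0).
#' @return An object of class `dose_map`.
#' @export
dose_map <- function(values, spacing_x, spacing_y = spacing_x, origin = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 3L || ncol(values) < 3L)
    stop("dose map grid must be at least 3x3", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("dose values must be finite", call. = FALSE)
  if (any(values < 0)) stop("dose values must be non-negative", call. = FALSE)
  if (!is.numeric(spacing_x) || length(spacing_x) != 1L || spacing_x <= 0 ||
      !is.numeric(spacing_y) || length(spacing_y) != 1L || spacing_y <= 0)
    stop("pixel spacing must be a positive scalar (mm)", call. = FALSE)
  if (is.null(origin)) {
    origin <- c(-(ncol(values) - 1L) / 2 * spacing_x,
                -(nrow(values) - 1L) / 2 * spacing_y)
  }
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("origin must be a finite length-2 vector (mm)", call. = FALSE)
  structure(list(values = values,
                 spacing_x = as.numeric(spacing_x),
                 spacing_y = as.numeric(spacing_y),
                 origin = as.numeric(origin)),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d px, pitch (%.4f, %.4f) mm, max %.4g Gy\n",
              nrow(x$values), ncol(x$values), x$spacing_x, x$spacing_y,
              max(x$values)))
  invisible(x)
}

# Physical x coordinates of the grid columns / y coordinates of the rows (mm).
map_x_coords <- function(map) map$origin[1] + (seq_len(ncol(map$values)) - 1L) * map$spacing_x
map_y_coords <- function(map) map$origin[2] + (seq_len(nrow(map$values)) - 1L) * map$spacing_y

#' Bilinear interpolation of a dose map
#'
#' Evaluates the dose at arbitrary physical positions by bilinear
#' interpolation between the four surrounding pixel centers. Positions must
#' lie inside the convex hull of pixel centers.
#'
#' @param map a [dose_map()].
#' @param x,y numeric vectors of physical coordinates (mm), recycled to a
#'   common length.
#' @return numeric vector of interpolated doses (Gy).
#' @export
interp_dose <- function(map, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  fx <- (x - map$origin[1]) / map$spacing_x
  fy <- (y - map$origin[2]) / map$spacing_y
  nx <- ncol(map$values); ny <- nrow(map$values)
  if (any(fx < -1e-9 | fx > nx - 1 + 1e-9 | fy < -1e-9 | fy > ny - 1 + 1e-9))
    stop("interpolation position outside the dose map", call. = FALSE)
  fx <- pmin(pmax(fx, 0), nx - 1); fy <- pmin(pmax(fy, 0), ny - 1)
  i0 <- pmin(floor(fx), nx - 2); j0 <- pmin(floor(fy), ny - 2)
  tx <- fx - i0; ty <- fy - j0
  v <- map$values
  # matrix is indexed [row = y, col = x]
  idx <- function(j, i) v[cbind(j + 1L, i + 1L)]
  (1 - tx) * (1 - ty) * idx(j0, i0) + tx * (1 - ty) * idx(j0, i0 + 1L) +
    (1 - tx) * ty * idx(j0 + 1L, i0) + tx * ty * idx(j0 + 1L, i0 + 1L)
}

#' Extract a 1D dose profile through a point
#'
#' Samples the map along a line parallel to one axis through `center`,
#' at the native pixel pitch, using bilinear interpolation when the line
#' does not coincide with a grid row/column.
#'
#' @param map a [dose_map()].
#' @param center length-2 numeric (x, y) in mm.
#' @param axis `"x"` (cross-line, varying x at fixed y) or `"y"`.
#' @return A `dose_profile`: data.frame with columns `position` (mm,
#'   strictly increasing) and `value` (Gy).
#' @export
extract_profile <- function(map, center, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") {
    pos <- map_x_coords(map)
    val <- interp_dose(map, pos, rep(center[2], length(pos)))
  } else {
    pos <- map_y_coords(map)
    val <- interp_dose(map, rep(center[1], length(pos)), pos)
  }
  dose_profile(pos, val)
}

#' Construct a dose profile
#'
#' @param positions strictly increasing physical coordinates (mm).
#' @param values dose values (Gy), same length as `positions`.
#' @return data.frame of class `dose_profile`.
#' @export
dose_profile <- function(positions, values) {
  if (length(positions) != length(values))
    stop("positions and values must have the same length", call. = FALSE)
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing", call. = FALSE)
  structure(data.frame(position = as.numeric(positions),
                       value = as.numeric(values)),
            class = c("dose_profile", "data.frame"))
}

#' Read a dose map from a delimited-text grid
#'
#' The expected format is a one-line header `spacing_x spacing_y` (mm)
#' followed by the whitespace-delimited dose matrix (rows = y).
#'
#' @param path file path.
#' @return a [dose_map()].
#' @export
read_dose_map_text <- function(path) {
  header <- scan(path, what = numeric(), nlines = 1L, quiet = TRUE)
  if (length(header) < 2L)
    stop("dose map header must contain 'spacing_x spacing_y'", call. = FALSE)
  values <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(values) <- NULL
  dose_map(values, header[1], header[2])
}

#' Write a dose map as a delimited-text grid
#'
#' @param map a [dose_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dose_map_text <- function(map, path) {
  cat(sprintf("%.6g %.6g\n", map$spacing_x, map$spacing_y), file = path)
  utils::write.table(map$values, path, append = TRUE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a dose map from a single-channel TIFF
#'
#' Reads a 16-bit or float TIFF (first channel if multi-channel). The pixel
#' pitch comes either from a YAML sidecar (same path with extension
#' `.yaml`, keys `spacing_x`/`spacing_y` in mm, optional `scale` Gy per
#' unit) or from the `spacing` argument.
#'
#' @param path TIFF file path.
#' @param spacing optional length-1/2 numeric pixel pitch (mm), overriding
#'   any sidecar.
#' @param scale dose per stored unit (Gy); default 1 or sidecar value.
#' @return a [dose_map()].
#' @export
read_dose_map_tiff <- function(path, spacing = NULL, scale = NULL) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  sidecar <- paste0(sub("\\.[^.]+$", "", path), ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  if (is.null(spacing)) spacing <- c(meta$spacing_x, meta$spacing_y)
  if (length(spacing) == 0L)
    stop("pixel spacing not given and no YAML sidecar found", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (is.null(scale)) scale <- if (!is.null(meta$scale)) meta$scale else 1
  dose_map(img * scale, spacing[1], spacing[2])
}
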