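#' Full width at half maximum of a dose profile
#'
#' The half-maximum level is defined relative to the profile maximum.
#' Each crossing is located by linear interpolation between the bracketing
#' samples, scanning outward from the maximum, so the result is invariant
#' under multiplication of the profile by a positive constant.
#'
#' @param profile a [dose_profile()], or a numeric vector of positions when
#'   `values` is supplied.
#' @param values dose values if `profile` is a bare position vector.
#' @return width (mm) between the two half-maximum crossings.
#' @export
fwhm <- function(profile, values = NULL) {
  if (!is.null(values)) profile <- dose_profile(profile, values)
  pos <- profile$position; val <- profile$value
  imax <- which.max(val)
  vmax <- val[imax]
  half <- vmax / 2
  if (val[1] >= vmax || val[length(val)] >= vmax)
    stop("profile maximum must be strictly above both end values", call. = FALSE)
  cross_out <- function(indices) {
    # first crossing below half-maximum scanning outward from the peak
    below <- which(val[indices] < half)
    if (length(below) == 0L)
      stop("profile does not fall below half-maximum: no crossing", call. = FALSE)
    k <- indices[below[1]]
    prev <- if (k > imax) k - 1L else k + 1L  # neighbour toward the peak
    # linear interpolation between bracketing samples
    pos[prev] + (half - val[prev]) * (pos[k] - pos[prev]) / (val[k] - val[prev])
  }
  right <- cross_out(seq(imax, length(val)))
  left <- cross_out(rev(seq(1L, imax)))
  right - left
}

#' Locate the center of an irradiated field
#'
#' The field center is defined as the center of the dose profiles in both
#' directions: starting from the grid maximum, row/column profiles through
#' the current center are extracted, the half-maximum crossings found, and
#' the center moved to the midpoint of the crossings on each axis. This is
#' iterated to a fixed point (< `tol` mm change) or `max_iter` iterations.
#'
#' @param map a [dose_map()].
#' @param tol convergence tolerance (mm).
#' @param max_iter iteration cap.
#' @return length-2 numeric (x, y) center (mm).
#' @export
locate_field_center <- function(map, tol = 0.01, max_iter = 20L) {
  v <- map$values
  if (max(v) <= min(v))
    stop("degenerate field: uniform dose map has no half-maximum crossing",
         call. = FALSE)
  ij <- which(v == max(v), arr.ind = TRUE)[1, ]
  center <- c(map_x_coords(map)[ij[2]], map_y_coords(map)[ij[1]])
  axis_mid <- function(profile) {
    pos <- profile$position; val <- profile$value
    imax <- which.max(val); half <- val[imax] / 2
    if (val[1] >= val[imax] || val[length(val)] >= val[imax])
      stop("degenerate field: profile does not fall below half-maximum",
           call. = FALSE)
    crossing <- function(indices) {
      below <- which(val[indices] < half)
      if (length(below) == 0L)
        stop("degenerate field: no half-maximum crossing", call. = FALSE)
      k <- indices[below[1]]
      prev <- if (k > imax) k - 1L else k + 1L
      pos[prev] + (half - val[prev]) * (pos[k] - pos[prev]) / (val[k] - val[prev])
    }
    (crossing(seq(imax, length(val))) + crossing(rev(seq(1L, imax)))) / 2
  }
  for (iter in seq_len(max_iter)) {
    new_center <- c(axis_mid(extract_profile(map, center, "x")),
                    axis_mid(extract_profile(map, center, "y")))
    shift <- max(abs(new_center - center))
    center <- new_center
    if (shift < tol) break
  }
  center
}

#' Equivalent square small field size
#'
#' Converts the two FWHM field widths into the side of the equivalent
#' square field, `s_clin = sqrt(A * B)`.
#'
#' @param A in-line FWHM (cm).
#' @param B cross-line FWHM (cm).
#' @return equivalent square side (cm).
#' @export
equivalent_square <- function(A, B) {
  if (any(!is.finite(A)) || any(!is.finite(B)) || any(A <= 0) || any(B <= 0))
    stop("field widths must be positive", call. = FALSE)
  sqrt(A * B)
}

#' Measure field size from a dose map
#'
#' Locates the field center, extracts re-centered profiles along both axes
#' and returns the FWHM widths together with the equivalent square size.
#'
#' @param map a [dose_map()].
#' @return list with `center` (mm), `A` and `B` (cm; in-line y and
#'   cross-line x FWHM) and `s_clin` (cm).
#' @export
field_size_from_map <- function(map) {
  center <- locate_field_center(map)
  B <- fwhm(extract_profile(map, center, "x")) / 10  # cross-line, cm
  A <- fwhm(extract_profile(map, center, "y")) / 10  # in-line, cm
  list(center = center, A = A, B = B, s_clin = equivalent_square(A, B))
}

#' Mean dose in a circular central region of interest
#'
#' Mean and SD of the dose over grid elements whose centers lie within a
#' circle around `center`. If fewer than 4 elements qualify, the map is
#' resampled bilinearly at <= 0.05 mm pitch inside the ROI first.
#'
#' @param map a [dose_map()].
#' @param center length-2 numeric (x, y) (mm). Default: the located field
#'   center.
#' @param diameter ROI diameter (mm); default 0.5.
#' @return list with `mean`, `sd` (Gy) and `n` grid elements used.
#' @export
central_roi_dose <- function(map, center = NULL, diameter = 0.5) {
  if (is.null(center)) center <- locate_field_center(map)
  r <- diameter / 2
  xr <- range(map_x_coords(map)); yr <- range(map_y_coords(map))
  if (center[1] - r < xr[1] || center[1] + r > xr[2] ||
      center[2] - r < yr[1] || center[2] + r > yr[2])
    stop("ROI extends outside the dose map", call. = FALSE)
  xs <- map_x_coords(map); ys <- map_y_coords(map)
  ix <- which(abs(xs - center[1]) <= r); iy <- which(abs(ys - center[2]) <= r)
  if (length(ix) && length(iy)) {
    gx <- rep(xs[ix], each = length(iy)); gy <- rep(ys[iy], times = length(ix))
    keep <- (gx - center[1])^2 + (gy - center[2])^2 <= r^2
  } else keep <- logical(0)
  if (sum(keep) >= 4L) {
    vals <- map$values[as.matrix(expand.grid(iy, ix))][keep]
  } else {
    pitch <- min(0.05, map$spacing_x, map$spacing_y)
    g <- seq(-r, r, by = pitch)
    gx <- rep(center[1] + g, each = length(g))
    gy <- rep(center[2] + g, times = length(g))
    keep <- (gx - center[1])^2 + (gy - center[2])^2 <= r^2
    vals <- interp_dose(map, gx[keep], gy[keep])
  }
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}
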