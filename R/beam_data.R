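#' Catalog of published output-factor parameter sets
#'
#' The eight Sauer-Wilbert parameter sets (one per linac/energy/filtration
#' combination) determined from film + scintillator reference measurements
#' on an Elekta Versa HD and a Varian TrueBeam for 6 and 10 MV beams with
#' (WFF) and without (FFF) flattening filter. These anchor the synthetic
#' campaign generator and serve as evaluation inputs.
#'
#' @return data.frame with columns `linac`, `energy`, `filter`, `beam`
#'   (label), `p_inf`, `n`, `l`, `s_inf`, `b`.
#' @export
beam_catalog <- function() {
  data.frame(
    linac = rep(c("ElektaVersaHD", "VarianTrueBeam"), each = 4),
    energy = rep(c(6, 6, 10, 10), 2),
    filter = rep(c("WFF", "FFF", "WFF", "FFF"), 2),
    beam = c("Elekta 6 MV WFF", "Elekta 6 MV FFF",
             "Elekta 10 MV WFF", "Elekta 10 MV FFF",
             "Varian 6 MV WFF", "Varian 6 MV FFF",
             "Varian 10 MV WFF", "Varian 10 MV FFF"),
    p_inf = c(0.751, 0.767, 0.774, 0.829, 0.741, 0.790, 0.816, 0.816),
    n     = c(2.701, 2.614, 2.183, 1.791, 2.646, 2.097, 1.844, 1.904),
    l     = c(0.542, 0.514, 0.578, 0.511, 0.461, 0.419, 0.588, 0.497),
    s_inf = c(0.384, 0.299, 0.313, 0.198, 0.508, 1.424, 0.478, 0.227),
    b     = c(0.105, 0.151, 0.130, 0.214, 0.072, 0.016, 0.050, 0.173),
    stringsAsFactors = FALSE)
}

#' Published parameter set for one beam
#'
#' @param beam a `beam` label from [beam_catalog()], or a row index 1-8.
#' @return an [sw_params()] object.
#' @export
beam_params <- function(beam) {
  cat_ <- beam_catalog()
  row <- if (is.numeric(beam)) cat_[beam, ] else cat_[cat_$beam == beam, ]
  if (nrow(row) != 1L)
    stop("unknown beam label; see beam_catalog()$beam", call. = FALSE)
  sw_params(row$p_inf, row$n, row$l, row$s_inf, row$b)
}

#' Measured equivalent square field sizes per beam
#'
#' The mapping from the nine nominal square field side lengths (cm) to the
#' measured equivalent square small field sizes `s_clin` (cm) for each of
#' the eight beams, as determined from film FWHM measurements.
#'
#' @return data.frame with columns `beam`, `nominal`, `s_clin`.
#' @export
sclin_catalog <- function() {
  nominal <- c(0.5, 0.8, 1.0, 1.5, 2.0, 3.0, 4.0, 5.0, 10.0)
  s <- list(
    "Elekta 6 MV WFF"   = c(0.60, 0.87, 1.03, 1.51, 2.04, 3.06, 4.04, 5.04, 10.04),
    "Elekta 6 MV FFF"   = c(0.59, 0.85, 1.03, 1.52, 2.03, 3.04, 4.03, 5.01, 9.94),
    "Elekta 10 MV WFF"  = c(0.62, 0.87, 1.06, 1.55, 2.05, 3.08, 4.06, 5.05, 10.05),
    "Elekta 10 MV FFF"  = c(0.58, 0.86, 1.04, 1.52, 2.04, 3.02, 4.01, 4.99, 9.90),
    "Varian 6 MV WFF"   = c(0.56, 0.81, 1.01, 1.50, 2.00, 3.03, 4.03, 5.02, 10.03),
    "Varian 6 MV FFF"   = c(0.54, 0.82, 0.99, 1.49, 1.99, 3.00, 3.99, 5.00, 9.96),
    "Varian 10 MV WFF"  = c(0.57, 0.84, 1.03, 1.52, 2.01, 3.00, 4.02, 5.01, 10.02),
    "Varian 10 MV FFF"  = c(0.55, 0.81, 1.02, 1.51, 1.99, 2.98, 3.98, 4.96, 9.87))
  do.call(rbind, lapply(names(s), function(bm)
    data.frame(beam = bm, nominal = nominal, s_clin = s[[bm]],
               stringsAsFactors = FALSE)))
}

#' Load a detector geometry table
#'
#' Reads a delimited table with columns `name`, `shape`
#' (`circular`/`square`) and `dimension_mm` (radius for circular, side
#' for square) into a list of [detector_geometry()] objects. The packaged
#' fixture `system.file("extdata", "detectors.csv", package =
#' "smallfieldOF")` covers the seven solid-state detectors plus the film
#' ROI and the scintillator.
#'
#' @param path CSV file path; default the packaged fixture.
#' @return named list of `detector_geometry` objects.
#' @export
load_detector_table <- function(path = system.file("extdata", "detectors.csv",
                                                   package = "smallfieldOF")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "shape", "dimension_mm")
  if (!all(req %in% names(tab)))
    stop("detector table must have columns name, shape, dimension_mm",
         call. = FALSE)
  bad <- setdiff(unique(tab$shape), c("circular", "square"))
  if (length(bad))
    stop("unknown detector shape keyword: ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    detector_geometry(tab$name[i], tab$shape[i], tab$dimension_mm[i]))
  names(out) <- tab$name
  out
}
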