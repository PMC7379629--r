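#' One-axis small-field profile model
#'
#' Ideal collimated profile (rect of width `w`) convolved with a Gaussian
#' penumbra of scale `sigma`:
#' `g(u) = 0.5 * (erf((w/2 - u)/(sigma*sqrt(2))) + erf((w/2 + u)/(sigma*sqrt(2))))`.
#' For `w >> sigma` the center is flat (erf saturation); for `w` of the
#' order of `2*sigma` the center is non-flat, emulating partial source
#' occlusion in the smallest fields.
#'
#' @param u position(s) from the field center (mm).
#' @param w_mm nominal field width (mm).
#' @param sigma_mm penumbra scale (mm).
#' @return profile value(s), 1 at the center of a broad field.
#' @export
field_profile_model <- function(u, w_mm, sigma_mm) {
  0.5 * (pracma::erf((w_mm / 2 - u) / (sigma_mm * sqrt(2))) +
           pracma::erf((w_mm / 2 + u) / (sigma_mm * sqrt(2))))
}

#' Analytic FWHM of the profile model
#'
#' Locates the half-maximum crossing of [field_profile_model()] by
#' root-finding; used as the independent oracle for FWHM measurement on
#' simulated maps.
#'
#' @inheritParams field_profile_model
#' @return full width at half maximum (mm).
#' @export
analytic_field_fwhm <- function(w_mm, sigma_mm) {
  g0 <- field_profile_model(0, w_mm, sigma_mm)
  root <- stats::uniroot(function(u) field_profile_model(u, w_mm, sigma_mm) - g0 / 2,
                         lower = 0, upper = w_mm / 2 + 10 * sigma_mm,
                         tol = 1e-10)$root
  2 * root
}

# Exact volume-averaging factor of the separable model field over a
# centered d x d square footprint (Gauss-Legendre per axis).
kvol_exact_model <- function(d_mm, w_mm, sigma_mm, n_nodes = 64L) {
  gl <- pracma::gaussLegendre(n_nodes, -d_mm / 2, d_mm / 2)
  I <- sum(gl$w * field_profile_model(gl$x, w_mm, sigma_mm))
  (field_profile_model(0, w_mm, sigma_mm) * d_mm / I)^2
}

#' Configuration of a synthetic measurement campaign
#'
#' Defines the study conditions emulated by the generator: the planted
#' output-factor truth curve per beam, the penumbra scale, the planted
#' detector perturbation curves (the total correction the pipeline must
#' recover), the noise levels, and one master seed from which all
#' randomness flows.
#'
#' @param beam a beam label from [beam_catalog()]; sets the default truth
#'   curve.
#' @param truth an [sw_params()] truth curve (default: the published set
#'   for `beam`).
#' @param fields nominal square field side lengths (cm).
#' @param penumbra_sigma penumbra scale (mm). The default 1.8 mm puts the
#'   simulated equivalent square size of the nominal 0.5 cm field near
#'   0.58 cm, inside the measured 0.54-0.62 cm spread.
#' @param spacing pixel pitch of simulated dose maps (mm); default
#'   0.1693 mm (150 dpi).
#' @param n_film film pieces (maps) per field.
#' @param n_repeats point-detector repeats per field.
#' @param d_ref peak dose of the reference field map (Gy).
#' @param film_piece_sd relative SD of the per-piece film dose scale.
#' @param film_pixel_sd relative SD of per-pixel film noise.
#' @param w1_sd,diode_sd relative SD per scintillator / diode reading.
#' @param clr_true planted Cerenkov light ratio.
#' @param detector_perturbations named list of planted correction-curve
#'   parameter lists (`a`, `b`, `c`, `d`) per solid-state detector; the
#'   planted curves are total corrections (volume averaging plus fluence
#'   perturbation), mildly under- or over-responding at the smallest
#'   fields as solid-state detectors do.
#' @param seed master integer seed (mandatory for stochastic output).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(beam = "Elekta 6 MV WFF", truth = beam_params(beam),
                       fields = c(0.5, 0.8, 1, 1.5, 2, 3, 4, 5, 10),
                       penumbra_sigma = 1.8, spacing = 0.1693,
                       n_film = 3L, n_repeats = 3L, d_ref = 5,
                       film_piece_sd = 0.010, film_pixel_sd = 0.003,
                       w1_sd = 0.005, diode_sd = 0.003,
                       clr_true = 0.92,
                       detector_perturbations = default_perturbations(),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(penumbra_sigma > 0, spacing > 0, all(fields > 0),
            film_piece_sd >= 0, film_pixel_sd >= 0, w1_sd >= 0, diode_sd >= 0)
  structure(list(beam = beam, truth = truth, fields = sort(fields),
                 penumbra_sigma = penumbra_sigma, spacing = spacing,
                 n_film = as.integer(n_film),
                 n_repeats = as.integer(n_repeats), d_ref = d_ref,
                 film_piece_sd = film_piece_sd, film_pixel_sd = film_pixel_sd,
                 w1_sd = w1_sd, diode_sd = diode_sd, clr_true = clr_true,
                 detector_perturbations = detector_perturbations,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default planted detector perturbation curves
#'
#' Plausible total-correction curves per solid-state detector: unshielded
#' small-volume diodes under-respond slightly (k > 1) at the smallest
#' fields, while the higher-density P-type, EDGE and microdiamond
#' detectors over-respond (k < 1), with magnitudes of a few percent at
#' 0.8-1 cm.
#'
#' @return named list of parameter lists (`a`, `b`, `c`, `d`).
#' @export
default_perturbations <- function() {
  list(
    "IBA SFD diode"       = list(a = 0.8, b = 0.5, c = 0.0005, d = -0.04),
    "IBA Razor diode"     = list(a = 0.8, b = 0.5, c = 0.0004, d = -0.02),
    "PTW 60008 Diode P"   = list(a = 1.0, b = 0.8, c = 0.0002, d = 0.10),
    "PTW 60012 Diode E"   = list(a = 0.8, b = 0.5, c = 0.0004, d = -0.01),
    "PTW 60018 Diode SRS" = list(a = 0.9, b = 0.6, c = 0.0003, d = 0.03),
    "SN EDGE Detector"    = list(a = 1.0, b = 0.7, c = 0.0003, d = 0.05),
    "PTW 60019 mD"        = list(a = 0.9, b = 0.6, c = 0.0002, d = 0.06))
}

#' Simulate a planar dose map for one field
#'
#' Separable model `D(x, y) = amplitude * g(x) * g(y)` with
#' [field_profile_model()] on each axis, optional multiplicative Gaussian
#' pixel noise, on a grid extending half the field width plus a penumbra
#' margin on each side. Deterministic for a given seed.
#'
#' The map is scaled so that the dose on the central axis equals
#' `amplitude`: the occlusion-shaped core is the distribution's shape,
#' while the central dose carries the field's output.
#'
#' @param nominal_cm nominal square field side length (cm).
#' @param config a [sim_config()] (spacing, penumbra, pixel noise).
#' @param amplitude central-axis dose (Gy) before noise.
#' @param seed integer seed for the pixel noise.
#' @return a [dose_map()].
#' @export
simulate_dose_map <- function(nominal_cm, config, amplitude = config$d_ref,
                              seed = config$seed) {
  w <- cm_to_mm(nominal_cm)
  sigma <- config$penumbra_sigma
  half <- w / 2 + max(10, 6 * sigma)
  n_half <- ceiling(half / config$spacing)
  if (n_half < 1L) stop("grid too small for the field", call. = FALSE)
  u <- (-n_half:n_half) * config$spacing
  g <- field_profile_model(u, w, sigma)
  values <- amplitude * outer(g, g) / field_profile_model(0, w, sigma)^2
  if (config$film_pixel_sd > 0) {
    rng <- local_rng(seed)
    values <- values * (1 + rng$norm(length(values),
                                     sd = config$film_pixel_sd))
    values[values < 0] <- 0
  }
  dose_map(values, config$spacing, config$spacing)
}

# Planted truth at the analytic field size for each nominal field.
campaign_field_table <- function(config) {
  w <- cm_to_mm(config$fields)
  s_true <- vapply(w, function(wi)
    mm_to_cm(analytic_field_fwhm(wi, config$penumbra_sigma)), 0)
  data.frame(nominal = config$fields, w_mm = w, s_true = s_true,
             omega_true = sauer_wilbert(s_true, config$truth) /
               sauer_wilbert(10, config$truth))
}

#' Simulate point-detector reading tables
#'
#' Builds per-field repeated readings for the scintillator (two channels,
#' constructed so that Cerenkov correction with the planted CLR recovers
#' the intended signal) or for a solid-state detector (signal ratio
#' shaped by the planted truth curve divided by the planted total
#' correction). Reference-field readings for solid-state detectors are
#' emitted twice (pre and post session).
#'
#' @param config a [sim_config()].
#' @param detector `"W1"` or a name in `config$detector_perturbations`.
#' @param seed integer seed (default derived from the config seed).
#' @return data.frame of readings: for `"W1"` columns `nominal`, `rep`,
#'   `ch1`, `ch2`; otherwise `detector`, `nominal`, `session`
#'   (`clin`/`ref_pre`/`ref_post`), `rep`, `m`.
#' @export
simulate_readings <- function(config, detector, seed = config$seed) {
  ft <- campaign_field_table(config)
  rng <- local_rng(seed)
  if (identical(detector, "W1")) {
    # exact volume averaging of the model field over the fiber footprint
    d_w1 <- 0.5 * sqrt(pi)  # r = 0.5 mm
    kv <- vapply(ft$w_mm, function(wi)
      kvol_exact_model(d_w1, wi, config$penumbra_sigma), 0)
    scale <- 20  # nC at the reference field
    s_true <- scale * ft$omega_true / kv
    ch2_true <- scale * 0.1 * (0.3 + 0.7 * ft$nominal / 10)
    out <- do.call(rbind, lapply(seq_len(nrow(ft)), function(i) {
      ch2 <- ch2_true[i] * (1 + rng$norm(config$n_repeats, sd = config$w1_sd))
      ch1 <- (s_true[i] + config$clr_true * ch2_true[i]) *
        (1 + rng$norm(config$n_repeats, sd = config$w1_sd))
      data.frame(nominal = ft$nominal[i], rep = seq_len(config$n_repeats),
                 ch1 = ch1, ch2 = ch2)
    }))
    return(out)
  }
  pert <- config$detector_perturbations[[detector]]
  if (is.null(pert)) stop("unknown detector: ", detector, call. = FALSE)
  k_true <- evaluate_k(pert, ft$s_true)
  scale <- 10  # nC at the reference field
  m_true <- scale * ft$omega_true / k_true
  clin <- do.call(rbind, lapply(seq_len(nrow(ft)), function(i) {
    data.frame(detector = detector, nominal = ft$nominal[i],
               session = "clin", rep = seq_len(config$n_repeats),
               m = m_true[i] * (1 + rng$norm(config$n_repeats,
                                             sd = config$diode_sd)))
  }))
  iref <- which(ft$nominal == max(ft$nominal))
  ref <- do.call(rbind, lapply(c("ref_pre", "ref_post"), function(ses) {
    data.frame(detector = detector, nominal = ft$nominal[iref],
               session = ses, rep = seq_len(config$n_repeats),
               m = m_true[iref] * (1 + rng$norm(config$n_repeats,
                                                sd = config$diode_sd)))
  }))
  rbind(clin, ref)
}

#' Simulate a complete measurement campaign
#'
#' Generates, from one seed, everything a real campaign produces for one
#' beam: film dose maps (several pieces per field), two-channel
#' scintillator readings, solid-state detector readings with bracketing
#' reference sessions, Cerenkov-calibration readings, and a planted-truth
#' record for recovery tests. Regenerating with the same config is
#' bit-identical.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_campaign` with elements `config`,
#'   `field_table` (planted truth per field), `maps` (list per field of
#'   film-piece [dose_map()]s), `w1_readings`, `detector_readings`,
#'   `clr_readings`, `truth`.
#' @export
simulate_campaign <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ft <- campaign_field_table(config)
  rng <- local_rng(child_seed(config$seed, 1L))
  maps <- lapply(seq_len(nrow(ft)), function(i) {
    lapply(seq_len(config$n_film), function(p) {
      piece_scale <- 1 + if (config$film_piece_sd > 0)
        rng$norm(1, sd = config$film_piece_sd) else 0
      simulate_dose_map(ft$nominal[i], config,
                        amplitude = config$d_ref * ft$omega_true[i] *
                          piece_scale,
                        seed = child_seed(config$seed, 100L + 10L * i + p))
    })
  })
  names(maps) <- as.character(ft$nominal)
  w1 <- simulate_readings(config, "W1", seed = child_seed(config$seed, 2L))
  det <- do.call(rbind, lapply(names(config$detector_perturbations),
                               function(dn) simulate_readings(
                                 config, dn,
                                 seed = child_seed(config$seed,
                                                   3L + match(dn, names(config$detector_perturbations))))))
  # Cerenkov calibration: fixed scintillation signal, fiber-length-dependent
  # stem signal in the reference field; three repeated max/min pairs.
  rng_clr <- local_rng(child_seed(config$seed, 99L))
  nrep <- 3L
  cal_sd <- min(0.002, config$w1_sd)  # long-integration calibration readings
  ch2_max <- 8 * (1 + rng_clr$norm(nrep, sd = cal_sd))
  ch2_min <- 3 * (1 + rng_clr$norm(nrep, sd = cal_sd))
  s0 <- 50
  clr <- data.frame(
    rep = seq_len(nrep),
    max_ch1 = s0 + config$clr_true * ch2_max * (1 + rng_clr$norm(nrep, sd = cal_sd)),
    min_ch1 = s0 + config$clr_true * ch2_min * (1 + rng_clr$norm(nrep, sd = cal_sd)),
    max_ch2 = ch2_max, min_ch2 = ch2_min)
  d_w1 <- 0.5 * sqrt(pi)
  truth <- list(params = config$truth,
                omega = stats::setNames(ft$omega_true, as.character(ft$nominal)),
                s_clin = stats::setNames(ft$s_true, as.character(ft$nominal)),
                k_curves = config$detector_perturbations,
                clr = config$clr_true,
                kvol_w1 = stats::setNames(
                  vapply(ft$w_mm, function(wi)
                    kvol_exact_model(d_w1, wi, config$penumbra_sigma), 0),
                  as.character(ft$nominal)))
  structure(list(config = config, field_table = ft, maps = maps,
                 w1_readings = w1, detector_readings = det,
                 clr_readings = clr, truth = truth),
            class = "synthetic_campaign")
}

#' @export
print.synthetic_campaign <- function(x, ...) {
  cat(sprintf(
    "<synthetic_campaign> %s: %d fields x %d film pieces, %d detectors, seed %d\n",
    x$config$beam, nrow(x$field_table), x$config$n_film,
    length(x$config$detector_perturbations), x$config$seed))
  invisible(x)
}
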