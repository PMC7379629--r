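#' Cerenkov light ratio from a two-point fiber calibration
#'
#' The stem signal of a plastic scintillator is removed by spectral
#' discrimination between two electrometer channels. The calibration
#' coefficient is the ratio of channel-1 to channel-2 signal spans between
#' a maximum (~30 cm) and minimum (~10 cm) length of fiber in a 10 x 10 cm
#' field: `CLR = (M_max^Ch1 - M_min^Ch1) / (M_max^Ch2 - M_min^Ch2)`.
#' When repeated max/min pairs are supplied the final value is the mean of
#' the per-repeat ratios.
#'
#' @param max_ch1,max_ch2 charge readings (nC) at maximum fiber length;
#'   vectors over repeats.
#' @param min_ch1,min_ch2 matching readings at minimum fiber length.
#' @param epsilon_rel denominators smaller than `epsilon_rel` times the
#'   larger channel-2 reading are rejected as ill-conditioned.
#' @return list of class `clr_calibration`: `clr`, `n_repeats`, and the
#'   per-repeat values.
#' @export
compute_clr <- function(max_ch1, min_ch1, max_ch2, min_ch2,
                        epsilon_rel = 1e-12) {
  n <- length(max_ch1)
  if (length(min_ch1) != n || length(max_ch2) != n || length(min_ch2) != n)
    stop("all four reading vectors must have equal length", call. = FALSE)
  den <- max_ch2 - min_ch2
  eps <- epsilon_rel * pmax(abs(max_ch2), abs(min_ch2))
  if (any(abs(den) <= eps))
    stop("ill-conditioned calibration: channel-2 readings are too close",
         call. = FALSE)
  per_repeat <- (max_ch1 - min_ch1) / den
  structure(list(clr = mean(per_repeat), n_repeats = n,
                 per_repeat = per_repeat),
            class = "clr_calibration")
}

#' Cerenkov-correct a two-channel scintillator reading
#'
#' `M = M^Ch1 - CLR * M^Ch2`. The correction is linear in both channels.
#' A non-positive corrected signal is returned with a warning (it can
#' occur legitimately with noisy data) rather than rejected.
#'
#' @param m_ch1,m_ch2 channel readings (nC); vectors recycled to common
#'   length.
#' @param clr the Cerenkov light ratio, or a `clr_calibration`.
#' @return corrected signal(s) (nC).
#' @export
cerenkov_correct <- function(m_ch1, m_ch2, clr) {
  if (inherits(clr, "clr_calibration")) clr <- clr$clr
  out <- m_ch1 - clr * m_ch2
  if (any(out <= 0))
    warning("Cerenkov-corrected signal is non-positive for ",
            sum(out <= 0), " reading(s)", call. = FALSE)
  out
}

#' Cross-normalization constant between scintillator and film
#'
#' Mean over the clinical fields of the ratio of volume-averaging-corrected
#' scintillator to film signals; used to put both reference detectors on a
#' common scale before the joint output-factor fit.
#'
#' @param w1_corrected,ebt3_corrected numeric vectors of corrected signals
#'   (signal * k_vol), one per field, same field order; or named vectors,
#'   in which case names are aligned and must match.
#' @return epsilon_bar (dimensionless).
#' @export
cross_normalization <- function(w1_corrected, ebt3_corrected) {
  if (!is.null(names(w1_corrected)) && !is.null(names(ebt3_corrected))) {
    if (!setequal(names(w1_corrected), names(ebt3_corrected)))
      stop("field sets of the two series do not match", call. = FALSE)
    ebt3_corrected <- ebt3_corrected[names(w1_corrected)]
  }
  if (length(w1_corrected) != length(ebt3_corrected))
    stop("field sets of the two series do not match", call. = FALSE)
  if (any(w1_corrected <= 0) || any(ebt3_corrected <= 0))
    stop("corrected signals must be positive", call. = FALSE)
  mean(w1_corrected / ebt3_corrected)
}

#' Normalize a corrected scintillator signal to the film scale
#'
#' `M_norm = M * k_vol / epsilon_bar`.
#'
#' @param corrected_signal Cerenkov-corrected signal(s).
#' @param kvol_w1 volume-averaging factor(s) for the scintillator.
#' @param epsilon_bar cross-normalization constant, > 0.
#' @return normalized corrected signal(s).
#' @export
normalize_w1 <- function(corrected_signal, kvol_w1, epsilon_bar) {
  if (epsilon_bar <= 0) stop("epsilon_bar must be positive", call. = FALSE)
  corrected_signal * kvol_w1 / epsilon_bar
}
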