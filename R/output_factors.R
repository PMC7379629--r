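#' Volume-averaging correction of a film reading
#'
#' @param signal film signal (central ROI dose), > 0.
#' @param kvol_ebt3 volume-averaging factor for the film ROI.
#' @return corrected value `signal * kvol_ebt3`.
#' @export
correct_film_reading <- function(signal, kvol_ebt3) {
  if (any(signal <= 0) || any(kvol_ebt3 <= 0))
    stop("signal and kvol must be positive", call. = FALSE)
  signal * kvol_ebt3
}

#' Sauer-Wilbert output factor parameter set
#'
#' @param p_inf,n,l,s_inf,b the five coefficients; `p_inf`, `n`, `l`, `b`
#'   must be positive, `s_inf` may be any real (near-degenerate fits can
#'   drive it large while `b` compensates).
#' @return list of class `sw_params`.
#' @export
sw_params <- function(p_inf, n, l, s_inf, b) {
  if (p_inf <= 0 || n <= 0 || l <= 0 || b <= 0)
    stop("p_inf, n, l, b must be positive", call. = FALSE)
  structure(list(p_inf = p_inf, n = n, l = l, s_inf = s_inf, b = b),
            class = "sw_params")
}

#' Sauer-Wilbert field output factor function (unnormalized)
#'
#' `Omega(S) = P_inf * S^n / (l^n + S^n) + S_inf * (1 - exp(-b * S))`:
#' a saturating LCPE-buildup term plus a slowly rising scatter/head term.
#' Exponentiations are overflow-guarded by evaluating the first term as
#' `P_inf / (1 + exp(n * (log(l) - log(S))))`.
#'
#' @param S equivalent square field size (cm), > 0; vectorized.
#' @param params an `sw_params` (or list with the same fields).
#' @return unnormalized output factor values.
#' @export
sauer_wilbert <- function(S, params) {
  if (any(S <= 0)) stop("field size must be positive", call. = FALSE)
  with(params, {
    lr <- n * (log(l) - log(S))
    sat <- ifelse(lr > 700, 0, p_inf / (1 + exp(lr)))
    sat + s_inf * (1 - exp(-b * S))
  })
}

#' Evaluate a normalized output-factor curve
#'
#' `Omega_norm(S) = Omega(S) / Omega(10)` so that the curve passes through
#' exactly 1 at the 10 cm reference field, for any parameter set.
#'
#' @param curve an `of_curve` from [fit_output_factor_curve()], or an
#'   `sw_params` set.
#' @param S field size(s) (cm) in (0, 20].
#' @return normalized output factor(s).
#' @export
evaluate_output_factor <- function(curve, S) {
  if (any(S <= 0 | S > 20))
    stop("field size must be in (0, 20] cm", call. = FALSE)
  params <- if (inherits(curve, "of_curve")) curve$params else curve
  sauer_wilbert(S, params) / sauer_wilbert(10, params)
}

sw_start_grid <- function(scale, n_starts, seed) {
  base <- c(p_inf = 0.78 * scale, n = 2.2, l = 0.52, s_inf = 0.33 * scale,
            b = 0.12)
  starts <- list(base)
  if (n_starts > 1L) {
    rng <- local_rng(seed)
    for (i in seq_len(n_starts - 1L)) {
      starts[[i + 1L]] <- base * exp(rng$norm(5, sd = 0.35))
    }
  }
  starts
}

#' Fit the Sauer-Wilbert function to corrected readings
#'
#' Maximum-likelihood fit under independent Gaussian errors with known
#' per-point SDs, i.e. SD-weighted least squares, of the five-parameter
#' unnormalized function to pooled film and scintillator points (both
#' detectors weighted only by their own SDs). Uses multi-start
#' Levenberg-Marquardt with bounds `p_inf, n, l, b > 0`,
#' `s_inf in (-1 * scale, 10 * scale]`, followed by a seeded parametric
#' bootstrap for the uncertainty of the normalized curve.
#'
#' @param points data.frame with columns `s_clin` (cm), `value`
#'   (volume-averaging-corrected relative signal), `sd` (1 SD, same units;
#'   zeros are floored at 1e-6 of the median value), and optionally
#'   `detector`.
#' @param seed integer seed for the multi-start jitter and bootstrap.
#' @param n_starts number of randomized starts (>= 1).
#' @param n_boot bootstrap resamples for the uncertainty ensemble.
#' @return object of class `of_curve`: `params` (`sw_params`),
#'   `normalization` (unnormalized value at S = 10), `boot` (matrix of
#'   bootstrap parameter draws), `points`, `residual_wrms`.
#' @export
fit_output_factor_curve <- function(points, seed = 1L, n_starts = 5L,
                                    n_boot = 500L) {
  req <- c("s_clin", "value", "sd")
  if (!all(req %in% names(points)))
    stop("points must have columns s_clin, value, sd", call. = FALSE)
  pts <- points[order(points$s_clin), , drop = FALSE]
  s_vals <- unique(round(pts$s_clin, 6))
  if (length(s_vals) < 6L || min(s_vals) >= 1 || max(s_vals) < 9.5)
    stop("insufficient field-size coverage: need >= 6 distinct sizes ",
         "spanning below 1 cm up to the 10 cm reference", call. = FALSE)
  if (any(pts$value <= 0)) stop("values must be positive", call. = FALSE)
  sd_floor <- pmax(pts$sd, 1e-6 * stats::median(pts$value), 1e-12)
  scale <- stats::median(pts$value[pts$s_clin >= 9]) # ~ reference-field level
  if (!is.finite(scale) || scale <= 0) scale <- max(pts$value)
  fit_once <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        value ~ sw_rhs(s_clin, p_inf, n, l, s_inf, b),
        data = data.frame(s_clin = pts$s_clin, value = pts$value),
        start = as.list(start),
        weights = 1 / sd_floor^2,
        lower = c(p_inf = 1e-6, n = 1e-3, l = 1e-3,
                  s_inf = -1 * scale + 1e-9, b = 1e-4),
        upper = c(p_inf = 10 * scale, n = 12, l = 8, s_inf = 10 * scale, b = 10),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  }
  best <- NULL; best_dev <- Inf
  for (start in sw_start_grid(scale, n_starts, seed)) {
    fit <- fit_once(start)
    if (is.null(fit)) next
    dev <- sum(((pts$value - stats::fitted(fit)) / sd_floor)^2)
    if (dev < best_dev) { best <- fit; best_dev <- dev }
  }
  if (is.null(best))
    stop("output-factor fit failed to converge from all starts", call. = FALSE)
  cf <- stats::coef(best)
  params <- sw_params(cf[["p_inf"]], cf[["n"]], cf[["l"]], cf[["s_inf"]],
                      cf[["b"]])
  fitted_vals <- sauer_wilbert(pts$s_clin, params)
  # parametric bootstrap: resample points around the fitted curve
  boot <- NULL
  if (n_boot > 0L) {
    rng <- local_rng(seed + 1L)
    boot <- matrix(NA_real_, nrow = n_boot, ncol = 5,
                   dimnames = list(NULL, c("p_inf", "n", "l", "s_inf", "b")))
    for (i in seq_len(n_boot)) {
      yb <- fitted_vals + rng$norm(nrow(pts)) * sd_floor
      fb <- tryCatch(
        minpack.lm::nlsLM(
          value ~ sw_rhs(s_clin, p_inf, n, l, s_inf, b),
          data = data.frame(s_clin = pts$s_clin, value = yb),
          start = as.list(cf), weights = 1 / sd_floor^2,
          lower = c(p_inf = 1e-6, n = 1e-3, l = 1e-3,
                    s_inf = -1 * scale + 1e-9, b = 1e-4),
          upper = c(p_inf = 10 * scale, n = 12, l = 8, s_inf = 10 * scale,
                    b = 10),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fb)) boot[i, ] <- stats::coef(fb)
    }
    boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  }
  structure(list(params = params,
                 normalization = sauer_wilbert(10, params),
                 boot = boot, points = pts,
                 residual_wrms = sqrt(best_dev / nrow(pts))),
            class = "of_curve")
}

# Raw right-hand side used inside nlsLM (plain arguments, not sw_params).
sw_rhs <- function(S, p_inf, n, l, s_inf, b) {
  lr <- n * (log(l) - log(S))
  ifelse(lr > 700, 0, p_inf / (1 + exp(lr))) + s_inf * (1 - exp(-b * S))
}

#' @export
print.of_curve <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<of_curve> P_inf = %.4g, n = %.4g, l = %.4g, ",
                     "S_inf = %.4g, b = %.4g (norm %.4g, wrms %.3g)\n"),
              p$p_inf, p$n, p$l, p$s_inf, p$b, x$normalization,
              x$residual_wrms))
  invisible(x)
}

#' Tabulate discrete output factors with bootstrap uncertainties
#'
#' Evaluates the normalized curve at the requested field sizes; the 1-SD
#' column is the SD of the normalized value over the bootstrap ensemble
#' (0 when no ensemble is available). Values at measured sizes near but
#' not equal to 10 cm may legitimately differ from 1.000.
#'
#' @param curve an `of_curve`.
#' @param s_clin numeric vector of field sizes (cm).
#' @return data.frame with columns `s_clin`, `omega`, `sd`.
#' @export
tabulate_output_factors <- function(curve, s_clin) {
  omega <- evaluate_output_factor(curve, s_clin)
  sds <- rep(0, length(s_clin))
  if (!is.null(curve$boot) && nrow(curve$boot) > 1L) {
    ens <- apply(curve$boot, 1L, function(row) {
      p <- sw_params(row[["p_inf"]], row[["n"]], row[["l"]], row[["s_inf"]],
                     row[["b"]])
      sauer_wilbert(s_clin, p) / sauer_wilbert(10, p)
    })
    ens <- matrix(ens, ncol = nrow(curve$boot))
    sds <- apply(ens, 1L, stats::sd)
  }
  data.frame(s_clin = s_clin, omega = omega, sd = sds)
}
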