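#' Detector-specific output correction factor from a signal ratio
#'
#' `k = Omega / (M_clin / M_ref)`: the factor that converts the detector's
#' uncorrected signal ratio into the field output factor. The 1-SD
#' uncertainty combines the relative SDs of `omega` and `ratio` in
#' quadrature (independence assumed: different detectors/sessions).
#'
#' @param omega field output factor at the field size of the ratio.
#' @param ratio uncorrected signal ratio `mean(M_clin)/mean(M_ref)`.
#' @param omega_sd,ratio_sd absolute 1-SD uncertainties (default 0).
#' @return list with `k` and `sd`.
#' @export
output_correction_factor <- function(omega, ratio, omega_sd = 0,
                                     ratio_sd = 0) {
  if (any(omega <= 0) || any(ratio <= 0))
    stop("omega and ratio must be positive", call. = FALSE)
  k <- omega / ratio
  rel <- combine_relative_sd(cbind(omega_sd / omega, ratio_sd / ratio))
  list(k = k, sd = k * rel)
}

#' TRS-483 analytic output correction factor curve
#'
#' `k(S) = (1 + d*exp(-(10-a)/b)) / (1 + d*exp(-(S-a)/b)) + c*(S-10)`.
#' By construction the curve equals 1 identically at the 10 cm reference
#' field. Exponentials are overflow-guarded.
#'
#' @param params list with elements `a`, `b`, `c`, `d` (note: these are
#'   the sigmoid coefficients of this curve, a separate namespace from the
#'   Gaussian `b`, `c` and the output-factor `b`).
#' @param S field size(s) (cm), > 0.
#' @return k(S), vectorized.
#' @export
evaluate_k <- function(params, S) {
  if (any(S <= 0)) stop("field size must be positive", call. = FALSE)
  with(params, {
    if (b <= 0) stop("sigmoid width b must be positive", call. = FALSE)
    e10 <- exp(pmin((a - 10) / b, 700))
    eS <- exp(pmin((a - S) / b, 700))
    (1 + d * e10) / (1 + d * eS) + c * (S - 10)
  })
}

#' Fit the TRS-483 correction factor curve to discrete k values
#'
#' SD-weighted least squares of the analytic curve, with multi-start
#' Levenberg-Marquardt. Points below `min_field_cm` (default 0.8 cm,
#' where the sigmoid no longer represents the data) are excluded from the
#' residuals but returned flagged alongside the fit. The fourth
#' coefficient `d` may be fitted (default) or held fixed via `fix_d`.
#'
#' @param points data.frame with columns `s_clin`, `k`, and optionally
#'   `sd` (zeros/missing floored).
#' @param min_field_cm smallest field size included in the fit.
#' @param fix_d `NULL` to fit `d`, or a number to hold it fixed.
#' @param seed integer seed for the start jitter.
#' @param n_starts randomized starts.
#' @return object of class `k_curve`: `params` (a, b, c, d), `points`
#'   (with logical column `used`), `residual_wrms`.
#' @export
fit_correction_curve <- function(points, min_field_cm = 0.8, fix_d = NULL,
                                 seed = 1L, n_starts = 5L) {
  if (!all(c("s_clin", "k") %in% names(points)))
    stop("points must have columns s_clin and k", call. = FALSE)
  pts <- points[order(points$s_clin), , drop = FALSE]
  if (is.null(pts$sd)) pts$sd <- 0
  pts$used <- pts$s_clin >= min_field_cm
  fit_pts <- pts[pts$used, , drop = FALSE]
  if (nrow(fit_pts) < 4L)
    stop("insufficient points at or above min_field_cm for the fit",
         call. = FALSE)
  sd_floor <- pmax(fit_pts$sd, 1e-6 * stats::median(abs(fit_pts$k)), 1e-12)
  # flat data: sigmoid amplitude is unidentifiable, return the unit curve
  if (max(abs(fit_pts$k - 1)) < 1e-9) {
    return(structure(list(params = list(a = 1, b = 1, c = 0, d = 0),
                          points = pts, residual_wrms = 0),
                     class = "k_curve"))
  }
  # deterministic grid over both response signs, plus seeded jitter
  rng <- local_rng(seed)
  starts <- list()
  for (d0 in c(0.2, -0.2, 0.05, -0.05))
    starts[[length(starts) + 1L]] <- c(a = 1.0, b = 0.6, c = 0.0005, d = d0)
  for (i in seq_len(max(n_starts - 1L, 0L))) {
    jit <- starts[[1L + (i - 1L) %% 4L]] * exp(rng$norm(4, sd = 0.4))
    jit[["d"]] <- max(min(jit[["d"]], 45), -0.9)
    jit[["b"]] <- max(min(jit[["b"]], 19), 0.01)
    starts[[length(starts) + 1L]] <- jit
  }
  krhs <- function(S, a, b, c, d)
    (1 + d * exp(pmin((a - 10) / b, 700))) /
    (1 + d * exp(pmin((a - S) / b, 700))) + c * (S - 10)
  best <- NULL; best_dev <- Inf
  for (st in starts) {
    if (!is.null(fix_d)) {
      fml <- k ~ krhs(s_clin, a, b, c, fix_d)
      start <- as.list(st[c("a", "b", "c")])
      lower <- c(a = -5, b = 1e-3, c = -1)
      upper <- c(a = 10, b = 20, c = 1)
    } else {
      fml <- k ~ krhs(s_clin, a, b, c, d)
      start <- as.list(st)
      lower <- c(a = -5, b = 1e-3, c = -1, d = -0.95)
      upper <- c(a = 10, b = 20, c = 1, d = 50)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(fml,
                        data = data.frame(s_clin = fit_pts$s_clin,
                                          k = fit_pts$k),
                        start = start, weights = 1 / sd_floor^2,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- sum(((fit_pts$k - stats::fitted(fit)) / sd_floor)^2)
    if (dev < best_dev) { best <- fit; best_dev <- dev }
  }
  if (is.null(best)) {
    # degenerate fallback: no resolvable sigmoid, linear-in-S component only
    w <- 1 / sd_floor^2
    x <- fit_pts$s_clin - 10
    c_hat <- sum(w * x * (fit_pts$k - 1)) / sum(w * x^2)
    params <- list(a = 1, b = 1, c = c_hat, d = 0)
    dev <- sum(((fit_pts$k - evaluate_k(params, fit_pts$s_clin)) /
                  sd_floor)^2)
    return(structure(list(params = params, points = pts,
                          residual_wrms = sqrt(dev / nrow(fit_pts))),
                     class = "k_curve"))
  }
  cf <- as.list(stats::coef(best))
  if (!is.null(fix_d)) cf$d <- fix_d
  structure(list(params = cf[c("a", "b", "c", "d")], points = pts,
                 residual_wrms = sqrt(best_dev / nrow(fit_pts))),
            class = "k_curve")
}

#' @export
print.k_curve <- function(x, ...) {
  p <- x$params
  cat(sprintf("<k_curve> a = %.4g, b = %.4g, c = %.4g, d = %.4g (wrms %.3g)\n",
              p$a, p$b, p$c, p$d, x$residual_wrms))
  invisible(x)
}
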