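#' Run the full small-field dosimetry workflow
#'
#' Executes the complete analysis chain on a measurement campaign (real
#' or from [simulate_campaign()]): film field sizing (FWHM, equivalent
#' square size, central ROI dose) -> bivariate Gaussian fits of the
#' central dose -> volume-averaging factors for every detector ->
#' Cerenkov calibration and correction of the scintillator -> cross
#' normalization -> joint Sauer-Wilbert output-factor fit with bootstrap
#' uncertainties -> discrete output factor table -> detector-specific
#' output correction factors and their analytic curve fits.
#'
#' Volume-averaging corrections are applied only where `k_vol - 1`
#' exceeds `kvol_threshold` (default 0.1%); smaller factors are treated
#' as exactly 1.
#'
#' @param campaign a `synthetic_campaign`, or a list with the same
#'   structure assembled from measured data (`maps`, `w1_readings`,
#'   `detector_readings`, `clr_readings`).
#' @param detectors named list of [detector_geometry()] objects for the
#'   volume-averaging table; default the packaged catalog.
#' @param kvol_threshold apply k_vol only when `k_vol - 1` exceeds this.
#' @param min_field_cm smallest field size used in correction-curve fits.
#' @param n_boot bootstrap resamples for the output-factor uncertainties.
#' @param seed integer seed for fitting/bootstrap randomness; default the
#'   campaign seed.
#' @return list of class `pipeline_result`: `field_sizes`, `kvol`
#'   (per field x detector), `clr`, `epsilon_bar`, `of_curve`,
#'   `of_table`, `ratios`, `k_table`, `k_curves`.
#' @export
run_full_pipeline <- function(campaign, detectors = load_detector_table(),
                              kvol_threshold = 1e-3, min_field_cm = 0.8,
                              n_boot = 200L, seed = NULL) {
  if (is.null(seed)) seed <- if (!is.null(campaign$config$seed))
    campaign$config$seed else 1L
  nominals <- as.numeric(names(campaign$maps))
  if (!any(nominals >= 10))
    stop("coverage error: the 10 cm reference field is missing from the maps",
         call. = FALSE)
  ref_name <- names(campaign$maps)[which.max(nominals)]

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- film: field sizing, ROI dose, central Gaussian fit per piece ----
  film <- stage("field sizing", {
    do.call(rbind, lapply(names(campaign$maps), function(nm) {
      pieces <- campaign$maps[[nm]]
      per <- lapply(pieces, function(map) {
        fs <- field_size_from_map(map)
        roi <- central_roi_dose(map, fs$center, diameter = 0.5)
        gfit <- fit_central_gaussian(map, fs$center)
        data.frame(s_clin = fs$s_clin, A = fs$A, B = fs$B,
                   roi = roi$mean, b_mm = gfit$b, c_mm = gfit$c)
      })
      per <- do.call(rbind, per)
      data.frame(nominal = as.numeric(nm),
                 s_clin = mean(per$s_clin),
                 A = mean(per$A), B = mean(per$B),
                 roi_mean = mean(per$roi),
                 roi_sd = stats::sd(per$roi),
                 b_mm = mean(per$b_mm), c_mm = mean(per$c_mm),
                 n_pieces = nrow(per))
    }))
  })
  film <- film[order(film$nominal), ]
  if (any(!is.finite(film$roi_sd))) film$roi_sd[!is.finite(film$roi_sd)] <- 0

  # --- volume-averaging table for all detectors ------------------------
  kvol <- stage("volume averaging", {
    do.call(rbind, lapply(seq_len(nrow(film)), function(i) {
      tab <- kvol_table(list(b = film$b_mm[i], c = film$c_mm[i]),
                        detectors)
      tab$k_vol[tab$k_vol - 1 <= kvol_threshold] <- 1
      cbind(data.frame(nominal = film$nominal[i], s_clin = film$s_clin[i]),
            tab)
    }))
  })
  kv_of <- function(nominal, det)
    kvol$k_vol[kvol$nominal == nominal & kvol$detector == det]

  # --- scintillator: CLR, correction, cross-normalization -------------
  cal <- stage("Cerenkov calibration",
               with(campaign$clr_readings,
                    compute_clr(max_ch1, min_ch1, max_ch2, min_ch2)))
  w1 <- stage("Cerenkov correction", {
    w1r <- campaign$w1_readings
    w1r$m <- cerenkov_correct(w1r$ch1, w1r$ch2, cal)
    agg <- do.call(rbind, lapply(split(w1r, w1r$nominal), function(d)
      data.frame(nominal = d$nominal[1], m = mean(d$m),
                 sd = stats::sd(d$m) / sqrt(nrow(d)))))
    agg[order(agg$nominal), ]
  })
  film_corr <- vapply(seq_len(nrow(film)), function(i)
    correct_film_reading(film$roi_mean[i],
                         kv_of(film$nominal[i], "EBT3-ROI")), 0)
  w1_corr <- vapply(seq_len(nrow(w1)), function(i)
    w1$m[i] * kv_of(w1$nominal[i], "W1"), 0)
  epsilon_bar <- stage("cross-normalization",
                       cross_normalization(
                         stats::setNames(w1_corr, as.character(w1$nominal)),
                         stats::setNames(film_corr,
                                         as.character(film$nominal))))

  # --- joint output-factor fit ----------------------------------------
  # Per-point sample SDs from 3 repeats are too noisy to serve as fit
  # weights; the relative SD is pooled across fields within each
  # detector series (root mean square) before weighting.
  pool_rel <- function(rel) {
    rel <- rel[is.finite(rel)]
    if (length(rel) == 0L) return(0)
    sqrt(mean(rel^2))
  }
  scale0 <- film_corr[film$nominal == as.numeric(ref_name)]
  film_rel <- pool_rel(film$roi_sd / sqrt(pmax(film$n_pieces, 1)) /
                         film$roi_mean)
  w1_rel <- pool_rel(w1$sd / w1$m)
  film_val <- film_corr / scale0
  w1_val <- normalize_w1(w1$m, vapply(w1$nominal, kv_of, 0, det = "W1"),
                         epsilon_bar) / scale0
  points <- rbind(
    data.frame(s_clin = film$s_clin, detector = "EBT3",
               value = film_val, sd = film_rel * film_val),
    data.frame(s_clin = film$s_clin[match(w1$nominal, film$nominal)],
               detector = "W1",
               value = w1_val, sd = w1_rel * w1_val))
  curve <- stage("output-factor fit",
                 fit_output_factor_curve(points, seed = child_seed(seed, 11L),
                                         n_boot = n_boot))
  of_table <- stage("output-factor table", {
    tab <- tabulate_output_factors(curve, film$s_clin)
    cbind(nominal = film$nominal, tab)
  })

  # --- detector-specific output correction factors --------------------
  ratios <- k_table <- NULL; k_curves <- list()
  if (!is.null(campaign$detector_readings) &&
      nrow(campaign$detector_readings) > 0L) {
    ratios <- stage("signal ratios", {
      do.call(rbind, lapply(split(campaign$detector_readings,
                                  campaign$detector_readings$detector),
                            function(d) {
        refs <- d[d$session %in% c("ref_pre", "ref_post"), ]
        if (nrow(refs) == 0L)
          stop("no bracketing reference-field sessions for detector ",
               d$detector[1])
        m_ref <- mean(refs$m)
        m_ref_sd <- stats::sd(refs$m) / sqrt(nrow(refs))
        clin <- d[d$session == "clin", ]
        per_field <- do.call(rbind, lapply(split(clin, clin$nominal),
                                           function(cc)
          data.frame(detector = cc$detector[1], nominal = cc$nominal[1],
                     m = mean(cc$m),
                     msd = stats::sd(cc$m) / sqrt(nrow(cc)))))
        # pooled relative SD across fields (3-repeat sample SDs are noisy)
        rel_clin <- sqrt(mean((per_field$msd / per_field$m)^2, na.rm = TRUE))
        if (!is.finite(rel_clin)) rel_clin <- 0
        r <- per_field$m / m_ref
        data.frame(detector = per_field$detector, nominal = per_field$nominal,
                   ratio = r,
                   sd = r * combine_relative_sd(cbind(rel_clin,
                                                      m_ref_sd / m_ref)))
      }))
    })
    ratios$s_clin <- film$s_clin[match(ratios$nominal, film$nominal)]
    k_table <- stage("correction factors", {
      do.call(rbind, lapply(seq_len(nrow(ratios)), function(i) {
        om <- of_table[of_table$nominal == ratios$nominal[i], ]
        kk <- output_correction_factor(om$omega, ratios$ratio[i],
                                       om$sd, ratios$sd[i])
        data.frame(detector = ratios$detector[i],
                   nominal = ratios$nominal[i], s_clin = ratios$s_clin[i],
                   k = kk$k, sd = kk$sd)
      }))
    })
    k_curves <- stage("correction-curve fits", {
      lapply(split(k_table, k_table$detector), function(d)
        fit_correction_curve(d, min_field_cm = min_field_cm,
                             seed = child_seed(seed, 13L)))
    })
  }

  structure(list(field_sizes = film, kvol = kvol, clr = cal,
                 epsilon_bar = epsilon_bar, of_curve = curve,
                 of_table = of_table, ratios = ratios, k_table = k_table,
                 k_curves = k_curves, seed = seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d fields, epsilon_bar = %.4f\n",
              nrow(x$field_sizes), x$epsilon_bar))
  print(x$of_curve)
  if (!is.null(x$k_table))
    cat(sprintf("  correction factors for %d detector(s)\n",
                length(unique(x$k_table$detector))))
  invisible(x)
}

#' Write the pipeline result tables to a directory
#'
#' Persists all intermediate and final tables as delimited text with
#' header rows, and the fitted curve parameters as JSON.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(result$field_sizes, "field_sizes.tsv")
  wt(result$kvol, "kvol.tsv")
  wt(result$of_table, "output_factors.tsv")
  if (!is.null(result$k_table)) wt(result$k_table, "k_factors.tsv")
  params <- list(clr = result$clr$clr, epsilon_bar = result$epsilon_bar,
                 sauer_wilbert = unclass(result$of_curve$params),
                 k_curves = lapply(result$k_curves, function(k) k$params))
  jsonlite::write_json(params, file.path(dir, "curves.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
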