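#' Two-sample Student's t-test from summary statistics
#'
#' Standard two-sample t-test computed from group means, SDs and sizes
#' only, as used for comparing tabulated output factors between beams or
#' against reference datasets. `variance_mode = "welch"` (default) uses
#' the Welch-Satterthwaite degrees of freedom; `"pooled"` assumes equal
#' variances. The one-tailed p-value tests the directional alternative
#' `mean2 > mean1`.
#'
#' @param mean1,sd1,n1 summary of group 1 (`n1 >= 2`).
#' @param mean2,sd2,n2 summary of group 2.
#' @param tails 1 or 2.
#' @param variance_mode `"welch"` or `"pooled"`.
#' @return list of class `summary_t_test`: `t`, `df`, `p`, `tails`,
#'   `variance_mode`. `t` is computed as `(mean2 - mean1) / se`, so it is
#'   antisymmetric under swapping the groups.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                tails = 2L,
                                variance_mode = c("welch", "pooled")) {
  variance_mode <- match.arg(variance_mode)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative", call. = FALSE)
  if (!tails %in% c(1L, 2L)) stop("tails must be 1 or 2", call. = FALSE)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2)
    stop("undefined test: both variances zero with equal means",
         call. = FALSE)
  if (variance_mode == "welch") {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (mean2 - mean1) / se
  p <- if (tails == 1L) stats::pt(t, df, lower.tail = FALSE)
       else 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(t = t, df = df, p = p, tails = tails,
                 variance_mode = variance_mode),
            class = "summary_t_test")
}

#' @export
print.summary_t_test <- function(x, ...) {
  cat(sprintf("<summary_t_test> t = %.4g, df = %.3g, p(%d-tailed) = %.4g [%s]\n",
              x$t, x$df, x$tails, x$p, x$variance_mode))
  invisible(x)
}

#' Combine relative uncertainties in quadrature
#'
#' Root-sum-square of relative SDs, for products/ratios of independent
#' quantities (e.g. the output correction factor's uncertainty columns).
#'
#' @param rel_sds numeric vector of relative SDs, or a matrix combined
#'   row-wise.
#' @return combined relative SD (scalar, or one value per row).
#' @export
combine_relative_sd <- function(rel_sds) {
  if (is.matrix(rel_sds)) {
    if (any(rel_sds < 0)) stop("relative SDs must be >= 0", call. = FALSE)
    return(sqrt(rowSums(rel_sds^2)))
  }
  if (any(rel_sds < 0)) stop("relative SDs must be >= 0", call. = FALSE)
  sqrt(sum(rel_sds^2))
}

#' Compare two output-factor (or correction-factor) tables field by field
#'
#' Runs [t_test_from_summary()] per matched field size between two tables
#' with columns `s_clin` (or `nominal`), a value column and an `sd`
#' column, assuming `n` underlying measurements per entry.
#'
#' @param table_a,table_b data.frames; matched on `nominal` if present in
#'   both, otherwise on `s_clin`.
#' @param value_col name of the value column (default `"omega"`, falling
#'   back to `"k"`).
#' @param n measurements per summary entry (default 3).
#' @param tails 1 or 2.
#' @param variance_mode passed through.
#' @return data.frame with the matching key, both values, `t`, `df`, `p`.
#' @export
compare_tables <- function(table_a, table_b, value_col = NULL, n = 3L,
                           tails = 1L, variance_mode = "welch") {
  key <- if ("nominal" %in% names(table_a) && "nominal" %in% names(table_b))
    "nominal" else "s_clin"
  if (is.null(value_col))
    value_col <- if ("omega" %in% names(table_a)) "omega" else "k"
  merged <- merge(table_a[, c(key, value_col, "sd")],
                  table_b[, c(key, value_col, "sd")],
                  by = key, suffixes = c("_a", "_b"))
  if (nrow(merged) == 0L) stop("no matching fields between tables",
                               call. = FALSE)
  va <- paste0(value_col, "_a"); vb <- paste0(value_col, "_b")
  res <- lapply(seq_len(nrow(merged)), function(i) {
    tt <- t_test_from_summary(merged[[va]][i], merged$sd_a[i], n,
                              merged[[vb]][i], merged$sd_b[i], n,
                              tails = tails, variance_mode = variance_mode)
    data.frame(t = tt$t, df = tt$df, p = tt$p)
  })
  cbind(merged, do.call(rbind, res))
}
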