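#' Log-transform positive variables for allometric regression
#'
#' All allometric fits in this package operate on log10-transformed variables;
#' slopes are base-invariant, intercepts are reported in base-10 log units.
#'
#' @param values positive numeric vector.
#' @param ids optional specimen ids used in error messages.
#' @return `log10(values)`.
#' @export
log_transform <- function(values, ids = names(values)) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    who <- if (!is.null(ids)) ids[bad[1]] else paste("element", bad[1])
    stop("domain error: non-positive value for specimen ", who)
  }
  log10(values)
}

#' Reduced-major-axis (standardized major axis) fit
#'
#' Fits the SMA line to already log-transformed data: slope =
#' sign(r) * s_y / s_x, intercept = mean(y) - slope * mean(x). The confidence
#' interval for the slope uses B = F(1-alpha; 1, n-2) * (1-r^2) / (n-2) with
#' bounds slope * (sqrt(B+1) +/- sqrt(B)). Exactly collinear data yield a
#' zero-width interval and are flagged `exact`.
#'
#' @param x,y numeric vectors of equal length (log-transformed values).
#' @param alpha confidence level complement (default 0.05 for 95% CIs).
#' @return An object of class `sma_fit`: slope, intercept, r2, ci_low,
#'   ci_high, n, alpha, exact flag.
#' @examples
#' fit_sma(log10(c(1, 2, 4, 8)), log10(c(1, 4, 16, 64)))  # slope 2
#' @export
fit_sma <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("insufficient-data: SMA needs n >= 3 complete cases")
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0)
    stop("degenerate-data: zero variance in ",
         if (sx == 0) "x" else "y", " axis")
  r <- cor(x, y)
  slope <- (if (r < 0) -1 else 1) * sy / sx
  intercept <- mean(y) - slope * mean(x)
  r2 <- r^2
  exact <- isTRUE(all.equal(r2, 1, tolerance = 1e-14)) || r2 >= 1
  if (exact) {
    B <- 0
  } else {
    B <- qf(1 - alpha, 1, n - 2) * (1 - r2) / (n - 2)
  }
  ci <- sort(slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 ci_low = ci[1], ci_high = ci[2], n = n, alpha = alpha,
                 exact = exact),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf(
    "SMA fit (n = %d): slope %.5g [%.5g, %.5g] (%.0f%% CI), intercept %.5g, r2 %.5g\n",
    x$n, x$slope, x$ci_low, x$ci_high, 100 * (1 - x$alpha), x$intercept, x$r2))
  if (!is.null(x$null_slope))
    cat(sprintf("  H0 slope = %g: t = %.4g, p = %.4g\n",
                x$null_slope, x$test_statistic, x$p_value))
  invisible(x)
}

#' Test an SMA slope against an isometry null
#'
#' The slope test correlates the residual and fitted axes under the null:
#' r_rf = cor(y - b0*x, y + b0*x); the statistic t = r_rf *
#' sqrt((n-2)/(1-r_rf^2)) is referred to a Student t distribution with n-2
#' degrees of freedom (two-sided). Data lying exactly on a line of slope
#' different from b0 give |r_rf| = 1; the test then reports p = 0 with an
#' `infinite_statistic` flag rather than an error.
#'
#' @inheritParams fit_sma
#' @param b0 null (isometric) slope, nonzero.
#' @return list: `test_statistic`, `p_value`, `df`, `null_slope`,
#'   `infinite_statistic`.
#' @export
slope_test <- function(x, y, b0) {
  stopifnot(length(x) == length(y))
  if (!is.finite(b0) || b0 == 0) stop("null slope b0 must be nonzero")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("insufficient-data: slope test needs n >= 3")
  resid <- y - b0 * x
  fitted <- y + b0 * x
  scale <- abs(b0) * sd(x) + sd(y)
  if (sd(resid) <= 1e-12 * scale) {
    # data lie exactly on the null slope: no evidence against H0
    return(list(test_statistic = 0, p_value = 1, df = n - 2, null_slope = b0,
                infinite_statistic = FALSE))
  }
  if (sd(fitted) == 0)
    stop("degenerate-data: zero variance on the fitted axis")
  r_rf <- cor(resid, fitted)
  if (abs(r_rf) >= 1 - 1e-15) {
    return(list(test_statistic = sign(r_rf) * Inf, p_value = 0, df = n - 2,
                null_slope = b0, infinite_statistic = TRUE))
  }
  tstat <- r_rf * sqrt((n - 2) / (1 - r_rf^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(test_statistic = tstat, p_value = p, df = n - 2, null_slope = b0,
       infinite_statistic = FALSE)
}

#' Isometry null slope for a variable pairing
#'
#' Under geometric similarity a volume scales as the cube of a linear
#' dimension, as the 3/2 power of an area, and proportionally to another
#' volume; the corresponding log-log null slopes are 3, 1.5 and 1.
#'
#' @param pair_kind one of `"volume_on_linear"`, `"volume_on_area"`,
#'   `"volume_on_volume"`.
#' @return The null slope b0.
#' @export
isometry_null <- function(pair_kind = c("volume_on_linear", "volume_on_area",
                                        "volume_on_volume")) {
  switch(match.arg(pair_kind),
         volume_on_linear = 3,
         volume_on_area = 1.5,
         volume_on_volume = 1)
}

default_allometry_pairs <- function() {
  list(
    list(response = "middle_ear_volume_mm3", predictor = "gms_mm",
         label = "ME_v on GMS", null = 3),
    list(response = "middle_ear_volume_mm3", predictor = "braincase_volume_mm3",
         label = "ME_v on BC_v", null = 1),
    list(response = "middle_ear_volume_mm3", predictor = "tympanum_area_mm2",
         label = "ME_v on T_sa", null = 1.5))
}

#' Run the standard allometric regressions over a specimen series
#'
#' Fits SMA regressions of log10 middle-ear volume on log10 geometric-mean
#' skull size, braincase volume, and tympanum area (by default), each tested
#' against its isometry null (3, 1, 1.5 respectively), and assembles the
#' report table. The `gms_mm` column is computed from the measurement columns
#' when absent.
#'
#' @param table series data.frame (morphometry schema).
#' @param pairs list of pairings, each a list with `response`, `predictor`,
#'   `null`, and optional `label`; default the three standard regressions.
#' @param alpha significance level for CIs and slope tests (default 0.05).
#' @return data.frame with columns `regression`, `n`, `r2`, `slope`,
#'   `ci_low`, `ci_high`, `intercept`, `null_slope`, `t`, `p`, `decision`.
#' @export
run_allometry <- function(table, pairs = default_allometry_pairs(),
                          alpha = 0.05) {
  validate_series(table)
  needs_gms <- any(vapply(pairs, function(p)
    identical(p$predictor, "gms_mm"), logical(1)))
  if (needs_gms && !"gms_mm" %in% names(table)) table <- add_gms(table)
  rows <- lapply(pairs, function(p) {
    lab <- if (!is.null(p$label)) p$label
           else paste(p$response, "on", p$predictor)
    for (v in c(p$response, p$predictor))
      if (!v %in% names(table))
        stop("insufficient-data: variable ", v, " absent for pair ", lab)
    keep <- is.finite(table[[p$response]]) & is.finite(table[[p$predictor]])
    if (sum(keep) < 3L)
      stop("insufficient-data: fewer than 3 complete cases for pair ", lab)
    x <- log_transform(table[[p$predictor]][keep], table$specimen_id[keep])
    y <- log_transform(table[[p$response]][keep], table$specimen_id[keep])
    fit <- fit_sma(x, y, alpha)
    tst <- slope_test(x, y, p$null)
    decision <- if (tst$p_value < alpha) {
      if (fit$slope < p$null) "negative allometry" else "positive allometry"
    } else "isometry not rejected"
    data.frame(regression = lab, n = fit$n, r2 = fit$r2, slope = fit$slope,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               intercept = fit$intercept, null_slope = p$null,
               t = tst$test_statistic, p = tst$p_value, decision = decision,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
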