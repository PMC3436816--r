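# Xd significance threshold calibration.
#
# Xd scores and overlap q-values are strongly correlated for overlapping
# set pairs. That correlation is exploited: regress xd on -log10(q) over the
# overlapping pairs, then read off the Xd value matching a chosen q cutoff,
# adding the upper bound of the confidence band for the fitted mean response
# to account for uncertainty in the fitted parameters. Pairs with zero
# overlap carry no overlap information (q = 1 by construction) and are
# excluded from the fit, but are still ranked and thresholded by Xd.

#' Fit the Xd-versus-overlap-significance regression
#'
#' Ordinary least squares of `xd` on `x = -log10(q)` (default) or on raw `q`.
#' At least 3 finite pairs with `q` in (0, 1] are required; otherwise a
#' calibration-unavailable sentinel is returned and the threshold falls back
#' to a configured default downstream.
#'
#' @param xd numeric vector of Xd scores.
#' @param q matching vector of BH q-values in (0, 1].
#' @param transform `"neglog10"` (default) or `"raw"`.
#' @return object of class `xd_calibration`: list with `valid`, `slope`,
#'   `intercept`, `residual_std`, `n_points`, `pearson_r`, `transform` and the
#'   underlying `lm` fit (`model`). When `valid` is `FALSE` all numeric fields
#'   are `NA`.
#' @export
fit_xd_q_regression <- function(xd, q, transform = c("neglog10", "raw")) {
  transform <- match.arg(transform)
  stopifnot(length(xd) == length(q))
  ok <- is.finite(xd) & is.finite(q) & q > 0 & q <= 1
  xd <- xd[ok]; q <- q[ok]
  x <- if (transform == "neglog10") -log10(q) else q
  if (length(xd) < 3L || length(unique(x)) < 2L) {
    return(structure(list(valid = FALSE, slope = NA_real_, intercept = NA_real_,
                          residual_std = NA_real_, n_points = length(xd),
                          pearson_r = NA_real_, transform = transform,
                          model = NULL),
                     class = "xd_calibration"))
  }
  fit <- stats::lm(xd ~ x, data = data.frame(x = x, xd = xd))
  r <- if (stats::sd(xd) > 0) stats::cor(x, xd) else NA_real_
  if (is.na(r)) warning("constant xd across calibration points; correlation undefined")
  structure(list(valid = TRUE,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 # zero-residual (collinear) input is legitimate here; silence
                 # summary.lm's "essentially perfect fit" note
                 residual_std = suppressWarnings(summary(fit)$sigma),
                 n_points = length(xd),
                 pearson_r = r,
                 transform = transform,
                 model = fit),
            class = "xd_calibration")
}

#' @export
print.xd_calibration <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<xd_calibration> unavailable (%d usable points)\n", x$n_points))
  } else {
    cat(sprintf("<xd_calibration> xd = %.4g + %.4g * %s, n = %d, r = %.3f, sigma = %.4g\n",
                x$intercept, x$slope,
                if (x$transform == "neglog10") "-log10(q)" else "q",
                x$n_points, x$pearson_r, x$residual_std))
  }
  invisible(x)
}

#' Derive the Xd significance threshold from a calibration fit
#'
#' The threshold is the upper bound of the `conf`-level band at
#' `x = -log10(q_cut)` (or `x = q_cut` for a raw-q fit): the fitted mean
#' response plus a non-negative increment reflecting fit uncertainty. The
#' default band is the confidence band for the mean response; a prediction
#' band is available via `band`.
#'
#' @param fit an `xd_calibration`.
#' @param q_cut adjusted-p cutoff the threshold should correspond to
#'   (default 0.05).
#' @param conf confidence level of the band (default 0.95).
#' @param band `"confidence"` (default) or `"prediction"`.
#' @param fallback threshold returned (with a warning) when the fit is
#'   unavailable.
#' @return numeric Xd cutoff.
#' @export
significance_threshold <- function(fit, q_cut = 0.05, conf = 0.95,
                                   band = c("confidence", "prediction"),
                                   fallback = 0.5) {
  band <- match.arg(band)
  stopifnot(inherits(fit, "xd_calibration"), q_cut > 0, q_cut <= 1)
  if (!fit$valid) {
    warning("calibration unavailable; using fallback threshold")
    return(fallback)
  }
  x0 <- if (fit$transform == "neglog10") -log10(q_cut) else q_cut
  pr <- stats::predict(fit$model, newdata = data.frame(x = x0),
                       interval = band, level = conf)
  unname(pr[1L, "upr"])
}

#' Calibrate and flag a ranking table
#'
#' Convenience wrapper: fits the regression on rows with `overlap > 0`,
#' derives the threshold and adds a logical `significant_flag` column
#' (`xd >= threshold`; NA xd stays NA).
#'
#' @param ranking data.frame with columns `xd`, `overlap`, `fisher_q`.
#' @inheritParams significance_threshold
#' @param transform passed to [fit_xd_q_regression()].
#' @return the ranking with `significant_flag` added; attributes
#'   `calibration` (the fit) and `threshold`.
#' @export
calibrate_ranking <- function(ranking, q_cut = 0.05, conf = 0.95,
                              band = c("confidence", "prediction"),
                              transform = c("neglog10", "raw"),
                              fallback = 0.5) {
  band <- match.arg(band); transform <- match.arg(transform)
  use <- !is.na(ranking$xd) & !is.na(ranking$fisher_q) & ranking$overlap > 0
  fit <- fit_xd_q_regression(ranking$xd[use], ranking$fisher_q[use],
                             transform = transform)
  thr <- significance_threshold(fit, q_cut = q_cut, conf = conf, band = band,
                                fallback = fallback)
  ranking$significant_flag <- ranking$xd >= thr
  attr(ranking, "calibration") <- fit
  attr(ranking, "threshold") <- thr
  ranking
}
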