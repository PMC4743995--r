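# Growth-rate estimation and sigmoidal dose-response fitting.
#
# Salt tolerance is summarized by the concentrations inhibiting the maximum
# exponential growth rate by 10/25/50% (IC10/IC25/IC50), read from a
# three-parameter Hill inhibition curve fitted to rates normalized to the
# unstressed control:
#
#   r(c) = top / (1 + (c/k)^h),   top in [0.8, 1.2], k > 0, h > 0
#
# with the bottom fixed at 0. Under this model IC50 = k and
# IC_f = k * (f/(1-f))^(1/h).

#' Maximum exponential growth rate from a growth curve
#'
#' Fits a least-squares line to log(value) against time in every sliding
#' window of `window` consecutive points (after discarding values at or below
#' the detection floor) and returns the maximum slope, i.e. the maximum
#' exponential growth rate in 1/h.
#'
#' @param times Numeric vector of time points (h), strictly increasing.
#' @param values Non-negative measurements (OD or fluorescence-derived cell
#'   counts) at `times`.
#' @param window Number of consecutive points per regression window
#'   (default 8).
#' @param floor Detection floor; values `<= floor` are excluded (default 0).
#' @return Maximum growth rate (1/h).
#' @examples
#' t <- seq(0, 3, length.out = 10)
#' max_growth_rate(t, 0.05 * exp(0.6 * t), window = 5)
#' @export
max_growth_rate <- function(times, values, window = 8, floor = 0) {
  stopifnot(length(times) == length(values), window >= 2)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing")
  }
  if (any(values < 0, na.rm = TRUE)) stop("'values' must be non-negative")
  keep <- which(!is.na(values) & values > floor)
  if (length(keep) < window) {
    stop(sprintf("need at least %d values above the detection floor, have %d",
                 window, length(keep)))
  }
  tt <- times[keep]
  yy <- log(values[keep])
  n <- length(keep)
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    x <- tt[idx]; y <- yy[idx]
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }, numeric(1))
  max(slopes)
}

hill_rate <- function(conc, top, k, h) top / (1 + (conc / k)^h)

#' Fit a sigmoidal dose-response curve
#'
#' Least-squares fit of the three-parameter Hill inhibition model
#' `r(c) = top / (1 + (c/k)^h)` to growth rates normalized to the unstressed
#' control, with `top` constrained to `[0.8, 1.2]` and `k, h > 0`.
#' Initialization is multi-start over a grid of `(k, h)` values; the best
#' converged start (lowest residual sum of squares) is returned.
#'
#' If the fitted half-inhibitory concentration lies beyond the largest tested
#' concentration the IC values are extrapolations and the fit is flagged
#' `determined = FALSE` (e.g. when no inhibition is observed).
#'
#' @param conc Salt concentrations in mM; at least 4 distinct values
#'   including an unstressed (minimum) point.
#' @param rel_rates Growth rates relative to the unstressed control
#'   (dimensionless, roughly in `[0, 1.2]`).
#' @return Object of class `dose_response_fit` with elements `params`
#'   (named vector `top`, `k`, `h`), `ic10`, `ic25`, `ic50`, `rss`,
#'   `determined`, and the data.
#' @seealso [inhibitory_concentration()], [ic_from_growth()]
#' @export
fit_dose_response <- function(conc, rel_rates) {
  stopifnot(length(conc) == length(rel_rates))
  ok <- is.finite(conc) & is.finite(rel_rates)
  conc <- conc[ok]; rel_rates <- rel_rates[ok]
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct concentrations")
  }
  if (any(rel_rates < -0.05) || any(rel_rates > 1.5)) {
    stop("'rel_rates' must be normalized to the unstressed control (range ~[0, 1.2])")
  }
  cmax <- max(conc)
  cpos <- conc[conc > 0]
  k_starts <- unique(stats::quantile(cpos, c(0.25, 0.5, 0.75), names = FALSE))
  k_starts <- c(k_starts, cmax, 2 * cmax)
  h_starts <- c(0.5, 1, 2, 4)
  df <- data.frame(conc = conc, rate = rel_rates)
  lower <- c(top = 0.8, k = 1e-6, h = 0.05)
  upper <- c(top = 1.2, k = 1e6 * cmax, h = 20)
  best <- NULL
  diag <- character(0)
  for (k0 in k_starts) for (h0 in h_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(rate ~ top / (1 + (conc / k)^h), data = df,
                        start = list(top = 1, k = k0, h = h0),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diag <- c(diag, conditionMessage(fit))
      next
    }
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("dose-response fit failed to converge from any start: ",
         paste(unique(diag), collapse = "; "))
  }
  p <- stats::coef(best$fit)
  obj <- structure(
    list(params = c(top = unname(p["top"]), k = unname(p["k"]),
                    h = unname(p["h"])),
         rss = best$rss,
         conc = conc, rel_rates = rel_rates,
         determined = unname(p["k"]) <= cmax),
    class = "dose_response_fit")
  obj$ic10 <- inhibitory_concentration(obj, 0.10)
  obj$ic25 <- inhibitory_concentration(obj, 0.25)
  obj$ic50 <- inhibitory_concentration(obj, 0.50)
  obj
}

#' Concentration inhibiting growth by a given fraction
#'
#' Inverts the fitted Hill curve: the concentration at which the rate drops
#' to `(1 - fraction) * top`, i.e. `k * (fraction/(1-fraction))^(1/h)`.
#' IC50 equals the fitted `k`.
#'
#' @param fit A [fit_dose_response()] object, or a named vector/list with
#'   elements `k` and `h`.
#' @param fraction Inhibited fraction, strictly between 0 and 1.
#' @return Concentration in mM.
#' @export
inhibitory_concentration <- function(fit, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction <= 0 || fraction >= 1) {
    stop("'fraction' must lie strictly between 0 and 1")
  }
  p <- if (inherits(fit, "dose_response_fit")) fit$params else unlist(fit)
  unname(p["k"] * (fraction / (1 - fraction))^(1 / p["h"]))
}

#' @method print dose_response_fit
#' @export
print.dose_response_fit <- function(x, digits = 4, ...) {
  cat("Sigmoidal dose-response fit: r(c) = top / (1 + (c/k)^h)\n")
  cat(sprintf("  top = %.*g, k = %.*g mM, h = %.*g (RSS %.3g)\n",
              digits, x$params["top"], digits, x$params["k"],
              digits, x$params["h"], x$rss))
  cat(sprintf("  IC10 = %.*g  IC25 = %.*g  IC50 = %.*g mM%s\n",
              digits, x$ic10, digits, x$ic25, digits, x$ic50,
              if (x$determined) "" else "  [not determined: beyond tested range]"))
  invisible(x)
}

#' @method coef dose_response_fit
#' @export
coef.dose_response_fit <- function(object, ...) object$params

#' @method predict dose_response_fit
#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$conc else {
    if (is.data.frame(newdata)) newdata$conc else newdata
  }
  unname(hill_rate(conc, object$params["top"], object$params["k"],
                   object$params["h"]))
}

#' @method residuals dose_response_fit
#' @export
residuals.dose_response_fit <- function(object, ...) {
  object$rel_rates - predict(object)
}

#' @method plot dose_response_fit
#' @export
plot.dose_response_fit <- function(x, ...) {
  cpos <- x$conc[x$conc > 0]
  grid <- c(0, exp(seq(log(max(min(cpos), 1)), log(max(x$conc) * 1.2),
                       length.out = 200)))
  graphics::plot(x$conc, x$rel_rates, xlab = "NaCl (mM)",
                 ylab = "relative growth rate",
                 ylim = c(0, max(1.05, x$rel_rates)), ...)
  graphics::lines(grid, predict(x, grid), col = "firebrick")
  graphics::abline(v = c(x$ic10, x$ic25, x$ic50), lty = 3, col = "grey40")
  invisible(x)
}

#' Linear fluorescence-to-cell-count calibration
#'
#' For adherent cell lines the growth readout is a nuclear-stain fluorescence
#' intensity that is linear in cell number over its unsaturated range. Fits
#' `count = a + b * fluorescence` (b > 0) over the calibration points whose
#' fluorescence lies below `saturation` (default: all points).
#'
#' @param fluorescence,counts Calibration measurements.
#' @param saturation Upper fluorescence bound of the linear range.
#' @return List with `intercept`, `slope` and a `predict(fluorescence)`
#'   function.
#' @export
fluorescence_calibration <- function(fluorescence, counts, saturation = Inf) {
  keep <- is.finite(fluorescence) & is.finite(counts) &
    fluorescence <= saturation
  if (sum(keep) < 2L) stop("need at least 2 calibration points in range")
  fit <- stats::lm(counts[keep] ~ fluorescence[keep])
  b <- unname(stats::coef(fit))
  if (b[2] <= 0) stop("calibration slope is not positive")
  list(intercept = b[1], slope = b[2],
       predict = function(f) b[1] + b[2] * f)
}

#' IC values per organism from growth curves
#'
#' Convenience driver from raw growth curves to per-organism IC10/IC25/IC50.
#' For every (organism, replicate) series the maximum exponential growth rate
#' is computed per concentration, normalized to the rate at the lowest tested
#' concentration, and a dose-response curve is fitted per replicate; IC
#' values are reported as mean and standard deviation across replicates.
#'
#' @param curves Data frame with columns `organism_id`, `conc` (mM),
#'   `replicate`, `time` (h), `value`.
#' @param window Sliding-window width for [max_growth_rate()].
#' @return Data frame with one row per organism: mean and SD of each IC, and
#'   the number of replicate fits.
#' @export
ic_from_growth <- function(curves, window = 8) {
  need <- c("organism_id", "conc", "replicate", "time", "value")
  stopifnot(all(need %in% names(curves)))
  out <- lapply(split(curves, curves$organism_id), function(d) {
    fits <- lapply(split(d, d$replicate), function(r) {
      rates <- vapply(split(r, r$conc), function(cc) {
        max_growth_rate(cc$time, cc$value, window = window)
      }, numeric(1))
      conc <- as.numeric(names(rates))
      rel <- rates / rates[which.min(conc)]
      rel <- pmin(rel, 1.2)  # guard against noise pushing controls > top bound
      fit_dose_response(conc, rel)
    })
    ics <- vapply(fits, function(f) c(f$ic10, f$ic25, f$ic50), numeric(3))
    data.frame(organism_id = d$organism_id[1],
               ic10 = mean(ics[1, ]), ic10_sd = stats::sd(ics[1, ]),
               ic25 = mean(ics[2, ]), ic25_sd = stats::sd(ics[2, ]),
               ic50 = mean(ics[3, ]), ic50_sd = stats::sd(ics[3, ]),
               n_fits = length(fits),
               determined = all(vapply(fits, `[[`, logical(1), "determined")))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
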