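#' Plate-reader time series for one well
#'
#' @param times reading times (h), strictly increasing.
#' @param od optical density (or fluorescence) readings, finite.
#' @param well_id well identifier.
#' @param group replicate-group label (condition, concentration, ...).
#' @return An object of class `plate_series`.
#' @export
plate_series <- function(times, od, well_id = "W1", group = NA) {
  times <- as.numeric(times); od <- as.numeric(od)
  if (length(times) != length(od)) stop("times and od must match in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(od))) stop("od readings must be finite")
  structure(list(times = times, od = od, well_id = well_id, group = group),
            class = "plate_series")
}

#' Exponential growth rate from OD readings
#'
#' Implements the standard plate-reader protocol: the per-well background is
#' the mean of readings at time-points 3-10 (the first two points are
#' dropped; condensation before the plate reaches temperature makes them
#' unreliable). After background subtraction, only points with
#' `window[1] < OD < window[2]` are kept (avoiding noise at low OD and
#' saturation at high OD) and a line is fitted to `log(OD)` versus time; the
#' slope is the growth rate. Because the background window also contains
#' the (small) live-cell signal, the estimate carries a slight upward bias
#' that shrinks with the inoculum-to-window ratio; supply `background` if
#' the blank is known.
#'
#' @param series a [plate_series()] with at least 10 time points.
#' @param window OD window for the log-linear fit.
#' @param background known background to subtract instead of estimating it.
#' @param background_points indices of the readings averaged for the
#'   background estimate.
#' @param drop_first leading readings excluded from the fit.
#' @param t_cap optional cap (h) on reading times used in the fit (e.g. the
#'   first 3 h for fluorescence assays where the mediator depletes).
#' @param min_points minimum number of in-window points for a fit.
#' @return The growth rate (1/h), or `NA` with attribute
#'   `"reason" = "no_fit"` when fewer than `min_points` readings fall in the
#'   window.
#' @export
growth_rate_from_od <- function(series, window = c(0.002, 0.02),
                                background = NULL,
                                background_points = 3:10, drop_first = 2,
                                t_cap = NULL, min_points = 3) {
  stopifnot(inherits(series, "plate_series"))
  if (length(series$od) < 10) stop("need at least 10 time points")
  bg <- if (is.null(background)) mean(series$od[background_points])
  else background
  keep <- seq_along(series$od) > drop_first
  if (!is.null(t_cap)) keep <- keep & series$times <= t_cap
  od <- series$od[keep] - bg
  tt <- series$times[keep]
  inwin <- od > window[1] & od < window[2]
  if (sum(inwin) < min_points) {
    out <- NA_real_
    attr(out, "reason") <- "no_fit"
    return(out)
  }
  unname(coef(lm(log(od[inwin]) ~ tt[inwin]))[2])
}

#' Growth rates for every well of a long-format plate table
#'
#' @param plate a data.frame with columns `time`, `well`, `value` (and
#'   optionally `group`), as returned by [read_plate_csv()].
#' @param ... passed to [growth_rate_from_od()].
#' @return A data.frame with one row per well: `well`, `group`, `rate`.
#' @export
growth_rates_from_plate <- function(plate, ...) {
  wells <- split(plate, plate$well)
  out <- lapply(wells, function(w) {
    w <- w[order(w$time), ]
    grp <- if ("group" %in% names(w)) w$group[1] else NA
    rate <- growth_rate_from_od(
      plate_series(w$time, w$value, well_id = w$well[1], group = grp), ...)
    data.frame(well = w$well[1], group = grp, rate = as.numeric(rate),
               no_fit = is.na(rate))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

dose_response_laws <- c("linear_inhibition", "threshold_inhibition",
                        "growth_inhibition", "monod", "moser")

law_fun <- function(law) {
  switch(law,
    linear_inhibition = function(C, p) p$r0 - p$strength * C,
    threshold_inhibition = function(C, p)
      p$r0 - p$strength * pmax(C - p$c_th, 0),
    growth_inhibition = function(C, p)
      ifelse(C > p$c_th, p$r0 - p$strength / (1 + p$K / (C - p$c_th)), p$r0),
    monod = function(C, p) p$r0 + p$strength * C / (C + p$K),
    moser = function(C, p)
      p$r0 + p$strength * C^p$n / (C^p$n + p$K^p$n))
}

#' Fit a dose-response law to growth-rate measurements
#'
#' Least-squares fit of one of the five response laws to (concentration,
#' rate) pairs: linear inhibition (`r0 - s C`, where the slope `s` is the
#' identifiable ratio of inhibition strength to its normalization
#' concentration), threshold inhibition, saturating "growth inhibition",
#' Monod facilitation, and Moser facilitation (exponent constrained to
#' `[1, 3]`). Nonlinear laws are fitted by Levenberg-Marquardt; the linear
#' law in closed form.
#'
#' @param concentrations mediator concentrations (fmol/ml), `>= 0`.
#' @param rates measured growth rates (1/h); at least 4 pairs.
#' @param law one of `"linear_inhibition"`, `"threshold_inhibition"`,
#'   `"growth_inhibition"`, `"monod"`, `"moser"`.
#' @return An object of class `dose_response_fit`: `law`, `r0_hat`,
#'   `strength_hat`, `K_hat`, `c_th_hat`, `n_hat`, `rss`, `fitted`,
#'   `converged`.
#' @export
fit_dose_response <- function(concentrations, rates, law = dose_response_laws) {
  law <- match.arg(law)
  C <- as.numeric(concentrations); y <- as.numeric(rates)
  if (length(C) != length(y)) stop("concentration/rate lengths differ")
  if (length(C) < 4) stop("need at least 4 (concentration, rate) pairs")
  if (any(C < 0)) stop("concentrations must be non-negative")
  est <- list(r0 = NA_real_, strength = NA_real_, K = NA_real_,
              c_th = NA_real_, n = NA_real_)
  converged <- TRUE
  if (law == "linear_inhibition") {
    fit <- lm(y ~ C)
    est$r0 <- unname(coef(fit)[1])
    est$strength <- -unname(coef(fit)[2])
  } else {
    span <- diff(range(y))
    posC <- C[C > 0]
    start <- switch(law,
      threshold_inhibition = list(r0 = max(y), strength = span / diff(range(C)),
                                  c_th = stats::median(C)),
      growth_inhibition = list(r0 = max(y), strength = span,
                               K = stats::median(posC),
                               c_th = min(posC) / 2),
      monod = list(r0 = min(y), strength = span, K = stats::median(posC)),
      moser = list(r0 = min(y), strength = span, K = stats::median(posC),
                   n = 2))
    lower <- switch(law,
      threshold_inhibition = c(-Inf, 0, 0),
      growth_inhibition = c(-Inf, 0, 1e-12, 0),
      monod = c(-Inf, 0, 1e-12),
      moser = c(-Inf, 0, 1e-12, 1))
    upper <- if (law == "moser") c(Inf, Inf, Inf, 3) else
      rep(Inf, length(lower))
    form <- switch(law,
      threshold_inhibition = y ~ r0 - strength * pmax(C - c_th, 0),
      growth_inhibition =
        y ~ ifelse(C > c_th, r0 - strength / (1 + K / (C - c_th)), r0),
      monod = y ~ r0 + strength * C / (C + K),
      moser = y ~ r0 + strength * C^n / (C^n + K^n))
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(C = C, y = y),
                        start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      converged <- FALSE
    } else {
      cf <- as.list(coef(fit))
      for (nm in names(cf)) est[[nm]] <- cf[[nm]]
    }
  }
  fitted <- if (converged) law_fun(law)(C, est) else rep(NA_real_, length(C))
  structure(list(law = law, r0_hat = est$r0, strength_hat = est$strength,
                 K_hat = est$K, c_th_hat = est$c_th, n_hat = est$n,
                 rss = if (converged) sum((y - fitted)^2) else NA_real_,
                 fitted = fitted, concentrations = C, rates = y,
                 converged = converged),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> law = ", x$law,
      if (!x$converged) "  [did not converge]", "\n", sep = "")
  ests <- c(r0 = x$r0_hat, strength = x$strength_hat, K = x$K_hat,
            c_th = x$c_th_hat, n = x$n_hat)
  ests <- ests[!is.na(ests)]
  cat("  ", paste(names(ests), format(ests, digits = 4), sep = " = ",
                  collapse = ", "), "\n", sep = "")
  cat("  RSS = ", format(x$rss, digits = 4), " over ",
      length(x$rates), " points\n", sep = "")
  invisible(x)
}

#' Compare dose-response laws on the same data
#'
#' @inheritParams fit_dose_response
#' @param laws laws to fit (default all five).
#' @return A data.frame of residual sums of squares, ordered best-first.
#' @export
compare_dose_response <- function(concentrations, rates,
                                  laws = dose_response_laws) {
  fits <- lapply(laws, function(l)
    fit_dose_response(concentrations, rates, l))
  out <- data.frame(law = laws,
                    rss = vapply(fits, function(f) f$rss, numeric(1)),
                    converged = vapply(fits, function(f) f$converged,
                                       logical(1)))
  out[order(out$rss), , drop = FALSE]
}

#' Synthetic plate-reader growth curve with known ground truth
#'
#' Generates `od(t) = background + amplitude * exp(rate * t)` (optionally
#' capped logistically at `saturation`) with Gaussian measurement noise;
#' deterministic under `seed`. Used so growth-rate extraction can be tested
#' without instrument data.
#'
#' @param rate true exponential rate (1/h).
#' @param background additive instrument background OD.
#' @param amplitude initial live-cell OD signal.
#' @param times reading times (h); default 5-min intervals over 24 h.
#' @param noise_sd Gaussian noise s.d. on each reading.
#' @param saturation optional carrying-capacity OD for a logistic curve.
#' @param seed RNG seed.
#' @param well_id,group passed to [plate_series()].
#' @return A [plate_series()].
#' @export
make_od_fixture <- function(rate, background = 0.09, amplitude = 0.001,
                            times = seq(0, 24, by = 5 / 60), noise_sd = 0,
                            saturation = NULL, seed = NULL,
                            well_id = "synthW1", group = NA) {
  signal <- if (is.null(saturation)) amplitude * exp(rate * times)
  else { # logistic with the same early-phase exponential rate
    saturation * amplitude /
      (amplitude + (saturation - amplitude) * exp(-rate * times))
  }
  od <- background + signal
  if (noise_sd > 0)
    od <- od + with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  plate_series(times, od, well_id = well_id, group = group)
}

#' Synthetic dose-response table with known ground truth
#'
#' @param law one of the five dose-response laws.
#' @param params named list of true parameters (`r0`, `strength`, and `K`,
#'   `c_th`, `n` as the law requires).
#' @param concentrations design concentrations.
#' @param noise_sd Gaussian noise s.d. on rates.
#' @param replicates measurements per concentration.
#' @param seed RNG seed.
#' @return A data.frame with columns `concentration`, `rate`.
#' @export
make_dose_response_fixture <- function(law, params, concentrations,
                                       noise_sd = 0, replicates = 1,
                                       seed = NULL) {
  law <- match.arg(law, dose_response_laws)
  C <- rep(concentrations, each = replicates)
  y <- law_fun(law)(C, params)
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(C), 0, noise_sd))
  data.frame(concentration = C, rate = y)
}
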