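#' Amplification time (At) of a fluorescence trace
#'
#' At is the time at which the (baseline-subtracted) signal first rises
#' above a threshold, linearly interpolated between the bracketing samples —
#' the isothermal analogue of the qPCR Ct. The baseline is the mean of the
#' first `min(3, ceiling(n/10))` samples (at least one), so short
#' already-baselined traces are left untouched while plate traces get the
#' mean of their first three readings removed.
#'
#' @param tr A [celia_trace()].
#' @param threshold Either `list(absolute = <signal units>)` (raw-signal
#'   scale, as when one fixed threshold line is shared by all wells) or
#'   `list(fraction_of_max = <0..1>)` (fraction of that trace's own plateau,
#'   robust to per-well optical rescaling; default 0.2).
#' @return A list: `at` (min, `NA` if never crossed), `threshold_used`
#'   (baseline-subtracted scale), `crossed` (logical).
#' @export
#' @examples
#' tr <- celia_trace(c(0, 10, 20), c(0, 0.4, 1.2))
#' amplification_time(tr, list(absolute = 1.0))$at  # 17.5
amplification_time <- function(tr, threshold = list(fraction_of_max = 0.2)) {
  stopifnot(inherits(tr, "celia_trace"))
  n <- length(tr$times)
  if (n < 2L) stop("trace needs at least 2 points", call. = FALSE)
  nb <- max(1L, min(3L, ceiling(n / 10)))
  base <- mean(tr$values[seq_len(nb)])
  v <- tr$values - base
  if (!is.null(threshold$absolute)) {
    thr <- threshold$absolute - base
  } else if (!is.null(threshold$fraction_of_max)) {
    f <- threshold$fraction_of_max
    if (f <= 0 || f >= 1)
      stop("fraction_of_max must be in (0, 1)", call. = FALSE)
    thr <- f * max(v)
  } else {
    stop("threshold must carry 'absolute' or 'fraction_of_max'",
         call. = FALSE)
  }
  if (thr <= 0)
    stop("threshold must exceed the baseline", call. = FALSE)
  above <- v >= thr
  if (!any(above))
    return(list(at = NA_real_, threshold_used = thr, crossed = FALSE))
  i <- which(above)[1L]
  at <- if (i == 1L) tr$times[1L] else {
    tr$times[i - 1L] + (tr$times[i] - tr$times[i - 1L]) *
      (thr - v[i - 1L]) / (v[i] - v[i - 1L])
  }
  list(at = at, threshold_used = thr, crossed = TRUE)
}

#' Gain, saturation and linear window of an amplification trace
#'
#' Characterizes the linear amplifier's observables: the plateau
#' (saturation), the time to reach `sat_fraction` of it (the linear window)
#' and the slope of the rising phase (the gain), fitted by ordinary least
#' squares over the central `fit_span` of the rising-phase points.
#'
#' The plateau is accepted when the local slope over the final 5% of the
#' trace has fallen below 1% of the peak slope; the saturation is then the
#' mean of those final points. Otherwise the trace is censored at its end:
#' the maximum value is reported as the saturation and the window is `NA`.
#'
#' @param tr A [celia_trace()].
#' @param sat_fraction Fraction of saturation defining the window (0.99).
#' @param fit_span Central fraction of rising-phase points used in the gain
#'   fit (0.8).
#' @return An object of class `celia_linfit`: `gain` (signal/min),
#'   `intercept`, `saturation` (signal units), `window` (min; `NA` when
#'   censored), `r2_fit`, `censored`.
#' @export
linear_phase_fit <- function(tr, sat_fraction = 0.99, fit_span = 0.8) {
  stopifnot(inherits(tr, "celia_trace"),
            sat_fraction > 0, sat_fraction < 1,
            fit_span > 0, fit_span <= 1)
  t <- tr$times
  v <- tr$values
  n <- length(t)
  if (n < 8L) stop("trace too short for linear-phase characterization",
                   call. = FALSE)
  slopes <- diff(v) / diff(t)
  max_slope <- max(slopes)
  if (max_slope <= 0)
    stop("trace has no rising phase", call. = FALSE)
  ntail <- max(1L, ceiling(0.05 * n))
  tail_slope <- mean(slopes[seq.int(n - ntail, n - 1L)])
  censored <- tail_slope >= 0.01 * max_slope
  if (censored) {
    saturation <- max(v)
    window <- NA_real_
  } else {
    saturation <- mean(v[seq.int(n - ntail + 1L, n)])
    window <- {
      target <- v[1L] + sat_fraction * (saturation - v[1L])
      i <- which(v >= target)[1L]
      if (i == 1L) t[1L]
      else t[i - 1L] + (t[i] - t[i - 1L]) *
        (target - v[i - 1L]) / (v[i] - v[i - 1L])
    }
  }
  # rising phase: contiguous run around the peak (smoothed) slope where the
  # local slope keeps at least half of it; this tracks the developed linear
  # regime and is invariant under time-translation of the amplification
  w <- min(5L, length(slopes))
  ssm <- stats::filter(slopes, rep(1 / w, w), sides = 2)
  ssm[is.na(ssm)] <- slopes[is.na(ssm)]
  imax <- which.max(ssm)
  keep <- ssm >= 0.5 * ssm[imax]
  lo <- imax
  while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- imax
  while (hi < length(keep) && keep[hi + 1L]) hi <- hi + 1L
  rising <- seq.int(lo, hi + 1L)   # slope i spans points i, i+1
  if (!censored)                   # don't fit into the plateau
    rising <- rising[t[rising] <= window]
  if (length(rising) < 4L)
    stop("fewer than 4 rising-phase points", call. = FALSE)
  drop <- floor(length(rising) * (1 - fit_span) / 2)
  core <- rising[seq.int(1L + drop, length(rising) - drop)]
  fit <- stats::lm(v[core] ~ t[core])
  structure(list(gain = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 saturation = saturation, window = window,
                 r2_fit = r_squared(fit, v[core]), censored = censored),
            class = "celia_linfit")
}

#' @export
print.celia_linfit <- function(x, ...) {
  cat(sprintf(
    "linear phase: gain = %.4g signal/min, saturation = %.4g, window = %s min (r2 = %.4f)%s\n",
    x$gain, x$saturation,
    if (is.na(x$window)) "NA" else sprintf("%.4g", x$window),
    x$r2_fit, if (x$censored) " [censored at trace end]" else ""))
  invisible(x)
}

#' Endpoint signal at a fixed time
#'
#' @param tr A [celia_trace()].
#' @param t_end Readout time (min), within the trace span.
#' @return Signal value, linearly interpolated between samples.
#' @export
endpoint_signal <- function(tr, t_end) {
  stopifnot(inherits(tr, "celia_trace"))
  if (t_end < min(tr$times) || t_end > max(tr$times))
    stop("t_end = ", t_end, " outside trace span", call. = FALSE)
  stats::approx(tr$times, tr$values, xout = t_end)$y
}

#' Regress endpoint signal on amplification time
#'
#' Ordinary least squares of endpoint on At across wells. A coupled
#' exponential-to-linear circuit yields a negative slope; the inverter
#' yields a positive one.
#'
#' @param pairs data.frame with columns `at` (min) and `endpoint` (signal
#'   units); at least 2 rows with distinct At.
#' @return List with `slope`, `intercept`, `r2`.
#' @export
endpoint_at_regression <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("at", "endpoint") %in% names(pairs)))
  pairs <- pairs[is.finite(pairs$at) & is.finite(pairs$endpoint), ]
  if (nrow(pairs) < 2L)
    stop("need at least 2 finite (At, endpoint) pairs", call. = FALSE)
  if (length(unique(pairs$at)) < 2L)
    stop("degenerate regression: all At equal", call. = FALSE)
  fit <- stats::lm(endpoint ~ at, data = pairs)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = r_squared(fit, pairs$endpoint))
}

# R^2 without summary.lm's perfect-fit warning; exact fits report 1
r_squared <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / ss_tot))
}

#' Per-well observables of a plate experiment
#'
#' Extracts, for every well, the amplification time from the `"alpha"`
#' channel and the gain / saturation / window / endpoint from the `"omega"`
#' channel. Wells whose trace does not admit an observable (no threshold
#' crossing, flat signal) get `NA` in the corresponding column.
#'
#' @param plate A `celia_plate` (see [generate_plate()]) or a named list of
#'   `celia_traceset` objects.
#' @param t_end Endpoint readout time (min; default: last common time).
#' @param threshold At threshold specification (see [amplification_time()]).
#' @return data.frame: `well_id`, `channel`, `at_min`, `gain`, `saturation`,
#'   `window_min`, `endpoint`.
#' @export
analyze_wells <- function(plate, t_end = NULL,
                          threshold = list(fraction_of_max = 0.2)) {
  tracesets <- if (inherits(plate, "celia_plate")) plate$traces else plate
  stopifnot(length(tracesets) >= 1L)
  ids <- names(tracesets)
  if (is.null(ids)) ids <- sprintf("W%03d", seq_along(tracesets))
  rows <- lapply(seq_along(tracesets), function(i) {
    ts <- tracesets[[i]]
    te <- if (is.null(t_end)) max(ts$times) else t_end
    at <- NA_real_
    if ("alpha" %in% colnames(ts$channels)) {
      res <- tryCatch(
        amplification_time(get_trace(ts, "alpha", ids[i]), threshold),
        error = function(e) NULL)
      if (!is.null(res) && res$crossed) at <- res$at
    }
    gain <- sat <- win <- ep <- NA_real_
    if ("omega" %in% colnames(ts$channels)) {
      tro <- get_trace(ts, "omega", ids[i])
      lf <- tryCatch(linear_phase_fit(tro), error = function(e) NULL)
      if (!is.null(lf)) {
        gain <- lf$gain; sat <- lf$saturation; win <- lf$window
      }
      ep <- tryCatch(endpoint_signal(tro, te), error = function(e) NA_real_)
    }
    data.frame(well_id = ids[i], channel = "omega", at_min = at,
               gain = gain, saturation = sat, window_min = win,
               endpoint = ep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
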