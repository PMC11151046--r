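#' Evaluate the calibration sigmoid
#'
#' The endpoint-vs-log-concentration calibration curve is the sigmoid
#' `f(x) = L + H / (1 + b * exp(-k (x - x0)))`, with `x = log10` of the
#' molar concentration, `L` the lower bound, `L + H` the upper asymptote,
#' `k` the steepness and `x0` the mid-point.
#'
#' @param m A `celia_calibration` model (or a list with `L`, `H`, `b`, `k`,
#'   `x0`).
#' @param x log10 molar concentration(s).
#' @return Signal units.
#' @export
#' @examples
#' m <- list(L = 0, H = 10, b = 1, k = 1, x0 = 0)
#' sigmoid_eval(m, 0)  # 5, the midpoint
sigmoid_eval <- function(m, x) {
  m$L + m$H / (1 + m$b * exp(-m$k * (x - m$x0)))
}

#' Fit the endpoint calibration sigmoid
#'
#' Nonlinear least squares fit of the sigmoid to calibration points
#' (replicates allowed), with deterministic multi-start initialization:
#' `L = min(y)`, `H = diff(range(y))`, `x0` from the half-range crossing or
#' the median `x`, and `k` in `{0.5, 1, 2, 4}` (8 starts); the best
#' sum-of-squares wins, ties broken by the smallest `k`. The shape parameter
#' `b` is redundant with `x0` (`b = exp(k * delta)`), so it is held at 1 and
#' absorbed into `x0`; the fitted curve is unaffected.
#'
#' @param x log10 molar concentrations (blanks must be excluded — log of
#'   zero is undefined; they belong to [lod()]).
#' @param y Endpoint signals (same length).
#' @return An object of class `celia_calibration`: `L`, `H`, `b` (= 1),
#'   `k`, `x0`, `residual_sd`, `lod_molar` (`NA` until [lod()] is run),
#'   `x_range`, and the fitting data.
#' @export
fit_sigmoid <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  ux <- sort(unique(x))
  if (length(ux) < 5L)
    stop("calibration needs >= 5 distinct concentrations", call. = FALSE)
  if (diff(range(ux)) < 3)
    stop("calibration must span >= 3 decades of concentration",
         call. = FALSE)
  L0 <- min(y)
  H0 <- max(y) - min(y)
  if (H0 <= 0) stop("calibration signals are constant", call. = FALSE)
  ymid <- L0 + H0 / 2
  x0_half <- x[which.min(abs(y - ymid))]
  starts <- expand.grid(k = c(0.5, 1, 2, 4),
                        x0 = unique(c(x0_half, stats::median(x))))
  if (nrow(starts) < 8L)
    starts <- starts[rep(seq_len(nrow(starts)), length.out = 8L), ]
  dat <- data.frame(x = x, y = y)
  best <- NULL
  best_sse <- Inf
  best_k_start <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ L + H / (1 + exp(-k * (x - x0))), data = dat,
        start = list(L = L0, H = H0, k = starts$k[i], x0 = starts$x0[i]),
        lower = c(L = -Inf, H = 1e-12, k = 1e-6, x0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (sse < best_sse * (1 - 1e-9) ||
        (abs(sse - best_sse) <= 1e-9 * max(best_sse, 1) &&
         starts$k[i] < best_k_start)) {
      best <- fit
      best_sse <- sse
      best_k_start <- starts$k[i]
    }
  }
  if (is.null(best))
    stop("sigmoid fit failed to converge from all 8 starts; check that the ",
         "calibration spans both asymptotes", call. = FALSE)
  cf <- stats::coef(best)
  dof <- max(1L, length(y) - 4L)
  structure(list(L = unname(cf["L"]), H = unname(cf["H"]), b = 1,
                 k = unname(cf["k"]), x0 = unname(cf["x0"]),
                 residual_sd = sqrt(best_sse / dof),
                 lod_molar = NA_real_,
                 x_range = range(x), data = dat),
            class = "celia_calibration")
}

#' @export
print.celia_calibration <- function(x, ...) {
  cat("Endpoint calibration sigmoid f(x) = L + H/(1 + b exp(-k (x - x0)))\n")
  cat(sprintf("  L = %.4g, H = %.4g, b = %g, k = %.4g per log10 M, x0 = %.4g\n",
              x$L, x$H, x$b, x$k, x$x0))
  cat(sprintf("  residual sd = %.4g; calibrated range 1e%+.0f .. 1e%+.0f M\n",
              x$residual_sd, x$x_range[1], x$x_range[2]))
  if (is.finite(x$lod_molar))
    cat(sprintf("  LoD = %.3g M\n", x$lod_molar))
  invisible(x)
}

#' @export
summary.celia_calibration <- function(object, ...) {
  print(object)
  cat("note: b is not identifiable jointly with x0 (b = exp(k*delta));\n",
      "      it is held at 1 and absorbed into x0 during fitting.\n",
      sep = "")
  pred <- sigmoid_eval(object, object$data$x)
  cat(sprintf("fit on %d points; RMS residual %.4g\n",
              nrow(object$data),
              sqrt(mean((object$data$y - pred)^2))))
  invisible(object)
}

#' @export
coef.celia_calibration <- function(object, ...) {
  c(L = object$L, H = object$H, b = object$b, k = object$k, x0 = object$x0)
}

#' @export
residuals.celia_calibration <- function(object, ...) {
  object$data$y - sigmoid_eval(object, object$data$x)
}

#' Predict from a calibration model
#'
#' @param object A `celia_calibration`.
#' @param x log10 molar concentrations (`type = "response"`) or endpoint
#'   signals (`type = "inverse"`).
#' @param type `"response"` maps concentration to signal; `"inverse"` maps
#'   signal back to log10 molar concentration (NA outside the invertible
#'   band).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.celia_calibration <- function(object, x,
                                      type = c("response", "inverse"),
                                      ...) {
  type <- match.arg(type)
  if (type == "response") return(sigmoid_eval(object, x))
  vapply(x, function(yy) invert_sigmoid(object, yy)$x, numeric(1))
}

#' @export
plot.celia_calibration <- function(x, ...) {
  xs <- seq(x$x_range[1] - 0.5, x$x_range[2] + 0.5, length.out = 200)
  graphics::plot(x$data$x, x$data$y, xlab = "log10 concentration (M)",
                 ylab = "endpoint signal (a.u.)", ...)
  graphics::lines(xs, sigmoid_eval(x, xs))
  if (is.finite(x$lod_molar))
    graphics::abline(v = log10(x$lod_molar), lty = 2)
  invisible(x)
}

#' Invert the calibration sigmoid
#'
#' Closed-form inverse `x = x0 - (1/k) * log((H/(y - L) - 1)/b)`, defined on
#' the open band `(L + eps, L + H - eps)` with
#' `eps = max(residual_sd, 1e-6 * H)`; outside the band the estimate is
#' censored.
#'
#' @param m A `celia_calibration` (or list with `L`, `H`, `b`, `k`, `x0`,
#'   optionally `residual_sd`).
#' @param y Endpoint signal (single value).
#' @return List with `x` (log10 molar, `NA` if censored) and `flag` (one of
#'   `"ok"`, `"below_range"`, `"above_range"`).
#' @export
invert_sigmoid <- function(m, y) {
  rsd <- if (is.null(m$residual_sd) || !is.finite(m$residual_sd)) 0
         else m$residual_sd
  eps <- max(rsd, 1e-6 * m$H)
  if (y <= m$L + eps)
    return(list(x = NA_real_, flag = "below_range"))
  if (y >= m$L + m$H - eps)
    return(list(x = NA_real_, flag = "above_range"))
  list(x = m$x0 - (1 / m$k) * log((m$H / (y - m$L) - 1) / m$b), flag = "ok")
}

#' Limit of detection from blank endpoints
#'
#' The LoD is the concentration whose calibrated signal equals the blank
#' mean plus three blank standard deviations (sample SD, n - 1
#' denominator), mapped through the inverse calibration.
#'
#' @param m A `celia_calibration`.
#' @param blank_endpoints Endpoint signals of negative-control wells
#'   (>= 2 values).
#' @return List: `y_star` (blank mean + 3 SD), `lod_molar` (M; `NA` when
#'   `y_star` falls below the invertible band, i.e. the LoD is below the
#'   lowest calibrated concentration), `censored_low` (logical).
#' @export
lod <- function(m, blank_endpoints) {
  stopifnot(inherits(m, "celia_calibration") || is.list(m))
  if (length(blank_endpoints) < 2L)
    stop("need >= 2 blank endpoints to define an SD", call. = FALSE)
  mu <- mean(blank_endpoints)
  if (mu >= m$L + m$H)
    stop("blank signals at or above the upper asymptote: assay failure",
         call. = FALSE)
  y_star <- mu + 3 * stats::sd(blank_endpoints)
  inv <- invert_sigmoid(m, y_star)
  if (identical(inv$flag, "above_range"))
    stop("blank mean + 3 SD exceeds the calibrated range: assay failure",
         call. = FALSE)
  censored <- identical(inv$flag, "below_range")
  list(y_star = y_star,
       lod_molar = if (censored) NA_real_ else 10^inv$x,
       censored_low = censored)
}

#' Estimate concentrations from endpoint signals
#'
#' Maps endpoint signals through the inverse calibration and applies the
#' censoring policy: signals outside the invertible band are flagged
#' `below_range` / `above_range` with no numeric estimate; in-band
#' estimates below the LoD are flagged `below_lod` (estimate retained for
#' inspection but excluded from accuracy summaries).
#'
#' @param m A `celia_calibration`.
#' @param endpoints Endpoint signals.
#' @param lod_molar Optional LoD (M); defaults to `m$lod_molar`.
#' @param well_id Optional well identifiers.
#' @return data.frame: `well_id`, `endpoint_used`, `estimate_molar`,
#'   `flag`.
#' @export
quantify_endpoints <- function(m, endpoints, lod_molar = NULL,
                               well_id = NULL) {
  if (is.null(lod_molar)) lod_molar <- m$lod_molar
  if (is.null(well_id)) well_id <- sprintf("W%03d", seq_along(endpoints))
  rows <- lapply(seq_along(endpoints), function(i) {
    inv <- invert_sigmoid(m, endpoints[i])
    est <- if (is.na(inv$x)) NA_real_ else 10^inv$x
    flag <- inv$flag
    if (identical(flag, "ok") && !is.null(m$x_range)) {
      if (inv$x < m$x_range[1]) flag <- "below_range"
      else if (inv$x > m$x_range[2]) flag <- "above_range"
      if (flag != "ok") est <- NA_real_
    }
    if (identical(flag, "ok") && is.finite(lod_molar) && est < lod_molar)
      flag <- "below_lod"
    data.frame(well_id = well_id[i], endpoint_used = endpoints[i],
               estimate_molar = est, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fold-difference accuracy of a quantification panel
#'
#' The per-sample fold difference is the symmetric ratio
#' `max(estimate/truth, truth/estimate) >= 1`. Censored or invalid
#' estimates (non-positive, NA, flag other than `"ok"`) are excluded and
#' counted.
#'
#' @param estimate_molar Estimated concentrations (M).
#' @param true_molar Spiked (true) concentrations (M, > 0).
#' @param flag Optional per-sample flags; only `"ok"` samples enter the
#'   summary.
#' @return List: `fd` (per-sample fold differences), `mean_fd`, `sd_fd`,
#'   `n_used`, `n_censored`.
#' @export
fold_difference <- function(estimate_molar, true_molar, flag = NULL) {
  stopifnot(length(estimate_molar) == length(true_molar))
  if (any(!is.finite(true_molar) | true_molar <= 0))
    stop("true concentrations must be positive", call. = FALSE)
  use <- is.finite(estimate_molar) & estimate_molar > 0
  if (!is.null(flag)) use <- use & flag == "ok"
  r <- estimate_molar[use] / true_molar[use]
  fd <- pmax(r, 1 / r)
  list(fd = fd, mean_fd = if (length(fd)) mean(fd) else NA_real_,
       sd_fd = if (length(fd) > 1L) stats::sd(fd) else NA_real_,
       n_used = sum(use), n_censored = sum(!use))
}
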