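#' Solver options for deterministic integration
#'
#' @param rel_tol Relative tolerance (dimensionless).
#' @param abs_tol Absolute tolerance (nM).
#' @param max_step Maximum internal step (min; `Inf` = unrestricted).
#' @param method_hint `"stiff"` (default; LSODA switches automatically) or
#'   `"nonstiff"`.
#' @return An object of class `celia_solver_options`.
#' @export
solver_options <- function(rel_tol = 1e-8, abs_tol = 1e-12, max_step = Inf,
                           method_hint = c("stiff", "nonstiff")) {
  method_hint <- match.arg(method_hint)
  stopifnot(rel_tol > 0, abs_tol > 0, max_step > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 method_hint = method_hint),
            class = "celia_solver_options")
}

# compile the network into fast index structures for rate evaluation
compile_network <- function(net) {
  spn <- net$species$name
  ns <- length(spn)
  rxs <- net$reactions
  nr <- length(rxs)
  S <- matrix(0, ns, nr, dimnames = list(spn, NULL))
  factors <- vector("list", nr)   # list of (index, power)
  driver_i <- rep(NA_integer_, nr)
  K <- rep(NA_real_, nr)
  k <- numeric(nr)
  for (j in seq_len(nr)) {
    rx <- rxs[[j]]
    k[j] <- rx$rate_constant
    for (nm in names(rx$reactants))
      S[nm, j] <- S[nm, j] - rx$reactants[[nm]]
    for (nm in names(rx$products))
      S[nm, j] <- S[nm, j] + rx$products[[nm]]
    pow <- c(rx$reactants,
             stats::setNames(rep(1L, length(rx$modifiers)), rx$modifiers))
    if (rx$form == "saturating") {
      driver_i[j] <- match(rx$driver, spn)
      K[j] <- rx$half_saturation
      pow <- pow[names(pow) != rx$driver]
    }
    factors[[j]] <- cbind(idx = match(names(pow), spn),
                          pow = as.numeric(pow))
  }
  rate_fn <- function(y) {
    y <- pmax(y, 0)
    r <- k
    for (j in seq_len(nr)) {
      f <- factors[[j]]
      if (nrow(f))
        r[j] <- r[j] * prod(y[f[, "idx"]]^f[, "pow"])
      if (!is.na(driver_i[j])) {
        d <- y[driver_i[j]]
        r[j] <- r[j] * d / (K[j] + d)
      }
    }
    r
  }
  list(species = spn, S = S, rate_fn = rate_fn, nr = nr)
}

eval_channels <- function(net, conc) {
  chn <- names(net$reporters)
  out <- matrix(0, nrow(conc), length(chn),
                dimnames = list(NULL, chn))
  for (ch in chn) {
    rp <- net$reporters[[ch]]
    out[, ch] <- if (identical(rp$type, "species")) {
      rp$s_F * conc[, rp$species]
    } else {
      d <- conc[, rp$driver]
      rp$s_F * rp$total * d / (rp$K + d)
    }
  }
  out
}

new_traceset <- function(times, conc, channels, provenance) {
  structure(list(times = times, conc = conc, channels = channels,
                 provenance = provenance),
            class = "celia_traceset")
}

#' Deterministically integrate a reaction network
#'
#' Integrates the network ODEs with LSODA (automatic stiff/non-stiff
#' switching) and samples the dense solution on the uniform output grid
#' `{0, dt_out, ..., t_end}`. Tiny negative concentrations from the solver
#' (bounded by numerical noise near zero) are clipped to 0 on output; the
#' largest clipped magnitude is recorded in the provenance.
#'
#' @param net A [celia_network()].
#' @param t_end Horizon (min, > 0).
#' @param dt_out Output cadence (min; default 2, plate-reader-like).
#' @param opts [solver_options()].
#' @return A `celia_traceset`: `times` (min), `conc` (nM, one column per
#'   species), `channels` (signal units, one column per reporter channel)
#'   and `provenance`.
#' @export
#' @examples
#' net <- build_linear_module(5, 125, preactivated_frac = 1)
#' ts <- simulate_ode(net, t_end = 100, dt_out = 2)
#' head(ts$channels[, "omega"])
simulate_ode <- function(net, t_end, dt_out = 2, opts = solver_options()) {
  stopifnot(inherits(net, "celia_network"), t_end > 0, dt_out > 0)
  cm <- compile_network(net)
  times <- seq(0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  y0 <- stats::setNames(net$species$init, cm$species)
  rhs <- function(t, y, parms) list(as.vector(cm$S %*% cm$rate_fn(y)))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = opts$rel_tol, atol = opts$abs_tol,
                        hmax = if (is.finite(opts$max_step)) opts$max_step
                               else NULL)
  istate <- attr(sol, "istate")[1L]
  if (!is.null(istate) && istate < 0)
    stop("ODE integration failed (istate = ", istate, ") near t = ",
         max(sol[, "time"]), " min", call. = FALSE)
  conc <- sol[, cm$species, drop = FALSE]
  if (anyNA(conc) || any(!is.finite(conc)))
    stop("ODE integration produced non-finite state", call. = FALSE)
  max_clip <- max(0, -min(conc))
  conc[conc < 0] <- 0
  new_traceset(sol[, "time"], conc, eval_channels(net, conc),
               list(network_hash = fnv1a32(serialize_obj(net)),
                    solver = unclass(opts), max_clip = max_clip,
                    kind = "ode"))
}

#' Stochastic simulation (Gillespie direct method)
#'
#' Exact stochastic trajectory of the copy-number process in a well-mixed
#' volume, used as a validation oracle for the deterministic integrator.
#' Saturating rate laws are evaluated on instantaneous counts converted to
#' concentrations (mean-field hybrid), so small-copy realism is only claimed
#' for mass-action networks.
#'
#' @param net A [celia_network()].
#' @param volume Reaction volume (liters).
#' @param t_end Horizon (min).
#' @param seed Integer seed (trajectory is deterministic given the seed).
#' @param dt_out Output cadence (min).
#' @return A `celia_traceset` (concentrations are counts / (N_A V)).
#' @export
simulate_ssa <- function(net, volume, t_end, seed, dt_out = 2) {
  stopifnot(inherits(net, "celia_network"), volume > 0, t_end > 0)
  cm <- compile_network(net)
  omega <- 6.02214076e23 * volume * 1e-9   # molecules per nM
  x0 <- round(net$species$init * omega)
  if (any(x0 > 1e6))
    stop("species count exceeds 1e6; use a smaller volume or ODE mode",
         call. = FALSE)
  times <- seq(0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  nt <- length(times)
  conc <- matrix(0, nt, length(cm$species),
                 dimnames = list(NULL, cm$species))
  with_seed(as.integer(seed), {
    x <- x0
    t <- 0
    irec <- 1L
    repeat {
      a <- cm$rate_fn(x / omega) * omega   # events per min
      a[a < 0] <- 0
      a0 <- sum(a)
      tnext <- if (a0 <= 0) Inf else t + stats::rexp(1, a0)
      while (irec <= nt && times[irec] <= min(tnext, t_end)) {
        conc[irec, ] <- x / omega
        irec <- irec + 1L
      }
      if (tnext > t_end || irec > nt) break
      t <- tnext
      j <- sample.int(cm$nr, 1L, prob = a)
      x <- x + cm$S[, j]
      if (any(x > 1e6))
        stop("species count exceeds 1e6; use a smaller volume or ODE mode",
             call. = FALSE)
    }
    while (irec <= nt) {            # pad if no events remain
      conc[irec, ] <- x / omega
      irec <- irec + 1L
    }
  })
  new_traceset(times, conc, eval_channels(net, conc),
               list(network_hash = fnv1a32(serialize_obj(net)),
                    volume = volume, seed = as.integer(seed),
                    kind = "ssa"))
}

#' @export
print.celia_traceset <- function(x, ...) {
  cat("CELIA trace set:", length(x$times), "time points, 0 to",
      max(x$times), "min;", ncol(x$conc), "species,",
      ncol(x$channels), "channel(s)\n")
  invisible(x)
}

#' @export
as.data.frame.celia_traceset <- function(x, row.names = NULL,
                                         optional = FALSE,
                                         well_id = NA_character_, ...) {
  long <- function(mat, type) {
    if (is.null(mat) || ncol(mat) == 0L) return(NULL)
    do.call(rbind, lapply(colnames(mat), function(nm)
      data.frame(well_id = well_id, time_min = x$times, series_type = type,
                 name = nm, value = mat[, nm], stringsAsFactors = FALSE)))
  }
  out <- rbind(long(x$conc, "species"), long(x$channels, "channel"))
  rownames(out) <- NULL
  out
}

#' @export
plot.celia_traceset <- function(x, what = c("channels", "species"), ...) {
  what <- match.arg(what)
  mat <- if (what == "channels") x$channels else x$conc
  graphics::matplot(x$times, mat, type = "l", lty = 1,
                    xlab = "time (min)",
                    ylab = if (what == "channels") "signal (a.u.)"
                           else "concentration (nM)", ...)
  graphics::legend("topleft", legend = colnames(mat), lty = 1,
                   col = seq_len(ncol(mat)), bty = "n")
  invisible(x)
}

#' Extract a single-channel fluorescence trace
#'
#' @param ts A `celia_traceset`.
#' @param channel Reporter channel name.
#' @param well_id Optional well identifier carried along.
#' @return A `celia_trace`: list with `times`, `values`, `channel`,
#'   `well_id`.
#' @export
get_trace <- function(ts, channel, well_id = NA_character_) {
  stopifnot(inherits(ts, "celia_traceset"))
  if (!channel %in% colnames(ts$channels))
    stop("no channel '", channel, "' in trace set", call. = FALSE)
  celia_trace(ts$times, ts$channels[, channel], channel, well_id)
}

#' Construct a fluorescence trace
#'
#' @param times Time grid (min), strictly increasing.
#' @param values Signal values (finite).
#' @param channel Channel label.
#' @param well_id Optional well identifier.
#' @return A `celia_trace`.
#' @export
celia_trace <- function(times, values, channel = "signal",
                        well_id = NA_character_) {
  stopifnot(length(times) == length(values))
  if (length(times) >= 2L && any(diff(times) <= 0))
    stop("trace time axis must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("trace values must be finite", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 channel = channel, well_id = well_id),
            class = "celia_trace")
}

#' @export
print.celia_trace <- function(x, ...) {
  cat("CELIA trace [", x$channel, "]: ", length(x$times), " points, ",
      min(x$times), "-", max(x$times), " min\n", sep = "")
  invisible(x)
}

# evaluate code with a local, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
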