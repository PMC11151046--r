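#' Optical noise model for synthetic plate data
#'
#' Emulates the inter-well variation of a real-time fluorescence scanner:
#' each well gets a multiplicative optical factor (lognormal, unit mean,
#' coefficient of variation `well_scale_cv`) and an additive baseline
#' offset, and every timepoint gets i.i.d. additive measurement noise.
#' Noise is applied to reporter channels only, never to the species
#' kinetics.
#'
#' @param well_scale_cv CV of the per-well multiplicative factor (0.05).
#' @param additive_sd Per-timepoint additive noise SD (signal units, 0.01).
#' @param baseline_offset_sd Per-well baseline offset SD (signal units,
#'   0.02).
#' @param seed Default integer seed used when [apply_noise()] is called
#'   without one.
#' @return An object of class `celia_noise`.
#' @export
noise_model <- function(well_scale_cv = 0.05, additive_sd = 0.01,
                        baseline_offset_sd = 0.02, seed = 1L) {
  stopifnot(well_scale_cv >= 0, additive_sd >= 0, baseline_offset_sd >= 0)
  structure(list(well_scale_cv = well_scale_cv, additive_sd = additive_sd,
                 baseline_offset_sd = baseline_offset_sd,
                 seed = as.integer(seed)),
            class = "celia_noise")
}

# deterministic per-well, per-channel RNG stream (stable under reordering)
stream_seed <- function(seed, well_index, channel = "") {
  h <- fnv1a32(paste(seed, well_index, channel, sep = "/"))
  v <- strtoi(substr(h, 1, 4), 16L) * 65536 + strtoi(substr(h, 5, 8), 16L)
  as.integer(v %% 2147483647)
}

#' Apply the optical noise model to a trace
#'
#' `value' = scale_w * value + offset_w + eps_t`, with `scale_w` lognormal
#' (unit mean, CV `well_scale_cv`) and `offset_w` normal, drawn once per
#' (well, channel), and `eps_t` normal i.i.d. per timepoint. The RNG stream
#' is derived from `(seed, well_index, channel)`, so plates are reproducible
#' under well reordering. With all noise parameters zero the trace is
#' returned unchanged.
#'
#' @param tr A [celia_trace()].
#' @param noise A [noise_model()].
#' @param well_index Integer well index.
#' @param seed Integer seed (defaults to `noise$seed`).
#' @return A [celia_trace()] with noisy values.
#' @export
apply_noise <- function(tr, noise, well_index = 1L, seed = noise$seed) {
  stopifnot(inherits(tr, "celia_trace"), inherits(noise, "celia_noise"))
  if (noise$well_scale_cv == 0 && noise$additive_sd == 0 &&
      noise$baseline_offset_sd == 0)
    return(tr)
  n <- length(tr$values)
  with_seed(stream_seed(seed, well_index, tr$channel), {
    sdlog <- sqrt(log(1 + noise$well_scale_cv^2))
    scale_w <- if (noise$well_scale_cv > 0)
      stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
    offset_w <- if (noise$baseline_offset_sd > 0)
      stats::rnorm(1, 0, noise$baseline_offset_sd) else 0
    eps <- if (noise$additive_sd > 0)
      stats::rnorm(n, 0, noise$additive_sd) else numeric(n)
    celia_trace(tr$times, scale_w * tr$values + offset_w + eps,
                tr$channel, tr$well_id)
  })
}

#' Random spiked-concentration panel
#'
#' Draws, for every sample and every target, a concentration log-uniform on
#' `[c_min, c_max]` — the in-silico analogue of a blinded panel of samples
#' spiked at random levels. Deterministic given the seed.
#'
#' @param n Number of samples (> 0).
#' @param c_min,c_max Concentration bounds (M), `0 < c_min <= c_max`.
#'   Defaults 5 fM and 100 pM.
#' @param targets Character vector of target (microRNA) names.
#' @param seed Integer seed.
#' @return data.frame: `sample_id`, `target`, `true_molar`.
#' @export
random_panel <- function(n, c_min = 5e-15, c_max = 1e-10,
                         targets = c("let-7a", "miR-203a"), seed = 1L) {
  if (!is.numeric(n) || n <= 0) stop("n must be positive", call. = FALSE)
  stopifnot(c_min > 0, c_min <= c_max, length(targets) >= 1L)
  n <- as.integer(n)
  with_seed(as.integer(seed), {
    rows <- lapply(targets, function(tg)
      data.frame(sample_id = sprintf("S%03d", seq_len(n)), target = tg,
                 true_molar = 10^stats::runif(n, log10(c_min),
                                              log10(c_max)),
                 stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out <- out[order(out$sample_id, out$target), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Calibration dilution series
#'
#' Tenfold dilution series (default 1e-15 to 1e-9 M) with replicates and
#' no-target blanks, mirroring a standard-curve plate layout.
#'
#' @param concentrations Molar concentrations (default `10^(-15:-9)`).
#' @param replicates Replicates per level (default 3).
#' @param include_blank Include `replicates` blank (0 M) wells.
#' @param target Target name label.
#' @return data.frame: `sample_id`, `target`, `true_molar`.
#' @export
calibration_series <- function(concentrations = 10^seq(-15, -9),
                               replicates = 3L, include_blank = TRUE,
                               target = "let-7a") {
  stopifnot(replicates >= 1L)
  conc <- sort(concentrations)
  if (include_blank) conc <- c(0, conc)
  rows <- do.call(rbind, lapply(seq_along(conc), function(i)
    data.frame(sample_id = sprintf("C%02d_r%d", i, seq_len(replicates)),
               target = target, true_molar = conc[i],
               stringsAsFactors = FALSE)))
  rownames(rows) <- NULL
  rows
}

#' Generate a synthetic plate experiment
#'
#' Simulates, for every sample row, the default endpoint-assay circuit (the
#' microRNA converter feeding the exponential switch and the linear
#' amplifier) at that sample's target concentration, then applies the
#' optical noise model to the reporter channels. Wells sharing a
#' concentration reuse one deterministic simulation (noise still differs
#' per well).
#'
#' @param samples data.frame with columns `sample_id`, `target`,
#'   `true_molar` (see [random_panel()], [calibration_series()]).
#' @param t_end,dt_out Simulation horizon and output cadence (min).
#' @param noise A [noise_model()] (use zero SDs for noise-free plates).
#' @param seed Integer seed for the noise streams.
#' @param templates,params,alpha0 Circuit configuration forwarded to
#'   [celia_circuit()].
#' @return An object of class `celia_plate`: `wells` (metadata incl. true
#'   concentrations), `traces` (named list of `celia_traceset` with noisy
#'   channels), `seed`.
#' @export
generate_plate <- function(samples, t_end = 1000, dt_out = 2,
                           noise = noise_model(), seed = 1L,
                           templates = list(), params = celia_params(),
                           alpha0 = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "target", "true_molar") %in% names(samples)))
  nw <- nrow(samples)
  well_id <- sprintf("W%03d", seq_len(nw))
  cache <- new.env(parent = emptyenv())
  traces <- vector("list", nw)
  names(traces) <- well_id
  for (i in seq_len(nw)) {
    key <- sprintf("%.17g", samples$true_molar[i])
    ts <- if (!is.null(cache[[key]])) cache[[key]] else {
      net <- celia_circuit("assay", target_molar = samples$true_molar[i],
                           alpha0 = alpha0, templates = templates,
                           params = params)
      cache[[key]] <- simulate_ode(net, t_end, dt_out)
      cache[[key]]
    }
    noisy <- ts
    for (ch in colnames(ts$channels)) {
      tr <- apply_noise(celia_trace(ts$times, ts$channels[, ch], ch,
                                    well_id[i]),
                        noise, well_index = i, seed = seed)
      noisy$channels[, ch] <- tr$values
    }
    noisy$provenance$seed <- as.integer(seed)
    noisy$provenance$well_index <- i
    traces[[i]] <- noisy
  }
  wells <- cbind(data.frame(well_id = well_id, stringsAsFactors = FALSE),
                 samples)
  rownames(wells) <- NULL
  structure(list(wells = wells, traces = traces, seed = as.integer(seed)),
            class = "celia_plate")
}

#' @export
print.celia_plate <- function(x, ...) {
  cat("CELIA synthetic plate:", nrow(x$wells), "wells, seed", x$seed, "\n")
  print(utils::head(x$wells))
  invisible(x)
}
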