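# -- hashing ----------------------------------------------------------------

# canonical string form of an R object (no environments in our objects)
serialize_obj <- function(x) paste(deparse(x, control = "all"),
                                   collapse = "\n")

# FNV-1a 32-bit hash of a string; returns an 8-hex-digit character scalar.
# Written out in base R (split multiply keeps everything inside double
# precision).
fnv1a32 <- function(x) {
  if (!is.character(x) || length(x) != 1L) x <- serialize_obj(x)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", (h - lo) / 65536, lo)
}

# -- trace CSV (shared long format) -----------------------------------------

#' Write traces to the long-format CSV
#'
#' Columns: `well_id`, `time_min`, `series_type` (`species` or `channel`),
#' `name`, `value`. Values are written with 17 significant digits so the
#' round trip through [read_traces()] is lossless at full double precision.
#'
#' @param x A `celia_traceset`, a `celia_plate`, or an already-long
#'   data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(x, path) {
  df <- traces_to_long(x)
  df$value <- sprintf("%.17g", df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

traces_to_long <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "celia_traceset")) return(as.data.frame(x))
  if (inherits(x, "celia_plate")) {
    out <- do.call(rbind, lapply(names(x$traces), function(w)
      as.data.frame(x$traces[[w]], well_id = w)))
    rownames(out) <- NULL
    return(out)
  }
  stop("cannot serialize object of class ", class(x)[1L], call. = FALSE)
}

#' Read the long-format trace CSV
#'
#' @param path CSV path written by [write_traces()].
#' @return data.frame with columns `well_id`, `time_min`, `series_type`,
#'   `name`, `value` (numeric).
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "series_type", "name", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trace CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))))
  if (length(bad))
    stop("malformed trace rows (non-numeric value) at line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "), call. = FALSE)
  df$value <- as.numeric(df$value)
  if (is.null(df$well_id)) df$well_id <- NA_character_
  df
}

# rebuild per-well channel trace sets from the long format
long_to_tracesets <- function(df) {
  df <- df[df$series_type == "channel", , drop = FALSE]
  if (!nrow(df)) return(list())
  wells <- unique(df$well_id)
  out <- lapply(wells, function(w) {
    d <- df[df$well_id == w, , drop = FALSE]
    times <- sort(unique(d$time_min))
    chn <- unique(d$name)
    ch <- matrix(NA_real_, length(times), length(chn),
                 dimnames = list(NULL, chn))
    for (nm in chn) {
      dd <- d[d$name == nm, , drop = FALSE]
      ch[match(dd$time_min, times), nm] <- dd$value
    }
    new_traceset(times, matrix(numeric(0), length(times), 0), ch,
                 list(kind = "csv", well_id = w))
  })
  names(out) <- wells
  out
}

# -- YAML run configuration --------------------------------------------------

config_defaults <- function() {
  list(
    circuit = list(type = "assay", target_molar = 0, alpha0 = NULL,
                   templates = list()),
    params = list(),
    simulate = list(t_end_min = 1000, dt_out_min = 2),
    noise = list(well_scale_cv = 0.05, additive_sd = 0.01,
                 baseline_offset_sd = 0.02, seed = 1),
    analysis = list(threshold_fraction = 0.2, threshold_absolute = NULL,
                    endpoint_min = NULL))
}

#' Read and validate a run configuration
#'
#' YAML with blocks `circuit` (type, target_molar, alpha0, templates),
#' `params` (kinetic overrides), `simulate` (`t_end_min`, `dt_out_min`),
#' `noise` and `analysis`. Unknown keys are rejected; defaults are
#' materialized into the returned object and into its config hash.
#'
#' @param path YAML file path (or a list already parsed).
#' @return A `celia_config`: the materialized configuration plus
#'   `config_hash`.
#' @export
read_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  def <- config_defaults()
  bad <- setdiff(names(raw), names(def))
  if (length(bad))
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (blk in names(raw)) {
    if (!is.list(raw[[blk]]))
      stop("configuration block '", blk, "' must be a mapping",
           call. = FALSE)
    badk <- setdiff(names(raw[[blk]]), names(def[[blk]]))
    if (length(badk))
      stop("unknown key(s) in '", blk, "': ", paste(badk, collapse = ", "),
           call. = FALSE)
    def[[blk]] <- utils::modifyList(def[[blk]], raw[[blk]])
  }
  # validate nested domains early, with errors naming the key
  badt <- setdiff(names(def$circuit$templates),
                  names(default_templates()))
  if (length(badt))
    stop("unknown template key(s): ", paste(badt, collapse = ", "),
         call. = FALSE)
  update_params(overrides = def$params)
  if (!def$circuit$type %in% c("coupled", "inverter", "assay"))
    stop("circuit type must be coupled, inverter or assay", call. = FALSE)
  def$config_hash <- fnv1a32(serialize_obj(def))
  class(def) <- "celia_config"
  def
}

#' Simulate a configured circuit and write trace CSV + provenance
#'
#' @param config Path to a YAML configuration or a `celia_config`.
#' @param out_dir Output directory (created if needed); writes `traces.csv`
#'   and `provenance.json`.
#' @param seed Seed for the noise streams (overrides the config's).
#' @param noisy Apply the configured noise model (default `FALSE`:
#'   deterministic kinetics only).
#' @return Invisibly, a list with the output paths and the trace set.
#' @export
run_simulate <- function(config, out_dir, seed = NULL, noisy = FALSE) {
  cfg <- if (inherits(config, "celia_config")) config else read_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params <- update_params(overrides = cfg$params)
  net <- celia_circuit(cfg$circuit$type,
                       target_molar = cfg$circuit$target_molar,
                       alpha0 = cfg$circuit$alpha0,
                       templates = cfg$circuit$templates, params = params)
  ts <- simulate_ode(net, cfg$simulate$t_end_min, cfg$simulate$dt_out_min)
  if (is.null(seed)) seed <- cfg$noise$seed
  if (noisy) {
    nm <- noise_model(cfg$noise$well_scale_cv, cfg$noise$additive_sd,
                      cfg$noise$baseline_offset_sd, seed)
    for (ch in colnames(ts$channels))
      ts$channels[, ch] <- apply_noise(
        celia_trace(ts$times, ts$channels[, ch], ch), nm, 1L, seed)$values
  }
  trace_path <- file.path(out_dir, "traces.csv")
  write_traces(as.data.frame(ts, well_id = "W001"), trace_path)
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    list(config_hash = cfg$config_hash, seed = seed, noisy = noisy,
         network_hash = ts$provenance$network_hash,
         n_times = length(ts$times)),
    prov_path, auto_unbox = TRUE, digits = NA)
  message("simulated '", cfg$circuit$type, "' circuit: ",
          length(ts$times), " timepoints, config ", cfg$config_hash,
          ", seed ", seed)
  invisible(list(traces = trace_path, provenance = prov_path,
                 traceset = ts))
}

#' Extract per-well observables from a trace CSV
#'
#' @param traces_csv Long-format trace CSV (see [write_traces()]).
#' @param out_csv Output path for the observables table.
#' @param threshold At threshold (see [amplification_time()]).
#' @param t_end Endpoint time (min; default: end of each trace).
#' @return The observables data.frame, invisibly.
#' @export
run_analyze <- function(traces_csv, out_csv,
                        threshold = list(fraction_of_max = 0.2),
                        t_end = NULL) {
  df <- read_traces(traces_csv)
  sets <- long_to_tracesets(df)
  obs <- if (length(sets)) analyze_wells(sets, t_end, threshold) else
    data.frame(well_id = character(), channel = character(),
               at_min = numeric(), gain = numeric(), saturation = numeric(),
               window_min = numeric(), endpoint = numeric(),
               stringsAsFactors = FALSE)
  utils::write.csv(obs, out_csv, row.names = FALSE)
  invisible(obs)
}

#' Calibrate from standards and quantify unknowns
#'
#' @param calibration_csv CSV with columns `x_log10_M` (non-finite or empty
#'   for blanks), `endpoint`, optional `replicate_id`.
#' @param unknowns_csv CSV with columns `well_id`, `endpoint`.
#' @param out_dir Output directory; writes `calibration.json` (sigmoid
#'   parameters + LoD) and `estimates.csv` (`well_id`, `estimate_molar`,
#'   `flag`).
#' @return Invisibly, list with the model and the estimates data.frame.
#' @export
run_calibrate_quantify <- function(calibration_csv, unknowns_csv, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cal <- utils::read.csv(calibration_csv, stringsAsFactors = FALSE)
  if (!all(c("x_log10_M", "endpoint") %in% names(cal)))
    stop("calibration CSV needs columns x_log10_M, endpoint", call. = FALSE)
  x <- suppressWarnings(as.numeric(cal$x_log10_M))
  std <- is.finite(x)
  m <- fit_sigmoid(x[std], cal$endpoint[std])
  blanks <- cal$endpoint[!std]
  if (length(blanks) >= 2L) {
    ld <- lod(m, blanks)
    m$lod_molar <- ld$lod_molar
  }
  jsonlite::write_json(
    list(L = m$L, H = m$H, b = m$b, k = m$k, x0 = m$x0,
         residual_sd = m$residual_sd, lod_molar = m$lod_molar),
    file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
  unk <- utils::read.csv(unknowns_csv, stringsAsFactors = FALSE)
  if (!all(c("well_id", "endpoint") %in% names(unk)))
    stop("unknowns CSV needs columns well_id, endpoint", call. = FALSE)
  est <- quantify_endpoints(m, unk$endpoint, well_id = unk$well_id)
  utils::write.csv(est[, c("well_id", "estimate_molar", "flag")],
                   file.path(out_dir, "estimates.csv"), row.names = FALSE)
  invisible(list(model = m, estimates = est))
}
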