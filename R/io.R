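#' Default run configuration
#'
#' Desk-scale defaults: a 16-channel, 16-neuron hidden layer, 50-step
#' simulations and short search schedules sized so a full search runs in
#' seconds to minutes on one CPU. Named presets carry the standard
#' parameter-table constants for the four benchmark settings
#' (`"table1-ti46"`, `"table1-ntidigits"`, `"table1-dvsgesture"`,
#' `"table1-nmnist"`): membrane/synaptic/calcium time constants, learning
#' rate, batch size, simulation length, layer size and motif-size options.
#'
#' @return Nested configuration list with blocks `network`, `training`,
#'   `ip`, `schedule` and a top-level `seed`.
#' @export
default_config <- function() {
  list(
    network = list(n_in = 16L, n_hidden = 16L, n_out = 2L, V = c(2L, 4L, 8L),
                   v_th = 0.3, v_th_out = 0.3, tau_m = 16, tau_syn = 8,
                   tying = "shared_topology", w_exc_init = 0.2, w_inh = -2,
                   inter = TRUE),
    training = list(lr = 0.005, lr_alpha = 0.1, eta = "lr", epsilon = "auto",
                    batch_size = 20L, T_steps = 50L, mode = "hard",
                    surrogate = "bump", width = 0.5),
    ip = list(enabled = TRUE, mu = 0.05, tau_cal = 16, gamma = 0.01,
              tau_avg = 64, r_gain = 0.1, retrain = FALSE),
    schedule = list(warmup_iters = 10L, stage1_iters = 60L, stage2_iters = 30L,
                    finetune_epochs = 20L, ip_window = 1L, eval_every = 10L,
                    random_archs = 6L, random_train_epochs = 5L),
    seed = 1L
  )
}

config_presets <- function() {
  list(
    "table1-ti46" = list(
      network = list(n_hidden = 800L, V = c(5L, 10L, 16L, 25L, 40L),
                     tau_m = 16, tau_syn = 8),
      training = list(lr = 5e-4, batch_size = 50L, T_steps = 100L),
      ip = list(tau_cal = 16)),
    "table1-ntidigits" = list(
      network = list(n_hidden = 800L, V = c(2L, 4L, 8L, 16L, 32L),
                     tau_m = 64, tau_syn = 8),
      training = list(lr = 5e-4, batch_size = 50L, T_steps = 300L),
      ip = list(tau_cal = 16)),
    "table1-dvsgesture" = list(
      network = list(n_hidden = 512L, V = c(2L, 4L, 8L, 16L, 32L),
                     tau_m = 64, tau_syn = 8),
      training = list(lr = 1e-4, batch_size = 20L, T_steps = 400L),
      ip = list(tau_cal = 16)),
    "table1-nmnist" = list(
      network = list(n_hidden = 512L, V = c(2L, 4L, 8L, 16L, 32L),
                     tau_m = 16, tau_syn = 8),
      training = list(lr = 5e-4, batch_size = 50L, T_steps = 100L),
      ip = list(tau_cal = 16))
  )
}

merge_config <- function(base, upd, path = "") {
  for (nm in names(upd)) {
    if (!nm %in% names(base))
      stop(sprintf("unknown configuration key: %s%s", path, nm))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(upd[[nm]]))
        stop(sprintf("configuration key %s%s must be a block", path, nm))
      base[[nm]] <- merge_config(base[[nm]], upd[[nm]],
                                 paste0(path, nm, "$"))
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

#' Validate a configuration
#'
#' Checks types, ranges and cross-field invariants (every motif-size option
#' must divide the hidden-layer size; time constants must exceed one step).
#' Returns the configuration unchanged on success.
#'
#' @param cfg configuration list.
#' @return The validated configuration.
#' @export
validate_config <- function(cfg) {
  nw <- cfg$network
  bad <- nw$V[nw$n_hidden %% nw$V != 0]
  if (length(bad))
    stop(sprintf("motif size option(s) %s do not divide layer size %d",
                 paste(bad, collapse = ", "), nw$n_hidden))
  if (nw$tau_m <= 1 || nw$tau_syn <= 1)
    stop("time constants must exceed 1 step")
  if (nw$v_th <= 0) stop("v_th must be positive")
  if (nw$w_inh >= 0) stop("w_inh must be negative")
  if (cfg$training$lr <= 0 || cfg$training$lr_alpha <= 0)
    stop("learning rates must be positive")
  if (is.numeric(cfg$training$epsilon) && cfg$training$epsilon <= 0)
    stop("epsilon must be positive")
  if (any(unlist(cfg$schedule[c("stage1_iters", "stage2_iters",
                                "finetune_epochs")]) < 0))
    stop("schedule iteration counts must be nonnegative")
  cfg
}

#' Load a run configuration
#'
#' Builds the configuration by layering, in order: package defaults, an
#' optional named preset, an optional YAML/JSON file and programmatic
#' overrides. Unknown keys are rejected with the offending key path; the
#' result is validated before returning. An empty file yields the defaults
#' and round-trips losslessly through [save_config()].
#'
#' @param path optional path to a YAML (`.yaml`/`.yml`) or JSON file.
#' @param preset optional preset name, see [default_config()].
#' @param overrides optional nested list applied last.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL, preset = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(preset)) {
    pp <- config_presets()
    if (!preset %in% names(pp)) stop("unknown preset: ", preset)
    cfg <- merge_config(cfg, pp[[preset]])
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
           else yaml::read_yaml(path)
    if (length(raw)) cfg <- merge_config(cfg, raw)
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg configuration to write.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write / read a spike dataset as an event-list TSV
#'
#' Plain-text container: a commented header (sample count, channel count,
#' timestep count, the label vector and JSON-encoded generator metadata)
#' followed by one `sample / channel / timestep` row per spike (1-based) and
#' a terminating `# end` line, whose absence marks a truncated file.
#' Round-trips are lossless for `X`, `y` and metadata.
#'
#' @param ds a [spike_dataset()].
#' @param path output file path.
#' @return `write_dataset()`: the path, invisibly; `read_dataset()`: a
#'   `spike_dataset`.
#' @export
write_dataset <- function(ds, path) {
  d <- dim(ds$X)
  idx <- which(ds$X == 1, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# hrmas-dataset v1",
    paste("# samples", d[1L]),
    paste("# channels", d[2L]),
    paste("# timesteps", d[3L]),
    paste("# labels", paste(ds$y, collapse = ",")),
    paste("# meta", jsonlite::toJSON(ds$meta, auto_unbox = TRUE, digits = NA)),
    "sample\tchannel\ttimestep"), con)
  if (nrow(idx))
    utils::write.table(idx[order(idx[, 1L], idx[, 2L], idx[, 3L]), ,
                           drop = FALSE],
                       con, sep = "\t", row.names = FALSE, col.names = FALSE)
  writeLines("# end", con)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 7L || lines[1L] != "# hrmas-dataset v1")
    stop("not an hrmas event-list dataset: ", path)
  if (lines[length(lines)] != "# end")
    stop("truncated dataset file (missing '# end' terminator): ", path)
  hdr <- function(key) {
    ln <- grep(paste0("^# ", key, " "), lines[1:6], value = TRUE)
    if (!length(ln)) stop("missing header field: ", key)
    sub(paste0("^# ", key, " "), "", ln[1L])
  }
  S <- as.integer(hdr("samples")); C <- as.integer(hdr("channels"))
  Tt <- as.integer(hdr("timesteps"))
  y <- as.integer(strsplit(hdr("labels"), ",")[[1L]])
  if (length(y) != S) stop("label count disagrees with sample count")
  meta <- jsonlite::fromJSON(hdr("meta"), simplifyVector = TRUE)
  body <- if (length(lines) >= 9L) lines[8:(length(lines) - 1L)] else character(0)
  X <- array(0, c(S, C, Tt))
  if (length(body)) {
    ev <- utils::read.table(text = body, sep = "\t", col.names =
                              c("sample", "channel", "timestep"))
    bad <- which(ev$sample < 1 | ev$sample > S | ev$channel < 1 |
                   ev$channel > C | ev$timestep < 1 | ev$timestep > Tt)
    if (length(bad))
      stop(sprintf("malformed event record at data row %d: (%s)", bad[1L],
                   paste(ev[bad[1L], ], collapse = ", ")))
    X[cbind(ev$sample, ev$channel, ev$timestep)] <- 1
  }
  spike_dataset(X, y, meta = as.list(meta))
}

#' Write a reproducibility manifest
#'
#' Records the configuration (and its MD5 hash), the seed, package and R
#' versions and an ISO-8601 timestamp — enough to reproduce the run.
#'
#' @param path output JSON path.
#' @param cfg configuration list.
#' @param seed master seed of the run.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, cfg, seed) {
  tmp <- tempfile()
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config = cfg,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    package = "hrmas",
    package_version = as.character(utils::packageVersion("hrmas")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
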