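#' Known flat configuration keys
#'
#' The keys accepted in a configuration file or an `overrides` list, covering
#' every tunable of the frontend, FFI, channel and LGMD stages plus the run
#' controls `preset` and `gating_enabled`.
#'
#' @return character vector of key names.
#' @export
config_keys <- function() {
  c("preset", "gating_enabled",
    "persistence_coeff", "frame_interval", "tau_in",
    "tau3", "tau4", "omega_ffi", "omega1", "omega2", "th_ffi",
    "tau_on", "tau_off", "inhib_kernel_size", "group_kernel_size",
    "decay_threshold", "decay_coeff", "bias_on", "bias_off",
    "alpha6", "alpha7", "t_spi", "spike_mp_level", "n_sp", "n_ts",
    "sfa_tau", "sfa_mode", "sfa_rise_tol", "update_gated_state")
}

#' Load a run configuration
#'
#' Reads a flat `key = value` text file (`#` comments allowed) and resolves
#' it into a validated parameter bundle. Unknown keys are rejected with the
#' offending key named; numeric ranges are validated by the stage
#' constructors (so, e.g., `n_sp` larger than the decision window is rejected
#' here, at configuration time). An empty or missing file yields the preset's
#' defaults.
#'
#' @param path configuration file, or `NULL` for pure defaults.
#' @param preset preset name; a `preset` key in the file takes precedence.
#' @param overrides named list applied after the file.
#' @return an [olgmd_params()] bundle.
#' @export
load_config <- function(path = NULL, preset = "oLGMD1", overrides = NULL) {
  kv <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    kv <- parse_kv_file(path)
  }
  if (!is.null(overrides)) kv[names(overrides)] <- overrides
  bad <- setdiff(names(kv), config_keys())
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(kv$preset)) {
    preset <- kv$preset
    kv$preset <- NULL
  }
  fi <- if (!is.null(kv$frame_interval)) kv$frame_interval else 30
  olgmd_params(preset, overrides = kv, frame_interval = fi)
}

#' Run the model over an input directory or stimulus, writing a CSV trace
#'
#' The orchestration entry point behind the command-line tool: resolves the
#' input (a frame directory or a named battery stimulus), streams it through
#' the model, writes the trace, and reports whether any collision alarm
#' occurred. Every gate transition is logged with its frame index when
#' `verbose` is set.
#'
#' @param input a directory of frames, a `frame_sequence`, or one of the
#'   battery names (`"dark-looming"`, `"light-looming"`, `"dark-receding"`,
#'   `"light-receding"`, `"dark-translating"`, `"light-translating"`,
#'   `"grating-fine"`, `"grating-coarse"`).
#' @param params an [olgmd_params()] bundle (see [load_config()]).
#' @param output_csv optional path for the trace CSV.
#' @param verbose log gate transitions and the collision outcome.
#' @return list with `trace`, `collision` (any alarm raised), and
#'   `alarm_frame` (first alarm, or `NA`).
#' @export
run_olgmd <- function(input, params = olgmd_params(), output_csv = NULL,
                      verbose = FALSE) {
  frames <- resolve_input(input)
  trace <- run_model(frames, params)
  if (verbose) {
    for (col in c("beta_on", "beta_off")) {
      tr <- which(diff(trace[[col]]) != 0) + 1
      for (i in tr)
        message(sprintf("frame %d: %s -> %d", trace$frame[i], col,
                        trace[[col]][i]))
    }
  }
  alarms <- which(trace$collision)
  if (!is.null(output_csv)) write_trace(trace, output_csv)
  if (verbose)
    message(if (length(alarms)) sprintf("collision detected at frame %d",
                                        alarms[1])
            else "no collision")
  list(trace = trace, collision = length(alarms) > 0,
       alarm_frame = if (length(alarms)) alarms[1] else NA_integer_)
}

resolve_input <- function(input) {
  if (inherits(input, "frame_sequence")) return(input)
  if (is.character(input) && length(input) == 1) {
    if (dir.exists(input)) return(read_frames(input))
    battery <- default_battery()
    names(battery) <- vapply(battery, `[[`, "", "name")
    if (input %in% names(battery)) return(battery[[input]]$frames)
    stop("input is neither a directory nor a battery stimulus name: ", input)
  }
  stop("cannot resolve model input")
}
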