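#' Available selectivity presets
#' @return character vector of preset names.
#' @export
preset_names <- function() {
  c("oLGMD1", "oLGMD2", "reverse-oLGMD2", "baseline-LGMD1", "baseline-LGMD2")
}

# Per-preset asymmetries. Selectivity is obtained purely by re-balancing the
# polarity delay constants (tau), the baseline inhibition weights (omega) and
# the channel gains: oLGMD2 opposes its ON channel with fast, heavily
# weighted inhibition so brightening (light approach / dark recession) is
# cancelled; reverse-oLGMD2 mirrors the asymmetry onto OFF.
preset_table <- function(name) {
  sym <- list(tau_on = 60, tau_off = 60, omega1 = 0.5, omega2 = 0.5,
              bias_on = 1, bias_off = 1)
  on_suppressed <- list(tau_on = 15, tau_off = 90, omega1 = 4, omega2 = 0.5,
                        bias_on = 0.5, bias_off = 1)
  off_suppressed <- list(tau_on = 90, tau_off = 15, omega1 = 0.5, omega2 = 4,
                         bias_on = 1, bias_off = 0.5)
  switch(name,
         "oLGMD1" = c(sym, gating = TRUE),
         "oLGMD2" = c(on_suppressed, gating = TRUE),
         "reverse-oLGMD2" = c(off_suppressed, gating = TRUE),
         "baseline-LGMD1" = c(sym, gating = FALSE),
         "baseline-LGMD2" = c(on_suppressed, gating = FALSE),
         stop("unknown preset: ", name))
}

#' Full model parameter bundle for a preset
#'
#' Assembles frontend, FFI, channel and LGMD parameters for one of the
#' shipped presets, optionally overriding individual values. Baseline presets
#' are the ungated twins of their optimized counterparts: identical
#' parameters with the activation gate disabled, so both channels run on
#' every frame.
#'
#' @param preset one of [preset_names()].
#' @param overrides named list of scalar overrides; names are the flat
#'   configuration keys (see [config_keys()]). Unknown keys are rejected.
#' @param frame_interval frame interval in ms (also the default `tau_in`).
#' @return an `olgmd_params` bundle with elements `name`, `gating_enabled`,
#'   `frontend`, `ffi`, `channels`, `lgmd`, `frame_interval`.
#' @export
olgmd_params <- function(preset = "oLGMD1", overrides = NULL,
                         frame_interval = 30) {
  preset <- match.arg(preset, preset_names())
  p <- preset_table(preset)
  vals <- list(
    persistence_coeff = 0,
    frame_interval = frame_interval,
    tau_in = frame_interval,
    tau3 = 90, tau4 = 90,
    omega_ffi = 20, omega1 = p$omega1, omega2 = p$omega2,
    th_ffi = 1,
    tau_on = p$tau_on, tau_off = p$tau_off,
    inhib_kernel_size = 5, group_kernel_size = 3,
    decay_threshold = 15, decay_coeff = 0,
    bias_on = p$bias_on, bias_off = p$bias_off,
    alpha6 = 1.5, alpha7 = 10, t_spi = 5,
    spike_mp_level = 0.8, n_sp = 5, n_ts = 9,
    sfa_tau = 270, sfa_mode = "highpass", sfa_rise_tol = 0.02,
    update_gated_state = 1
  )
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), c(names(vals), "gating_enabled"))
    if (length(bad))
      stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
    vals[names(overrides)] <- overrides
  }
  gating <- p$gating
  if (!is.null(overrides$gating_enabled))
    gating <- as.logical(overrides$gating_enabled)

  structure(list(
    name = preset,
    gating_enabled = gating,
    frame_interval = vals$frame_interval,
    frontend = list(persistence_coeff = vals$persistence_coeff),
    ffi = ffi_params(tau3 = vals$tau3, tau4 = vals$tau4,
                     tau_in = vals$tau_in, omega_ffi = vals$omega_ffi,
                     omega1 = vals$omega1, omega2 = vals$omega2,
                     th_ffi = vals$th_ffi),
    channels = channel_params(
      w_inhib = inhibition_kernel(vals$inhib_kernel_size),
      tau_on = vals$tau_on, tau_off = vals$tau_off,
      w_group = grouping_kernel(vals$group_kernel_size),
      decay_threshold = vals$decay_threshold,
      decay_coeff = vals$decay_coeff,
      bias_on = vals$bias_on, bias_off = vals$bias_off),
    lgmd = lgmd_params(alpha6 = vals$alpha6, alpha7 = vals$alpha7,
                       t_spi = vals$t_spi,
                       spike_mp_level = vals$spike_mp_level,
                       n_sp = vals$n_sp, n_ts = vals$n_ts,
                       sfa_tau = vals$sfa_tau, sfa_mode = vals$sfa_mode,
                       sfa_rise_tol = vals$sfa_rise_tol),
    update_gated_state = as.logical(vals$update_gated_state)
  ), class = "olgmd_params")
}

#' Initialize the full model state for a sequence
#'
#' @param params an [olgmd_params()] bundle.
#' @param dims frame dimensions `c(rows, cols)`.
#' @return a `model_state`.
#' @export
model_state <- function(params, dims) {
  structure(list(
    frontend = frontend_state(params$frontend$persistence_coeff),
    ffi = ffi_state(),
    channels = channel_state(dims),
    prev_k = 0.5, prev_adapted = 0.5,
    spikes = integer(0),
    frame_idx = 0L
  ), class = "model_state")
}

# Deterministic pixel-operation counts for the cost surrogate.
cost_constants <- function(params, dims) {
  npx <- prod(dims)
  k2 <- length(params$channels$w_inhib)
  g2 <- length(params$channels$w_group)
  list(base = 5 * npx,                      # differencing, means, delay maps
       channel = npx * (k2 + 2),            # convolution + interaction
       group = npx * (g2 + 2))
}

#' Reference per-frame cost of a fully active frame
#'
#' The deterministic operation count of one frame with both polarity channels
#' open and grouping executed -- the cost the model pays at the peak of a
#' collision response, used as the `t_max` reference in suite-level
#' efficiency scoring.
#'
#' @param params an [olgmd_params()] bundle.
#' @param dims frame dimensions `c(rows, cols)`.
#' @return scalar operation count.
#' @export
frame_cost_reference <- function(params, dims) {
  k <- cost_constants(params, dims)
  k$base + 2 * k$channel + k$group
}

#' Advance the model by one frame
#'
#' Composes photoreceptor differencing, polarity splitting, per-channel FFI
#' (weights and gates), the gated channel stage, and LGMD integration with
#' spike-frequency adaptation and the windowed collision decision. With
#' gating disabled both channels run unconditionally through the identical
#' code path, so a gated run whose gates happen to stay open is bit-identical
#' to the ungated baseline.
#'
#' @param frame numeric luminance matrix (or a `frame` from
#'   [to_grayscale()]).
#' @param params an [olgmd_params()] bundle.
#' @param state a [model_state()].
#' @return list with `output` (one row of trace values) and updated `state`.
#' @export
step_model <- function(frame, params, state) {
  if (inherits(frame, "frame")) frame <- frame$values
  t0 <- proc.time()[["elapsed"]]
  dims <- dim(frame)
  cc <- cost_constants(params, dims)

  ph <- photoreceptor(frame, state$frontend)
  state$frontend <- ph$state
  maps <- split_polarity(ph$P)

  ff <- step_ffi(maps, params$ffi, state$ffi)
  state$ffi <- ff$state
  out <- ff$output
  if (!params$gating_enabled) {
    out$beta_on <- 1L
    out$beta_off <- 1L
  }

  ch <- step_channels(maps, out, params$channels, state$channels,
                      tau_in = params$ffi$tau_in,
                      update_gated_state = params$update_gated_state)
  state$channels <- ch$state

  ffe <- integrate_excitation(ch$g_hat)
  k <- membrane_potential(ffe, dims[1], dims[2], params$lgmd$alpha6)
  adapted <- adapt_sfa(k, state$prev_k, state$prev_adapted,
                       params$lgmd$sfa_tau, params$frame_interval,
                       params$lgmd$sfa_mode, params$lgmd$sfa_rise_tol)
  state$prev_k <- k
  state$prev_adapted <- adapted
  rate <- spike_rate(adapted, params$lgmd$alpha7, params$lgmd$t_spi)
  spike <- spike_indicator(adapted, params$lgmd$spike_mp_level)
  state$spikes <- utils::tail(c(state$spikes, spike), params$lgmd$n_ts + 1)
  collision <- collision_decision(state$spikes, params$lgmd$n_sp,
                                  params$lgmd$n_ts)
  state$frame_idx <- state$frame_idx + 1L

  output <- data.frame(
    frame = state$frame_idx,
    ffi_on = out$ffi_on, ffi_off = out$ffi_off,
    ffi_hat_on = out$ffi_hat_on, ffi_hat_off = out$ffi_hat_off,
    beta_on = out$beta_on, beta_off = out$beta_off,
    omega_on = out$omega_on, omega_off = out$omega_off,
    ffe = ffe, k = k, k_adapted = adapted,
    s_spike = rate, spike = spike, collision = collision,
    cost_ops = cc$base + ch$cost,
    cost_ms = (proc.time()[["elapsed"]] - t0) * 1000
  )
  list(output = output, state = state)
}

#' Run the model over a frame sequence
#'
#' @param frames a `frame_sequence` (from [render_stimulus()] or
#'   [read_frames()]) or a plain list of luminance matrices.
#' @param params an [olgmd_params()] bundle.
#' @return a data.frame trace with one row per frame (columns `frame`,
#'   `ffi_*`, `beta_*`, `omega_*`, `ffe`, `k`, `k_adapted`, `s_spike`,
#'   `spike`, `collision`, `cost_ops`, `cost_ms`). Model columns are
#'   deterministic given frames and parameters; `cost_ms` is wall-clock and
#'   informational only.
#' @export
run_model <- function(frames, params = olgmd_params()) {
  if (inherits(frames, "frame_sequence")) {
    if (!is.null(frames$interval) &&
        frames$interval != params$frame_interval) {
      params$frame_interval <- frames$interval
    }
    frames <- frames$frames
  }
  stopifnot(length(frames) >= 1)
  st <- model_state(params, dim(frames[[1]]))
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    res <- step_model(frames[[i]], params, st)
    st <- res$state
    rows[[i]] <- res$output
  }
  do.call(rbind, rows)
}

#' Write a model trace to CSV
#'
#' @param trace data.frame from [run_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
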