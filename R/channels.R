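#' Lateral-inhibition convolution kernel
#'
#' Hollow kernel (center weight 0) whose surround falls off with the inverse
#' square of pixel distance, normalized to sum to 1. The kernel's spatial
#' reach sets which image speeds lateral inhibition can cancel: a moving edge
#' whose per-frame displacement stays inside the reach lands on territory
#' still inhibited by its own recent history, while a fast-expanding looming
#' edge escapes into fresh, uninhibited territory.
#'
#' @param size odd kernel side length in pixels (default 5, reach 2).
#' @return a `size` x `size` numeric matrix, center 0, summing to 1.
#' @export
inhibition_kernel <- function(size = 5) {
  if (size %% 2 != 1 || size < 3) stop("kernel size must be odd and >= 3")
  half <- (size - 1) / 2
  d2 <- outer((-half:half)^2, (-half:half)^2, `+`)
  w <- ifelse(d2 == 0, 0, 1 / d2)
  w / sum(w)
}

#' Grouping kernel (uniform local mean)
#'
#' @param size odd kernel side length (default 3).
#' @return a `size` x `size` matrix of `1 / size^2`, summing to 1.
#' @export
grouping_kernel <- function(size = 3) {
  if (size %% 2 != 1 || size < 3) stop("kernel size must be odd and >= 3")
  matrix(1 / size^2, size, size)
}

#' Channel-stage parameters
#'
#' @param w_inhib lateral-inhibition kernel (odd-sized, center 0,
#'   non-negative surround); see [inhibition_kernel()].
#' @param tau_on,tau_off delay constants (ms) of the low-pass filters feeding
#'   each channel's inhibition; larger values make inhibition lag further
#'   behind the excitation it opposes.
#' @param w_group grouping kernel, non-negative and summing to 1.
#' @param decay_threshold excitation level below which grouped excitation is
#'   treated as isolated noise.
#' @param decay_coeff factor applied to sub-threshold grouped excitation
#'   (default 0: suppressed outright).
#' @param bias_on,bias_off gain on each channel's excitatory map.
#' @return a `channel_params` object.
#' @export
channel_params <- function(w_inhib = inhibition_kernel(5),
                           tau_on = 60, tau_off = 60,
                           w_group = grouping_kernel(3),
                           decay_threshold = 15, decay_coeff = 0,
                           bias_on = 1, bias_off = 1) {
  check_kernel <- function(k, name, hollow = FALSE) {
    if (!is.matrix(k) || nrow(k) %% 2 != 1 || ncol(k) %% 2 != 1)
      stop(name, " must be an odd-sized matrix")
    if (any(k < 0)) stop(name, " must be non-negative")
    if (hollow && k[(nrow(k) + 1) / 2, (ncol(k) + 1) / 2] != 0)
      stop(name, " must have center weight 0")
  }
  check_kernel(w_inhib, "w_inhib", hollow = TRUE)
  check_kernel(w_group, "w_group")
  if (abs(sum(w_group) - 1) > 1e-9) stop("w_group must sum to 1")
  if (tau_on <= 0 || tau_off <= 0) stop("delay constants must be positive")
  if (bias_on < 0 || bias_off < 0) stop("channel biases must be >= 0")
  if (decay_coeff < 0 || decay_coeff > 1)
    stop("decay_coeff must lie in [0, 1]")
  structure(list(w_inhib = w_inhib, tau_on = tau_on, tau_off = tau_off,
                 w_group = w_group, decay_threshold = decay_threshold,
                 decay_coeff = decay_coeff,
                 bias_on = bias_on, bias_off = bias_off),
            class = "channel_params")
}

#' Fresh channel state (zero delayed maps)
#'
#' @param dims frame dimensions `c(rows, cols)`.
#' @return a `channel_state` with zero-initialized delayed ON and |OFF| maps.
#' @export
channel_state <- function(dims) {
  z <- matrix(0, dims[1], dims[2])
  structure(list(delayed_on = z, delayed_off = z), class = "channel_state")
}

#' Elementwise first-order temporal low-pass of a map
#'
#' Same alpha-form as [smooth_ffi()], applied per pixel:
#' `alpha * current + (1 - alpha) * delayed_prev` with
#' `alpha = tau_in / (tau + tau_in)`.
#'
#' @param current current map.
#' @param delayed_prev previous delayed map.
#' @param tau delay constant, ms.
#' @param tau_in base interval constant, ms.
#' @return delayed map, same shape.
#' @export
delay_map <- function(current, delayed_prev, tau, tau_in) {
  if (!identical(dim(current), dim(delayed_prev)))
    stop("map shapes must match")
  if (tau <= 0 || tau_in <= 0) stop("tau and tau_in must be positive")
  a <- tau_in / (tau + tau_in)
  a * current + (1 - a) * delayed_prev
}

# Zero-padded 2-D correlation via shifted sums; kernels are small so this is
# a handful of vectorized matrix adds.
conv2_zero <- function(x, k) {
  R <- nrow(x); C <- ncol(x)
  hr <- (nrow(k) - 1) / 2; hc <- (ncol(k) - 1) / 2
  out <- matrix(0, R, C)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      w <- k[i, j]
      if (w == 0) next
      di <- i - 1 - hr; dj <- j - 1 - hc
      r1 <- max(1, 1 - di); r2 <- min(R, R - di)
      c1 <- max(1, 1 - dj); c2 <- min(C, C - dj)
      if (r1 > r2 || c1 > c2) next
      out[r1:r2, c1:c2] <- out[r1:r2, c1:c2] +
        w * x[(r1 + di):(r2 + di), (c1 + dj):(c2 + dj)]
    }
  }
  out
}

#' Spatially spread lateral inhibition
#'
#' Zero-padded 2-D correlation of the delayed polarity map with the
#' inhibition kernel.
#'
#' @param delayed delayed (low-passed) non-negative polarity map.
#' @param w_inhib inhibition kernel.
#' @return non-negative inhibition map, same shape as `delayed`.
#' @export
lateral_inhibition <- function(delayed, w_inhib) {
  if (nrow(w_inhib) > nrow(delayed) || ncol(w_inhib) > ncol(delayed))
    stop("kernel larger than the frame")
  conv2_zero(delayed, w_inhib)
}

#' Linear excitation-inhibition interaction
#'
#' `S = max(excitation - omega_t * inhibition, 0)`.
#'
#' @param excitation non-negative excitation map.
#' @param inhibition non-negative inhibition map.
#' @param omega_t current (FFI-adapted) inhibition weight, > 0.
#' @return rectified interaction map.
#' @export
interact <- function(excitation, inhibition, omega_t) {
  if (!identical(dim(excitation), dim(inhibition)))
    stop("map shapes must match")
  if (omega_t <= 0) stop("omega_t must be positive")
  pmax(excitation - omega_t * inhibition, 0)
}

#' Grouping and decay of summed channel excitation
#'
#' Local coherence pass: the summed map is scaled elementwise by its
#' normalized local mean (`conv(S, w_group) / (eps + max(S))`), so spatially
#' clustered excitation passes near-unchanged while isolated pixels are
#' attenuated by roughly the kernel area. Grouped values below
#' `decay_threshold` are then multiplied by `decay_coeff` (default 0),
#' discarding minor or brief isolated excitation.
#'
#' @param summed non-negative summed channel map.
#' @param w_group grouping kernel (sums to 1).
#' @param decay_threshold threshold in excitation units.
#' @param decay_coeff multiplier for sub-threshold values.
#' @return non-negative filtered excitation map `g_hat`.
#' @export
grouping <- function(summed, w_group, decay_threshold, decay_coeff = 0) {
  peak <- max(summed)
  if (peak <= 0) return(summed * 0)
  coherence <- conv2_zero(summed, w_group) / (1e-2 + peak)
  g <- summed * coherence
  low <- g < decay_threshold
  g[low] <- g[low] * decay_coeff
  g
}

#' One channel-stage step for both polarities
#'
#' Delay states always advance from the raw polarity maps, so gated-off
#' frames leave no stale inhibition behind. A channel whose gate is closed
#' contributes an all-zero map and skips its convolution and interaction
#' stages; the returned cost (a deterministic pixel-operation count) reflects
#' the skip. When at least one channel is active the summed map is grouped
#' into the filtered excitation.
#'
#' @param maps list with `on` (>= 0) and `off` (<= 0) polarity maps.
#' @param ffi_out FFI output for this frame (from [step_ffi()]).
#' @param params a [channel_params()].
#' @param state a [channel_state()].
#' @param tau_in base interval constant, ms.
#' @param update_gated_state advance delay states during gated-off frames
#'   (default TRUE).
#' @return list with `g_hat` (filtered excitation map), updated `state`, and
#'   `cost` (operation count for this frame's channel + grouping stages).
#' @export
step_channels <- function(maps, ffi_out, params, state, tau_in = 30,
                          update_gated_state = TRUE) {
  stopifnot(inherits(params, "channel_params"),
            inherits(state, "channel_state"))
  on_abs <- maps$on
  off_abs <- abs(maps$off)
  npx <- length(on_abs)
  k2 <- length(params$w_inhib)
  g2 <- length(params$w_group)

  new_on <- delay_map(on_abs, state$delayed_on, params$tau_on, tau_in)
  new_off <- delay_map(off_abs, state$delayed_off, params$tau_off, tau_in)

  cost <- 0
  run_channel <- function(beta, excit_raw, delayed, bias, omega) {
    if (beta == 0) return(NULL)
    inh <- lateral_inhibition(delayed, params$w_inhib)
    interact(bias * excit_raw, inh, omega)
  }
  s_on <- run_channel(ffi_out$beta_on, on_abs, new_on,
                      params$bias_on, ffi_out$omega_on)
  s_off <- run_channel(ffi_out$beta_off, off_abs, new_off,
                       params$bias_off, ffi_out$omega_off)
  if (!is.null(s_on)) cost <- cost + npx * (k2 + 2)
  if (!is.null(s_off)) cost <- cost + npx * (k2 + 2)

  if (is.null(s_on) && is.null(s_off)) {
    g_hat <- matrix(0, nrow(on_abs), ncol(on_abs))
  } else {
    summed <- (if (is.null(s_on)) 0 else s_on) +
      (if (is.null(s_off)) 0 else s_off)
    if (!is.matrix(summed)) summed <- matrix(summed, nrow(on_abs), ncol(on_abs))
    g_hat <- grouping(summed, params$w_group,
                      params$decay_threshold, params$decay_coeff)
    cost <- cost + npx * (g2 + 2)
  }

  if (update_gated_state || ffi_out$beta_on == 1) state$delayed_on <- new_on
  if (update_gated_state || ffi_out$beta_off == 1) state$delayed_off <- new_off

  list(g_hat = g_hat, state = state, cost = cost)
}
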