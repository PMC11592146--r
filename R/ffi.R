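#' Feed-forward inhibition parameters
#'
#' Each polarity channel owns one FFI statistic: the widefield mean of its
#' rectified luminance change. The statistic is smoothed by a first-order
#' low-pass with coefficient `alpha = tau_in / (tau + tau_in)`, then used
#' twice: the adaptive inhibition weight `omega = max(baseline, ffi_hat /
#' omega_ffi)` strengthens lateral inhibition when widefield change is large,
#' and the binary activation gate `beta = ffi_hat > th_ffi` lets a quiet
#' channel skip its spatial computation.
#'
#' @param tau3,tau4 smoothing delay constants for the ON / OFF FFI, ms.
#' @param tau_in base interval constant, ms (typically the frame interval).
#' @param omega_ffi scaling coefficient dividing the smoothed FFI to form the
#'   adaptive inhibition weight.
#' @param omega1,omega2 baseline inhibition weights of the ON / OFF channel.
#' @param th_ffi activation threshold in mean-luminance-change units; a
#'   channel participates only when its smoothed FFI strictly exceeds it.
#' @return an `ffi_params` object (also carries `alpha4`, `alpha5`).
#' @export
ffi_params <- function(tau3 = 90, tau4 = 90, tau_in = 30,
                       omega_ffi = 10, omega1 = 0.5, omega2 = 0.5,
                       th_ffi = 1) {
  if (tau3 <= 0 || tau4 <= 0 || tau_in <= 0)
    stop("tau3, tau4 and tau_in must be positive (ms)")
  if (omega_ffi <= 0) stop("omega_ffi must be positive")
  if (omega1 <= 0 || omega2 <= 0) stop("baseline weights must be positive")
  structure(list(tau3 = tau3, tau4 = tau4, tau_in = tau_in,
                 omega_ffi = omega_ffi, omega1 = omega1, omega2 = omega2,
                 th_ffi = th_ffi,
                 alpha4 = tau_in / (tau3 + tau_in),
                 alpha5 = tau_in / (tau4 + tau_in)),
            class = "ffi_params")
}

#' Fresh FFI state (smoothed values start at zero)
#' @return an `ffi_state` with `hat_on = hat_off = 0`.
#' @export
ffi_state <- function() {
  structure(list(hat_on = 0, hat_off = 0), class = "ffi_state")
}

#' Mean ON-contrast response over the visual field
#'
#' @param p_on non-negative ON polarity map.
#' @return scalar mean of `p_on` over all rows x cols cells.
#' @export
mean_ffi_on <- function(p_on) {
  stopifnot(is.matrix(p_on))
  if (length(p_on) == 0) stop("empty polarity map")
  sum(p_on) / length(p_on)
}

#' Mean OFF-contrast response (magnitude) over the visual field
#'
#' @param p_off non-positive OFF polarity map (signed).
#' @return scalar mean of `|p_off|`; always >= 0.
#' @export
mean_ffi_off <- function(p_off) {
  stopifnot(is.matrix(p_off))
  if (length(p_off) == 0) stop("empty polarity map")
  sum(abs(p_off)) / length(p_off)
}

#' First-order low-pass smoothing of an FFI value
#'
#' `alpha * current + (1 - alpha) * previous` with
#' `alpha = tau_in / (tau + tau_in)`.
#'
#' @param current current mean response.
#' @param previous previous smoothed value.
#' @param tau delay constant, ms.
#' @param tau_in base interval constant, ms.
#' @return smoothed scalar.
#' @export
smooth_ffi <- function(current, previous, tau, tau_in) {
  if (tau <= 0 || tau_in <= 0) stop("tau and tau_in must be positive")
  a <- tau_in / (tau + tau_in)
  a * current + (1 - a) * previous
}

#' Adaptive lateral-inhibition weight
#'
#' @param ffi_hat smoothed FFI value.
#' @param baseline baseline weight (floor).
#' @param omega_ffi scaling coefficient.
#' @return `max(baseline, ffi_hat / omega_ffi)`; non-decreasing in `ffi_hat`.
#' @export
inhibition_weight <- function(ffi_hat, baseline, omega_ffi) {
  if (omega_ffi <= 0) stop("omega_ffi must be positive")
  max(baseline, ffi_hat / omega_ffi)
}

#' Binary channel activation gate
#'
#' Strict comparison, no tolerance: the channel activates only when the
#' smoothed FFI exceeds the threshold.
#'
#' @param ffi_hat smoothed FFI value.
#' @param th_ffi activation threshold.
#' @return 0 if `ffi_hat <= th_ffi`, 1 otherwise.
#' @export
ffi_gate <- function(ffi_hat, th_ffi) {
  if (ffi_hat > th_ffi) 1L else 0L
}

#' One FFI step for both polarity channels
#'
#' Computes the widefield means, smooths them, derives the adaptive weights
#' and gates, and advances the state. The two channels are fully independent:
#' perturbing one polarity map never changes the other channel's outputs.
#'
#' @param maps list with matrices `on` (>= 0) and `off` (<= 0), from
#'   [split_polarity()].
#' @param params an [ffi_params()].
#' @param state an [ffi_state()].
#' @return list with `output` (fields `ffi_on`, `ffi_off`, `ffi_hat_on`,
#'   `ffi_hat_off`, `omega_on`, `omega_off`, `beta_on`, `beta_off`) and the
#'   updated `state`.
#' @export
step_ffi <- function(maps, params, state) {
  stopifnot(inherits(params, "ffi_params"), inherits(state, "ffi_state"))
  ffi_on <- mean_ffi_on(maps$on)
  ffi_off <- mean_ffi_off(maps$off)
  hat_on <- smooth_ffi(ffi_on, state$hat_on, params$tau3, params$tau_in)
  hat_off <- smooth_ffi(ffi_off, state$hat_off, params$tau4, params$tau_in)
  out <- list(ffi_on = ffi_on, ffi_off = ffi_off,
              ffi_hat_on = hat_on, ffi_hat_off = hat_off,
              omega_on = inhibition_weight(hat_on, params$omega1,
                                           params$omega_ffi),
              omega_off = inhibition_weight(hat_off, params$omega2,
                                            params$omega_ffi),
              beta_on = ffi_gate(hat_on, params$th_ffi),
              beta_off = ffi_gate(hat_off, params$th_ffi))
  state$hat_on <- hat_on
  state$hat_off <- hat_off
  list(output = out, state = state)
}
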