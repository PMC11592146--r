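#' LGMD integration parameters
#'
#' @param alpha6 sigmoid scale: the integrated excitation is divided by
#'   `rows * cols * alpha6` before the logistic squash, so `alpha6` is the
#'   mean per-pixel filtered excitation at which the membrane potential
#'   reaches ~0.73.
#' @param alpha7 spike-rate scale; larger values give higher firing rates.
#' @param t_spi firing threshold inside the exponential rate mapping.
#' @param spike_mp_level membrane-potential level in `(0.5, 1)` whose strict
#'   exceedance fires the binary spike indicator (default 0.8).
#' @param n_sp spike count that must be reached within the decision window.
#' @param n_ts window length: the current frame plus the previous `n_ts`
#'   frames are counted. Requires `n_sp <= n_ts + 1`.
#' @param sfa_tau spike-frequency-adaptation time constant, ms.
#' @param sfa_mode `"highpass"` (default) or `"off"`.
#' @param sfa_rise_tol minimum frame-to-frame membrane-potential increase that
#'   counts as a genuine rise (transmitted unattenuated); smaller fluctuations
#'   take the decaying branch, so a flat but jittering response still adapts
#'   away.
#' @return an `lgmd_params` object.
#' @export
lgmd_params <- function(alpha6 = 1.5, alpha7 = 10, t_spi = 5,
                        spike_mp_level = 0.8, n_sp = 5, n_ts = 9,
                        sfa_tau = 270, sfa_mode = c("highpass", "off"),
                        sfa_rise_tol = 0.02) {
  sfa_mode <- match.arg(sfa_mode)
  if (alpha6 <= 0 || alpha7 <= 0) stop("alpha6 and alpha7 must be positive")
  if (spike_mp_level <= 0.5 || spike_mp_level >= 1)
    stop("spike_mp_level must lie in (0.5, 1)")
  if (n_sp < 1) stop("n_sp must be >= 1")
  if (n_sp > n_ts + 1)
    stop("n_sp exceeds the decision window (need n_sp <= n_ts + 1)")
  if (sfa_tau <= 0) stop("sfa_tau must be positive")
  if (sfa_rise_tol < 0) stop("sfa_rise_tol must be >= 0")
  structure(list(alpha6 = alpha6, alpha7 = alpha7, t_spi = t_spi,
                 spike_mp_level = spike_mp_level,
                 n_sp = as.integer(n_sp), n_ts = as.integer(n_ts),
                 sfa_tau = sfa_tau, sfa_mode = sfa_mode,
                 sfa_rise_tol = sfa_rise_tol),
            class = "lgmd_params")
}

#' Integrate filtered excitation into the feed-forward excitation sum
#'
#' @param g_hat filtered excitation map.
#' @return scalar sum over the field; >= 0 for non-negative maps.
#' @export
integrate_excitation <- function(g_hat) {
  sum(g_hat)
}

#' Sigmoid membrane potential
#'
#' `K = 1 / (1 + exp(-ffe / (rows * cols * alpha6)))`, normalized into
#' `[0.5, 1)`: zero excitation gives exactly 0.5 and the potential approaches
#' but never reaches 1.
#'
#' @param ffe integrated excitation (>= 0).
#' @param rows,cols visual-field dimensions.
#' @param alpha6 sigmoid scale.
#' @return membrane potential in `[0.5, 1)`.
#' @export
membrane_potential <- function(ffe, rows, cols, alpha6) {
  if (rows * cols <= 0) stop("field must be non-empty")
  if (alpha6 <= 0) stop("alpha6 must be positive")
  k <- 1 / (1 + exp(-ffe / (rows * cols * alpha6)))
  # the sigmoid never reaches 1 analytically; keep that true in floating
  # point when exp() underflows for very large excitation
  pmin(k, 1 - .Machine$double.eps / 2)
}

#' Spike-frequency adaptation of the membrane potential
#'
#' High-pass scheme: a genuine rise (exceeding `rise_tol`) is transmitted
#' unattenuated, while flat or falling potential decays as
#' `max(0.5, a * (prev_adapted + k - prev_k))` with
#' `a = sfa_tau / (sfa_tau + interval)`. A sustained constant potential
#' therefore sinks back toward the 0.5 resting level, sharpening selectivity
#' for the accelerating excitation of a true approach.
#'
#' @param k current membrane potential.
#' @param prev_k previous membrane potential.
#' @param prev_adapted previous adapted value.
#' @param sfa_tau adaptation time constant, ms.
#' @param interval frame interval, ms.
#' @param mode `"highpass"` or `"off"` (identity).
#' @param rise_tol minimum increase counted as a rise.
#' @return adapted membrane potential in `[0.5, 1)`.
#' @export
adapt_sfa <- function(k, prev_k, prev_adapted, sfa_tau, interval,
                      mode = "highpass", rise_tol = 0) {
  if (mode == "off") return(k)
  if (k - prev_k > rise_tol) return(k)
  a <- sfa_tau / (sfa_tau + interval)
  max(0.5, a * (prev_adapted + k - prev_k))
}

#' Exponential spike-rate mapping
#'
#' @param k (adapted) membrane potential.
#' @param alpha7 rate scale.
#' @param t_spi firing threshold.
#' @return `exp(alpha7 * k - t_spi)`; strictly increasing in `k`.
#' @export
spike_rate <- function(k, alpha7, t_spi) {
  exp(alpha7 * k - t_spi)
}

#' Binary spike indicator
#'
#' Fires when the adapted membrane potential strictly exceeds the level
#' (default 0.8).
#'
#' @param adapted_k adapted membrane potential.
#' @param spike_mp_level exceedance level.
#' @return 1 or 0.
#' @export
spike_indicator <- function(adapted_k, spike_mp_level = 0.8) {
  if (adapted_k > spike_mp_level) 1L else 0L
}

#' Windowed spike-count collision decision
#'
#' @param spike_history integer vector of spike flags, most recent last; the
#'   last `n_ts + 1` entries (shorter prefixes count as-is, implicitly
#'   zero-padded) form the decision window.
#' @param n_sp spike count threshold.
#' @param n_ts window length minus one (previous frames included).
#' @return TRUE if the windowed spike count reaches `n_sp`.
#' @export
collision_decision <- function(spike_history, n_sp, n_ts) {
  if (length(spike_history) < 1) stop("spike history must be non-empty")
  if (n_sp > n_ts + 1)
    stop("n_sp exceeds the decision window (need n_sp <= n_ts + 1)")
  window <- utils::tail(spike_history, n_ts + 1)
  sum(window) >= n_sp
}
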