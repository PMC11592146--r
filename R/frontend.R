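#' Convert a raw frame to grayscale luminance
#'
#' Three-channel input is reduced with the fixed luma weights
#' (0.299, 0.587, 0.114); single-channel input passes through. Values are kept
#' real (no re-quantization) so downstream recurrences are exact.
#'
#' @param raw a rows x cols matrix or a rows x cols x channels array with 1 or
#'   3 channels, luminance on the 0--255 scale.
#' @param index frame number, stored on the result.
#' @param interval frame interval in ms.
#' @return a `frame`: list with `values` (matrix), `index`, `interval`.
#' @export
to_grayscale <- function(raw, index = 1L, interval = 30) {
  if (is.matrix(raw)) {
    values <- raw
  } else if (is.array(raw) && length(dim(raw)) == 3) {
    ch <- dim(raw)[3]
    if (ch == 1) {
      values <- raw[, , 1]
    } else if (ch == 3) {
      values <- 0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else {
      stop("expected 1 or 3 channels, got ", ch)
    }
    if (!is.matrix(values))
      values <- matrix(values, dim(raw)[1], dim(raw)[2])
  } else {
    stop("raw frame must be a matrix or a rows x cols x channels array")
  }
  structure(list(values = values, index = as.integer(index),
                 interval = interval), class = "frame")
}

#' Initialize photoreceptor state
#'
#' The photoreceptor layer differences consecutive frames with an optional
#' luminance-persistence term: `P(t) = L(t) - L(t-1) + p * P(t-1)`. State holds
#' the previous frame and previous output; a fresh state encodes the start of a
#' sequence, whose first frame always yields `P = 0`.
#'
#' @param persistence_coeff persistence coefficient `p` in `[0, 1)`; the
#'   default 0 is pure frame differencing.
#' @return a `frontend_state`.
#' @export
frontend_state <- function(persistence_coeff = 0) {
  if (persistence_coeff < 0 || persistence_coeff >= 1)
    stop("persistence_coeff must lie in [0, 1)")
  structure(list(previous = NULL, previous_P = NULL,
                 persistence_coeff = persistence_coeff),
            class = "frontend_state")
}

#' Photoreceptor: temporal luminance change with persistence
#'
#' @param current numeric matrix of luminance, or a `frame` from
#'   [to_grayscale()].
#' @param state a [frontend_state()].
#' @return list with `P` (change matrix, zero on the first frame of a
#'   sequence) and the updated `state`.
#' @export
photoreceptor <- function(current, state) {
  stopifnot(inherits(state, "frontend_state"))
  if (inherits(current, "frame")) current <- current$values
  stopifnot(is.matrix(current))
  if (is.null(state$previous)) {
    P <- matrix(0, nrow(current), ncol(current))
  } else {
    if (!identical(dim(current), dim(state$previous)))
      stop("frame shape changed mid-sequence")
    P <- current - state$previous + state$persistence_coeff * state$previous_P
  }
  state$previous <- current
  state$previous_P <- P
  list(P = P, state = state)
}

#' Half-wave split of the change signal into ON and OFF polarity maps
#'
#' `on = max(P, 0)` encodes brightening, `off = min(P, 0)` (kept signed)
#' encodes darkening; `on + off` reconstructs `P` exactly and at most one map
#' is nonzero at any pixel.
#'
#' @param P change matrix from [photoreceptor()].
#' @return list with matrices `on` (>= 0) and `off` (<= 0).
#' @export
split_polarity <- function(P) {
  stopifnot(is.matrix(P))
  list(on = pmax(P, 0), off = pmin(P, 0))
}
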