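#' Specify a synthetic visual stimulus
#'
#' Builds and validates the description of one synthetic grayscale test
#' stimulus: an object approaching (looming), receding, translating across the
#' field, or a drifting square-wave grating. Looming/receding objects are drawn
#' centered; a pixel belongs to the object when its (Chebyshev for `square`,
#' Euclidean for `disc`) distance from the center is strictly less than the
#' frame's half-width, so a half-width of 0 draws nothing. Rendering is binary
#' (no antialiasing) so pixel counts can be checked exactly.
#'
#' @param kind one of `"looming"`, `"receding"`, `"translating"`, `"grating"`.
#' @param polarity `"dark_object_on_light_bg"` or `"light_object_on_dark_bg"`
#'   (abbreviations `"dark"` / `"light"` accepted). Controls the default
#'   luminance levels and is validated against them.
#' @param resolution integer vector `c(rows, cols)`.
#' @param n_frames number of frames.
#' @param frame_interval frame interval in milliseconds.
#' @param object_shape `"square"` or `"disc"`.
#' @param size_profile optional numeric vector of per-frame half-widths in
#'   pixels (length `n_frames`). If `NULL`, looming uses a hyperbolic
#'   constant-approach-speed profile from `w_start` to `w_end` (image expansion
#'   accelerates toward the final frame, as it does for an object closing at
#'   constant speed); receding uses the reverse. Must be non-decreasing for
#'   looming and non-increasing for receding.
#' @param w_start,w_end half-width (pixels) at the first/last frame of the
#'   default looming profile. `w_end` defaults to `0.9 * min(resolution) / 2`.
#' @param delta shape parameter of the hyperbolic profile: the virtual
#'   time-to-contact at the last frame, in frames. Smaller values give a
#'   steeper final expansion.
#' @param object_halfwidth half-width of the translating object, pixels.
#' @param translate_speed horizontal drift of the translating object,
#'   pixels/frame (position is clamped so the object stays inside the frame).
#' @param grating_period,grating_speed period (pixels) and drift speed
#'   (pixels/frame) of the vertical square-wave grating.
#' @param background_level,object_level luminance levels in `[0, 255]`;
#'   defaults are 200/50 for dark polarity and 50/200 for light.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (luminance units); frames are clipped back to `[0, 255]`.
#' @param seed integer seed making noisy rendering bit-reproducible.
#' @return an object of class `stimulus_spec`.
#' @seealso [render_stimulus()], [default_battery()]
#' @export
stimulus_spec <- function(kind = c("looming", "receding", "translating", "grating"),
                          polarity = "dark_object_on_light_bg",
                          resolution = c(99, 99),
                          n_frames = 100,
                          frame_interval = 30,
                          object_shape = c("square", "disc"),
                          size_profile = NULL,
                          w_start = 2, w_end = NULL, delta = 5,
                          object_halfwidth = 10,
                          translate_speed = 2,
                          grating_period = 20,
                          grating_speed = 2,
                          background_level = NULL,
                          object_level = NULL,
                          noise_sd = 0,
                          seed = 0L) {
  kind <- match.arg(kind)
  object_shape <- match.arg(object_shape)
  polarity <- match.arg(polarity,
                        c("dark_object_on_light_bg", "light_object_on_dark_bg",
                          "dark", "light"))
  if (polarity == "dark") polarity <- "dark_object_on_light_bg"
  if (polarity == "light") polarity <- "light_object_on_dark_bg"
  dark <- polarity == "dark_object_on_light_bg"
  if (is.null(background_level)) background_level <- if (dark) 200 else 50
  if (is.null(object_level)) object_level <- if (dark) 50 else 200

  stopifnot(length(resolution) == 2, all(resolution >= 3))
  resolution <- as.integer(resolution)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (frame_interval <= 0) stop("frame_interval must be positive (ms)")
  lv <- c(background_level, object_level)
  if (any(lv < 0 | lv > 255)) stop("luminance levels must lie in [0, 255]")
  if (dark && !(object_level < background_level))
    stop("dark_object_on_light_bg requires object_level < background_level")
  if (!dark && !(object_level > background_level))
    stop("light_object_on_dark_bg requires object_level > background_level")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  half_max <- min(resolution) / 2
  if (is.null(w_end)) w_end <- floor(0.9 * half_max)

  if (kind %in% c("looming", "receding")) {
    if (is.null(size_profile)) {
      size_profile <- looming_profile(n_frames, w_start, w_end, delta)
      if (kind == "receding") size_profile <- rev(size_profile)
    }
    if (length(size_profile) != n_frames)
      stop("size_profile must have one half-width per frame")
    if (any(size_profile < 0)) stop("half-widths must be >= 0")
    d <- diff(size_profile)
    if (kind == "looming") {
      if (any(d < 0)) stop("looming size_profile must be non-decreasing")
      if (n_frames > 1 && size_profile[n_frames] < 0.8 * half_max)
        stop("looming must end at a half-width >= 0.8 * min(resolution) / 2")
    } else {
      if (any(d > 0)) stop("receding size_profile must be non-increasing")
    }
    if (max(size_profile) > half_max + 1)
      stop("object initial/final size exceeds the frame")
  } else {
    size_profile <- NULL
  }
  if (kind == "translating") {
    if (object_halfwidth <= 0 || object_halfwidth > half_max)
      stop("translating object_halfwidth must be in (0, min(resolution)/2]")
  }
  if (kind == "grating") {
    if (grating_period < 2 || grating_period > min(resolution))
      stop("grating_period must lie in [2, min(resolution)]")
  }

  structure(list(kind = kind, polarity = polarity,
                 resolution = resolution, n_frames = n_frames,
                 frame_interval = frame_interval,
                 object_shape = object_shape, size_profile = size_profile,
                 object_halfwidth = object_halfwidth,
                 translate_speed = translate_speed,
                 grating_period = grating_period, grating_speed = grating_speed,
                 background_level = background_level,
                 object_level = object_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "stimulus_spec")
}

#' Hyperbolic looming half-width profile
#'
#' Half-width of the retinal image of an object approaching at constant speed
#' grows like `1 / (time to contact)`. The profile is normalized to run from
#' `w_start` at frame 1 to `w_end` at frame `n`, with `delta` frames of
#' residual time-to-contact at the final frame controlling the steepness of
#' the last-moment expansion.
#'
#' @param n number of frames.
#' @param w_start,w_end first/last half-width in pixels.
#' @param delta residual time-to-contact at the final frame, in frames.
#' @return numeric vector of `n` non-decreasing half-widths.
#' @export
looming_profile <- function(n, w_start = 2, w_end = 44, delta = 5) {
  stopifnot(n >= 1, delta > 0, w_end >= w_start)
  if (n == 1) return(w_end)
  t <- seq_len(n) - 1
  g <- 1 / (1 - t / (n - 1 + delta)) - 1     # 0 at t=0, increasing
  w_start + (w_end - w_start) * g / g[n]
}

#' Render a stimulus specification into a frame sequence
#'
#' Deterministic: the same spec (including `seed`) always yields bit-identical
#' frames. With `noise_sd = 0` every pixel is exactly `background_level` or
#' `object_level`.
#'
#' @param spec a [stimulus_spec()].
#' @return a `frame_sequence`: list with `frames` (list of rows x cols numeric
#'   matrices in `[0, 255]`), `interval` (ms) and `resolution`.
#' @export
render_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  R <- spec$resolution[1]; C <- spec$resolution[2]
  cr <- (R + 1) / 2; cc <- (C + 1) / 2
  bg <- spec$background_level; ob <- spec$object_level

  dist_grid <- function(cr, cc) {
    dr <- abs(seq_len(R) - cr); dc <- abs(seq_len(C) - cc)
    if (spec$object_shape == "square") outer(dr, dc, pmax)
    else sqrt(outer(dr^2, dc^2, `+`))
  }

  frames <- vector("list", spec$n_frames)
  if (spec$kind %in% c("looming", "receding")) {
    g <- dist_grid(cr, cc)
    for (t in seq_len(spec$n_frames)) {
      f <- matrix(bg, R, C)
      f[g < spec$size_profile[t]] <- ob
      frames[[t]] <- f
    }
  } else if (spec$kind == "translating") {
    w <- spec$object_halfwidth
    lo <- ceiling(w); hi <- C + 1 - ceiling(w)
    for (t in seq_len(spec$n_frames)) {
      x <- min(max(lo + spec$translate_speed * (t - 1), lo), hi)
      g <- dist_grid(cr, x)
      f <- matrix(bg, R, C)
      f[g < w] <- ob
      frames[[t]] <- f
    }
  } else {                                   # grating
    half <- spec$grating_period / 2
    for (t in seq_len(spec$n_frames)) {
      phase <- spec$grating_speed * (t - 1)
      stripe <- floor(((seq_len(C) - 1 + phase) %% spec$grating_period) / half)
      row <- ifelse(stripe == 0, bg, ob)
      frames[[t]] <- matrix(row, R, C, byrow = TRUE)
    }
  }

  if (spec$noise_sd > 0) {
    frames <- with_local_seed(spec$seed, {
      lapply(frames, function(f) {
        f <- f + stats::rnorm(length(f), 0, spec$noise_sd)
        f[f < 0] <- 0; f[f > 255] <- 255
        f
      })
    })
  }
  structure(list(frames = frames, interval = spec$frame_interval,
                 resolution = spec$resolution),
            class = "frame_sequence")
}

# Evaluate expr under a temporary RNG state so rendering never disturbs the
# caller's random stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Label a frame sequence with collision ground truth
#'
#' @param frames a `frame_sequence`.
#' @param collision_expected named logical vector: for each preset name, should
#'   this sequence raise a collision alarm?
#' @param collision_window integer `c(first, last)` frame (1-based, inclusive)
#'   within which an alarm counts as a true positive.
#' @param name short identifier for reports.
#' @param spec the originating [stimulus_spec()], if any.
#' @return a `labelled_sequence`.
#' @export
labelled_sequence <- function(frames, collision_expected, collision_window,
                              name = "sequence", spec = NULL) {
  stopifnot(inherits(frames, "frame_sequence"))
  n <- length(frames$frames)
  if (collision_window[1] < 1 || collision_window[2] > n ||
      collision_window[1] > collision_window[2])
    stop("collision_window must lie within the sequence")
  if (is.null(names(collision_expected)))
    stop("collision_expected must be a named logical vector")
  structure(list(frames = frames,
                 collision_expected = collision_expected,
                 collision_window = as.integer(collision_window),
                 name = name, spec = spec),
            class = "labelled_sequence")
}

#' The default synthetic test battery
#'
#' Eight noise-free sequences covering \{dark, light\} x \{looming, receding,
#' translating\} plus two drifting gratings, each labelled with the selectivity
#' ground truth: `oLGMD1` should alarm on both loomings, `oLGMD2` only on the
#' dark looming, `reverse-oLGMD2` only on the light looming, and no preset on
#' receding, translating, or grating motion. Ungated baselines inherit the
#' expectations of their gated counterparts. The collision window is the final
#' 15% of each looming sequence, where the expanding edge accelerates.
#'
#' @param seed integer seed (forwarded to the renderer; the default battery is
#'   noise-free, so frames are identical for every seed).
#' @param n_frames frames per sequence.
#' @param resolution frame size `c(rows, cols)`.
#' @param noise_sd Gaussian pixel noise level for every sequence.
#' @return list of [labelled_sequence()] objects.
#' @export
default_battery <- function(seed = 0L, n_frames = 100, resolution = c(99, 99),
                            noise_sd = 0) {
  win <- c(n_frames - ceiling(0.15 * n_frames) + 1, n_frames)
  expect <- function(o1, o2, r2) {
    c("oLGMD1" = o1, "oLGMD2" = o2, "reverse-oLGMD2" = r2,
      "baseline-LGMD1" = o1, "baseline-LGMD2" = o2)
  }
  none <- expect(FALSE, FALSE, FALSE)
  mk <- function(name, truth, window = c(1, n_frames), ...) {
    spec <- stimulus_spec(resolution = resolution, n_frames = n_frames,
                          noise_sd = noise_sd, seed = seed, ...)
    labelled_sequence(render_stimulus(spec), truth, window, name, spec)
  }
  list(
    mk("dark-looming", expect(TRUE, TRUE, FALSE), win,
       kind = "looming", polarity = "dark"),
    mk("light-looming", expect(TRUE, FALSE, TRUE), win,
       kind = "looming", polarity = "light"),
    mk("dark-receding", none, kind = "receding", polarity = "dark"),
    mk("light-receding", none, kind = "receding", polarity = "light"),
    mk("dark-translating", none, kind = "translating", polarity = "dark"),
    mk("light-translating", none, kind = "translating", polarity = "light"),
    mk("grating-fine", none, kind = "grating", polarity = "dark",
       grating_period = max(4, 2 * round(min(resolution) / 10)),
       grating_speed = 2),
    mk("grating-coarse", none, kind = "grating", polarity = "dark",
       grating_period = max(8, 2 * round(min(resolution) / 5)),
       grating_speed = 4)
  )
}
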