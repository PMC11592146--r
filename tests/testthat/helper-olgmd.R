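# Independent brute-force oracles and small fixture builders.

# Naive O(R*C*k^2) zero-padded 2-D correlation.
naive_conv2 <- function(x, k) {
  R <- nrow(x); C <- ncol(x)
  hr <- (nrow(k) - 1) / 2; hc <- (ncol(k) - 1) / 2
  out <- matrix(0, R, C)
  for (r in seq_len(R)) for (c in seq_len(C)) {
    acc <- 0
    for (i in seq_len(nrow(k))) for (j in seq_len(ncol(k))) {
      rr <- r + i - 1 - hr; cc <- c + j - 1 - hc
      if (rr >= 1 && rr <= R && cc >= 1 && cc <= C)
        acc <- acc + k[i, j] * x[rr, cc]
    }
    out[r, c] <- acc
  }
  out
}

# Naive grouping oracle mirroring the documented definition.
naive_grouping <- function(s, w_group, decay_threshold, decay_coeff = 0) {
  peak <- max(s)
  if (peak <= 0) return(s * 0)
  g <- s * (naive_conv2(s, w_group) / (1e-2 + peak))
  ifelse(g < decay_threshold, g * decay_coeff, g)
}

# Count of object pixels by per-pixel distance test (rasterization oracle).
naive_object_count <- function(R, C, w, shape) {
  cr <- (R + 1) / 2; cc <- (C + 1) / 2
  n <- 0
  for (r in seq_len(R)) for (c in seq_len(C)) {
    d <- if (shape == "square") max(abs(r - cr), abs(c - cc))
         else sqrt((r - cr)^2 + (c - cc)^2)
    if (d < w) n <- n + 1
  }
  n
}

# Small random frame sequence (uniform noise frames, fixed seed).
random_sequence <- function(seed, n = 20, dims = c(16, 16)) {
  set.seed(seed)
  frames <- lapply(seq_len(n), function(i)
    matrix(runif(prod(dims), 0, 255), dims[1], dims[2]))
  structure(list(frames = frames, interval = 30, resolution = dims),
            class = "frame_sequence")
}

# Small quick looming sequence for end-to-end tests.
tiny_looming <- function(polarity = "dark", n = 60, res = c(49, 49)) {
  render_stimulus(stimulus_spec("looming", polarity, resolution = res,
                                n_frames = n, w_end = floor(0.9 * res[1] / 2)))
}

drop_wallclock <- function(trace) trace[, setdiff(names(trace), "cost_ms")]
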