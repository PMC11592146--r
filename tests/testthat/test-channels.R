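test_that("delay_map converges, decays geometrically and has a no-delay limit", {
  m <- matrix(5, 4, 4)
  d <- matrix(0, 4, 4)
  for (i in 1:200) d <- delay_map(m, d, 60, 30)
  expect_equal(d, m, tolerance = 1e-8)

  a <- 30 / (60 + 30)
  d <- delay_map(matrix(9, 2, 2), matrix(0, 2, 2), 60, 30)   # impulse
  for (k in 1:5) {
    d0 <- d
    d <- delay_map(matrix(0, 2, 2), d, 60, 30)
    expect_equal(d, (1 - a) * d0)
  }

  near0 <- delay_map(m, matrix(1, 4, 4), 1e-9, 30)
  expect_equal(near0, m, tolerance = 1e-9)
  expect_error(delay_map(m, matrix(0, 3, 3), 60, 30), "shapes")
})

test_that("lateral inhibition matches the naive convolution oracle", {
  expect_true(all(lateral_inhibition(matrix(0, 6, 6),
                                     inhibition_kernel(3)) == 0))
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  k <- inhibition_kernel(3)
  out <- lateral_inhibition(imp, k)
  expect_equal(out[3:5, 3:5], k[3:1, 3:1])  # impulse response, center 0
  expect_equal(out[4, 4], 0)

  set.seed(99)
  for (i in 1:25) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    x <- matrix(runif(n * m, 0, 10), n, m)
    kern <- if (min(n, m) >= 5 && runif(1) < 0.5) inhibition_kernel(5)
            else inhibition_kernel(3)
    expect_equal(lateral_inhibition(x, kern), naive_conv2(x, kern))
  }
  expect_error(lateral_inhibition(matrix(0, 3, 3), inhibition_kernel(5)),
               "larger")
})

test_that("excitation-inhibition interaction is linear then rectified", {
  e <- matrix(10, 3, 3); i <- matrix(4, 3, 3)
  expect_equal(interact(e, matrix(0, 3, 3), 1), e)
  expect_equal(interact(e, e / 0.5, 0.5), matrix(0, 3, 3))
  expect_equal(interact(e, i, 0.5)[1, 1], 8)
  expect_true(all(interact(i, e, 2) == 0))
  expect_error(interact(e, i, 0), "positive")
})

test_that("grouping keeps coherent blocks and suppresses isolated pixels", {
  wg <- grouping_kernel(3)
  expect_true(all(grouping(matrix(0, 5, 5), wg, 10) == 0))

  lone <- matrix(0, 9, 9); lone[5, 5] <- 50
  expect_true(all(grouping(lone, wg, 15) == 0))  # 50/9 < 15 -> suppressed

  block <- matrix(0, 11, 11); block[3:9, 3:9] <- 40
  g <- grouping(block, wg, 15)
  expect_gte(g[6, 6], 40 * (40 / (40 + 1e-2)) - 1e-9)

  set.seed(5)
  for (i in 1:25) {
    s <- matrix(runif(49, 0, 30), 7, 7)
    expect_equal(grouping(s, wg, 10, 0.25), naive_grouping(s, wg, 10, 0.25))
  }
})

test_that("closed gates contribute zero maps at strictly lower cost", {
  set.seed(1)
  maps <- split_polarity(matrix(rnorm(64, 0, 20), 8, 8))
  params <- channel_params()
  st <- channel_state(c(8, 8))
  both_closed <- list(beta_on = 0L, beta_off = 0L, omega_on = 1, omega_off = 1)
  both_open <- list(beta_on = 1L, beta_off = 1L, omega_on = 1, omega_off = 1)
  one_open <- list(beta_on = 1L, beta_off = 0L, omega_on = 1, omega_off = 1)

  r0 <- step_channels(maps, both_closed, params, st)
  r1 <- step_channels(maps, one_open, params, st)
  r2 <- step_channels(maps, both_open, params, st)
  expect_true(all(r0$g_hat == 0))
  expect_lt(r0$cost, r1$cost)
  expect_lt(r1$cost, r2$cost)
})

test_that("delay states advance from raw maps even when gated off", {
  maps <- split_polarity(matrix(10, 4, 4) - matrix(c(0, 20), 4, 4))
  params <- channel_params()
  st <- channel_state(c(4, 4))
  closed <- list(beta_on = 0L, beta_off = 0L, omega_on = 1, omega_off = 1)
  r <- step_channels(maps, closed, params, st)
  expect_true(any(r$state$delayed_on > 0) || any(r$state$delayed_off > 0))
  st_frozen <- step_channels(maps, closed, params, st,
                             update_gated_state = FALSE)$state
  expect_true(all(st_frozen$delayed_on == 0) && all(st_frozen$delayed_off == 0))
})

test_that("a gate threshold below any attainable FFI reproduces the ungated pipeline", {
  fr <- random_sequence(3, n = 15, dims = c(12, 12))
  for (preset in c("oLGMD1", "oLGMD2")) {
    baseline <- sub("oLGMD", "baseline-LGMD", preset)
    t_gated <- run_model(fr, olgmd_params(preset, list(th_ffi = -1)))
    t_free <- run_model(fr, olgmd_params(baseline))
    expect_identical(drop_wallclock(t_gated), drop_wallclock(t_free))
    expect_true(all(t_gated$beta_on == 1) && all(t_gated$beta_off == 1))
  }
})

test_that("strong ON suppression silences a pure brightening stimulus", {
  bright <- lapply(1:7, function(t) matrix(20 + 30 * t, 31, 31))
  fr <- structure(list(frames = bright, interval = 30,
                       resolution = c(31, 31)), class = "frame_sequence")
  ffe2 <- sum(run_model(fr, olgmd_params("oLGMD2"))$ffe)
  ffe1 <- sum(run_model(fr, olgmd_params("oLGMD1"))$ffe)
  expect_equal(ffe2, 0)
  expect_gt(ffe1, 0)
})

test_that("channel kernels and parameters are validated", {
  bad_center <- matrix(1, 3, 3)
  expect_error(channel_params(w_inhib = bad_center), "center")
  expect_error(channel_params(w_group = matrix(1, 3, 3)), "sum to 1")
  expect_error(channel_params(tau_on = 0), "positive")
  expect_error(channel_params(bias_on = -1), ">= 0")
})
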