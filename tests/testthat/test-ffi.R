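test_that("widefield FFI means match direct computation", {
  expect_equal(mean_ffi_on(matrix(0, 4, 4)), 0)
  expect_equal(mean_ffi_on(matrix(c(4, 0, 0, 0), 2, 2)), 1)
  expect_equal(mean_ffi_on(matrix(3.5, 6, 7)), 3.5)
  expect_equal(mean_ffi_off(matrix(c(-4, 0, 0, 0), 2, 2)), 1)
  m <- matrix(runif(20, 0, 9), 4, 5)
  expect_equal(mean_ffi_off(-m), mean_ffi_on(m))
  expect_error(mean_ffi_on(matrix(numeric(0), 0, 0)), "empty")
})

test_that("FFI smoothing has the right fixed point and closed form", {
  expect_equal(smooth_ffi(7, 7, 50, 30), 7)
  expect_equal(smooth_ffi(10, 0, 30, 30), 5)       # alpha = 1/2
  # constant input v from state 0 for k steps -> v * (1 - (1 - a)^k)
  for (a in c(0.1, 0.5, 0.9)) {
    tau_in <- 30; tau <- tau_in * (1 - a) / a
    v <- 4.2; s <- 0
    for (k in 1:25) {
      s <- smooth_ffi(v, s, tau, tau_in)
      expect_equal(s, v * (1 - (1 - a)^k), tolerance = 1e-12)
    }
  }
  expect_error(smooth_ffi(1, 0, -5, 30), "positive")
})

test_that("adaptive inhibition weight floors at the baseline", {
  expect_equal(inhibition_weight(0, 0.7, 3), 0.7)
  expect_equal(inhibition_weight(1, 0.3, 2), 0.5)
  expect_equal(inhibition_weight(0.3 * 2, 0.3, 2), 0.3)  # breakpoint
  h <- seq(0, 10, by = 0.5)
  w <- vapply(h, inhibition_weight, 0, baseline = 0.4, omega_ffi = 5)
  expect_true(all(diff(w) >= 0))
})

test_that("activation gate uses a strict threshold", {
  expect_identical(ffi_gate(1, 1), 0L)
  expect_identical(ffi_gate(1 + 1e-12, 1), 1L)
  expect_identical(ffi_gate(0, 0), 0L)
})

test_that("step_ffi composes the stages and keeps channels independent", {
  params <- ffi_params()
  st <- ffi_state()
  blank <- list(on = matrix(0, 5, 5), off = matrix(0, 5, 5))
  r <- step_ffi(blank, params, st)
  expect_identical(r$output$beta_on, 0L)
  expect_identical(r$output$beta_off, 0L)
  expect_equal(r$output$omega_on, params$omega1)
  expect_equal(r$output$omega_off, params$omega2)

  # ON-only stimulus never opens the OFF gate or moves OFF outputs
  on_maps <- list(on = matrix(50, 5, 5), off = matrix(0, 5, 5))
  st <- ffi_state()
  for (i in 1:10) {
    r <- step_ffi(on_maps, params, st)
    st <- r$state
    expect_identical(r$output$beta_off, 0L)
    expect_equal(r$output$ffi_off, 0)
    expect_equal(r$output$omega_off, params$omega2)
  }
  expect_identical(r$output$beta_on, 1L)
})

test_that("gate opens at the closed-form crossing frame under constant drive", {
  v <- 2; th <- 1
  params <- ffi_params(tau3 = 30, tau_in = 30, th_ffi = th)  # alpha = 1/2
  # v * (1 - (1-a)^k) > th  <=>  k > log(1 - th/v) / log(1-a)
  k_star <- ceiling(log(1 - th / v) / log(0.5) + 1e-12)
  maps <- list(on = matrix(v, 3, 3), off = matrix(0, 3, 3))
  st <- ffi_state()
  opened_at <- NA
  for (k in 1:20) {
    r <- step_ffi(maps, params, st)
    st <- r$state
    if (is.na(opened_at) && r$output$beta_on == 1L) opened_at <- k
  }
  expect_equal(opened_at, k_star)
})

test_that("raising the threshold never increases active channel-frames", {
  fr <- tiny_looming(n = 30, res = c(21, 21))
  active <- vapply(c(0, 0.5, 1, 2, 5, 50), function(th) {
    tr <- run_model(fr, olgmd_params("oLGMD1", list(th_ffi = th)))
    sum(tr$beta_on) + sum(tr$beta_off)
  }, 0)
  expect_true(all(diff(active) <= 0))
})

test_that("smoothed FFI converges geometrically and stays bounded", {
  params <- ffi_params(tau3 = 90, tau_in = 30)
  a <- params$alpha4
  v <- 6
  maps <- list(on = matrix(v, 2, 2), off = matrix(0, 2, 2))
  st <- ffi_state()
  hats <- numeric(40)
  for (k in 1:40) {
    r <- step_ffi(maps, params, st); st <- r$state
    hats[k] <- r$output$ffi_hat_on
  }
  expect_equal(hats, v * (1 - (1 - a)^(1:40)), tolerance = 1e-12)
  expect_true(all(hats >= 0 & hats <= v))
})
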