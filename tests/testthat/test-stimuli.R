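test_that("zero-size looming start is uniform background", {
  prof <- c(0, looming_profile(49, 2, 22, 5))
  spec <- stimulus_spec("looming", "dark", resolution = c(49, 49),
                        n_frames = 50, size_profile = prof)
  fr <- render_stimulus(spec)
  expect_true(all(fr$frames[[1]] == spec$background_level))
})

test_that("disc rasterization matches the per-pixel distance oracle", {
  for (w in c(0, 1, 3.5, 7, 10)) {
    spec <- stimulus_spec("looming", "dark", resolution = c(21, 21),
                          n_frames = 2, size_profile = c(w, 10),
                          object_shape = "disc")
    f <- render_stimulus(spec)$frames[[1]]
    expect_equal(sum(f == spec$object_level),
                 naive_object_count(21, 21, w, "disc"),
                 info = paste("half-width", w))
  }
})

test_that("square rasterization matches the distance oracle and grows monotonically", {
  spec <- stimulus_spec("looming", "light", resolution = c(33, 33),
                        n_frames = 40, w_end = 14)
  fr <- render_stimulus(spec)
  counts <- vapply(fr$frames, function(f) sum(f == spec$object_level), 0)
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[40],
               naive_object_count(33, 33, spec$size_profile[40], "square"))
})

test_that("grating shifted by a full period repeats exactly", {
  spec <- stimulus_spec("grating", "dark", resolution = c(30, 40),
                        n_frames = 5, grating_period = 10, grating_speed = 10)
  fr <- render_stimulus(spec)
  for (t in 2:5) expect_identical(fr$frames[[t]], fr$frames[[1]])
})

test_that("rendering is deterministic and noise-free frames are two-valued", {
  spec <- stimulus_spec("translating", "dark", resolution = c(25, 25),
                        n_frames = 10, object_halfwidth = 5, noise_sd = 3,
                        seed = 11)
  expect_identical(render_stimulus(spec), render_stimulus(spec))
  clean <- stimulus_spec("translating", "dark", resolution = c(25, 25),
                         n_frames = 10, object_halfwidth = 5)
  f <- render_stimulus(clean)$frames[[3]]
  expect_true(all(f %in% c(clean$background_level, clean$object_level)))
})

test_that("invalid stimulus specs are rejected", {
  expect_error(stimulus_spec("looming", n_frames = 0), "n_frames")
  expect_error(stimulus_spec("looming", "dark", object_level = 250),
               "object_level < background_level")
  expect_error(stimulus_spec("looming", resolution = c(21, 21), n_frames = 5,
                             size_profile = c(5, 4, 6, 8, 10)),
               "non-decreasing")
  expect_error(stimulus_spec("receding", resolution = c(21, 21), n_frames = 3,
                             size_profile = c(40, 30, 20)),
               "exceeds the frame")
  expect_error(stimulus_spec("looming", "dark", background_level = 300),
               "\\[0, 255\\]")
})

test_that("default battery covers the selectivity design with labels", {
  bat <- default_battery(0)
  expect_gte(length(bat), 8)
  kinds <- vapply(bat, function(s) s$spec$kind, "")
  expect_gte(sum(kinds == "grating"), 2)
  names(bat) <- vapply(bat, `[[`, "", "name")
  dark <- bat[["dark-looming"]]$collision_expected
  expect_true(dark[["oLGMD1"]] && dark[["oLGMD2"]])
  expect_false(dark[["reverse-oLGMD2"]])
  light <- bat[["light-looming"]]$collision_expected
  expect_true(light[["oLGMD1"]] && light[["reverse-oLGMD2"]])
  expect_false(light[["oLGMD2"]])
  for (s in bat) {
    expect_true(all(preset_names() %in% names(s$collision_expected)))
    if (s$spec$kind %in% c("grating", "translating", "receding"))
      expect_false(any(s$collision_expected))
    expect_true(s$collision_window[1] >= 1 &&
                s$collision_window[2] <= length(s$frames$frames))
  }
})

test_that("frame I/O round-trips through PGM (binary and ASCII) and PNG", {
  fr <- tiny_looming(n = 4, res = c(15, 17))
  for (fmt in c("pgm", "png")) {
    d <- withr::local_tempdir()
    write_frames(fr, d, format = fmt)
    back <- read_frames(d)
    expect_equal(back$frames, fr$frames, info = fmt)
    expect_equal(back$interval, fr$interval)
  }
  d2 <- withr::local_tempdir()
  write_frames(fr, d2, format = "pgm", ascii = TRUE)
  expect_equal(read_frames(d2)$frames, fr$frames)
})

test_that("mixed frame extensions are rejected", {
  d <- withr::local_tempdir()
  fr <- tiny_looming(n = 2, res = c(9, 9))
  write_pgm(fr$frames[[1]], file.path(d, "frame_00001.pgm"))
  png::writePNG(fr$frames[[2]] / 255, file.path(d, "frame_00002.png"))
  expect_error(read_frames(d), "mixed")
})
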