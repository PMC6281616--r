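test_that("SLB renders are flat fields with the requested density", {
  cfg0 <- render_config(gain = 0, read_noise = 0, seed = 1)
  img <- render_slb(2.5, shape = c(20, 30), cfg = cfg0)
  expect_equal(dim(img), c(20, 30))
  # expected ID over an ROI equals density x area (noise-free)
  id <- sum(img[1:10, 1:10] - cfg0$background)
  expect_equal(id, 2.5 * (10 * cfg0$pixel_size)^2, tolerance = 1e-9)
  # zero density -> background only
  img0 <- render_slb(0, shape = c(8, 8), cfg = cfg0)
  expect_true(all(img0 == cfg0$background))
})

test_that("tube renders are linear in radius and preserve flux", {
  cfg0 <- render_config(gain = 0, read_noise = 0, seed = 1)
  i1 <- render_tube(8, nx = 64, ny = 32, cfg = cfg0)
  i2 <- render_tube(16, nx = 64, ny = 32, cfg = cfg0)
  id1 <- sum(i1[, 30] - cfg0$background)
  id2 <- sum(i2[, 30] - cfg0$background)
  expect_equal(id2 / id1, 2, tolerance = 1e-6)
  # a zero-radius segment renders as pure background
  r <- c(rep(10, 30), rep(0, 34))
  i3 <- render_tube(r, nx = 64, ny = 32, cfg = cfg0)
  expect_lt(max(abs(i3[, 60] - cfg0$background)), 1e-6)
  expect_error(render_tube(5000, nx = 16, ny = 8, cfg = cfg0), "field")
})

test_that("remodeling movies conserve membrane area until scission", {
  mv <- simulate_remodeling_movie(growth_rate = 3, fission_radius = 5,
                                  scaffold_width = 1500, n_frames = 40,
                                  cfg = render_config(seed = 3))
  cut <- mv$events$time[mv$events$event == "scission"]
  expect_length(cut, 1)
  areas <- vapply(mv$profiles, function(r) sum(r), numeric(1))
  pre <- mv$times < cut
  expect_lt(diff(range(areas[pre])) / areas[1], 1e-6)
  # the thinned region passes ~7 nm on its way to the 5 nm threshold
  mins <- vapply(mv$profiles, function(r) min(r[r > 0]), numeric(1))
  expect_true(any(mins[pre] < 7.5 & mins[pre] > 6.5))
  expect_lt(min(mins[pre]), 5.6)
  # zero growth produces a static movie without events
  mv0 <- simulate_remodeling_movie(growth_rate = 0, n_frames = 10,
                                   cfg = render_config(seed = 3))
  expect_equal(nrow(mv0$events), 0)
  expect_equal(mv0$profiles[[1]], mv0$profiles[[10]])
})

test_that("generated movies are deterministic given the seed", {
  a <- simulate_remodeling_movie(n_frames = 6, cfg = render_config(seed = 5))
  b <- simulate_remodeling_movie(n_frames = 6, cfg = render_config(seed = 5))
  expect_identical(a$frames[[6]], b$frames[[6]])
  expect_identical(a$events, b$events)
})

test_that("kymograph edges advance linearly at the set speed", {
  cfg0 <- render_config(gain = 0, read_noise = 0, seed = 1)
  ky <- simulate_kymograph(speed = 27, duration = 10, frame_interval = 1,
                           cfg = cfg0)
  # displacement of the half-max crossing over 10 s is 270 nm
  x <- (seq_len(ncol(ky)) - 0.5) * attr(ky, "pixel_size")
  half <- (max(ky) + min(ky)) / 2
  e1 <- x[max(which(ky[1, ] > half))]
  e11 <- x[max(which(ky[11, ] > half))]
  expect_equal(e11 - e1, 270, tolerance = attr(ky, "pixel_size"))
  ky0 <- simulate_kymograph(speed = 0, duration = 5, cfg = cfg0)
  expect_equal(ky0[1, ], ky0[nrow(ky0), ], tolerance = 1e-9)
})

test_that("movie TIFF export round-trips frame content", {
  mv <- simulate_remodeling_movie(n_frames = 4, cfg = render_config(seed = 2))
  f <- tempfile(fileext = ".tif")
  write_movie_tiff(mv, f)
  back <- read_movie_tiff(f, pixel_size = mv$pixel_size)
  expect_length(back, 4)
  mx <- max(vapply(mv$frames, max, numeric(1)))
  expect_equal(as.vector(back[[2]]) * mx, as.vector(mv$frames[[2]]),
               tolerance = mx / 2^15)
})
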