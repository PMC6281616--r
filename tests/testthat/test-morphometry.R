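test_that("k1 calibration recovers the rendered membrane density", {
  cfg <- render_config(seed = 42, gain = 0.5, read_noise = 1)
  img <- render_slb(density = 3, shape = c(80, 80), cfg = cfg)
  img <- background_correct(img, cfg$background)
  rois <- list(list(x = c(1, 10), y = c(1, 10)),
               list(x = c(15, 34), y = c(5, 24)),
               list(x = c(40, 75), y = c(30, 69)),
               list(x = c(5, 60), y = c(50, 79)))
  cal <- calibrate_k1(img, rois)
  expect_equal(cal$k1, 3, tolerance = 0.02)
  # linearity: doubling all intensities doubles k1
  cal2 <- calibrate_k1(img * 2, rois)
  expect_equal(cal2$k1, 2 * cal$k1, tolerance = 1e-12)
  # identical ROI areas are rank-deficient
  same <- list(list(x = c(1, 10), y = c(1, 10)),
               list(x = c(21, 30), y = c(21, 30)),
               list(x = c(41, 50), y = c(41, 50)))
  expect_error(calibrate_k1(img, same), "rank-deficient")
})

test_that("integrated density converts to radius by the stated formula", {
  expect_equal(radius_from_integrated_density(0, 10, 5), 0)
  expect_equal(radius_from_integrated_density(2 * pi, 1, 1), 1)
  # forward-evaluate then invert
  expect_equal(radius_from_integrated_density(10 * 250 * 2 * pi * 20, 20, 250),
               10)
  expect_error(radius_from_integrated_density(5, 0, 1), "length")
  expect_error(radius_from_integrated_density(5, 1, 0), "k1")
  expect_error(radius_from_integrated_density(-1, 1, 1), "ID")
})

test_that("k2 calibration recovers the render constant within 5%", {
  cfg <- render_config(seed = 7, gain = 0.5, read_noise = 1)
  radii <- c(5, 10, 15, 20, 25)
  imgs <- lapply(seq_along(radii), function(i) {
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + i
    img <- render_tube(radii[i], nx = 96, ny = 32, cfg = cfg_i)
    background_correct(img, cfg$background)
  })
  cal <- calibrate_k2(imgs, radii)
  # reference: the peak of a noise-free render scales linearly in r
  ref <- max(background_correct(
    render_tube(10, nx = 96, ny = 32,
                cfg = render_config(seed = 1, gain = 0, read_noise = 0)),
    cfg$background)) / 10
  expect_equal(cal$k2, ref, tolerance = 0.05)
  expect_error(calibrate_k2(imgs[1], radii[1]), "rank-deficient")
  expect_warning(calibrate_k2(imgs[1:3], c(10, 10.5, 11)), "2-fold")
})

test_that("radius profiles come out of traces by dividing by k2", {
  prof <- radius_profile_from_trace(rep(50, 20), k2 = 5, pixel_size = 80)
  expect_true(all(prof$radius == 10))
  p0 <- radius_profile_from_trace(rep(0, 10), k2 = 5)
  expect_true(all(p0$radius == 0))
  pneg <- radius_profile_from_trace(c(-3, 10), k2 = 5)
  expect_equal(pneg$radius[1], 0)
  expect_equal(attr(pneg, "clipped"), 1)
})

test_that("protein:membrane ratios behave as ratios", {
  m <- matrix(10, 20, 20)
  roi <- list(x = c(1, 20), y = c(1, 20))
  expect_equal(protein_membrane_ratio(m, m, roi), 1)
  expect_equal(protein_membrane_ratio(m * 0, m, roi), 0)
  # tube ROI at 8x vs SLB ROI at 1x: ratio of ratios is 8
  tube_ratio <- protein_membrane_ratio(m * 8, m, roi)
  slb_ratio <- protein_membrane_ratio(m, m, roi)
  expect_equal(tube_ratio / slb_ratio, 8)
  expect_error(protein_membrane_ratio(m, m * 0, roi), "membrane")
})

test_that("Pearson correlation obeys its sign conventions", {
  x <- c(1, 4, 2, 8, 5, 7)
  expect_equal(pearson_protein_membrane(x, 3 * x + 2), 1)
  expect_equal(pearson_protein_membrane(x, -2 * x + 1), -1)
  expect_error(pearson_protein_membrane(x, rep(1, 6)), "variance")
  expect_error(pearson_protein_membrane(x, x[1:3]), "equal-length")
})

test_that("bulge detection counts, merges and measures density", {
  x <- seq(0, 10000, by = 50)  # a 10 um tube
  r <- rep(10, length(x))
  flat <- detect_bulges(data.frame(x = x, radius = r))
  expect_equal(nrow(flat$bulges), 0)
  expect_equal(flat$density_per_um, 0)
  # three well-separated bulges -> density 0.3 per um
  for (c0 in c(2000, 5000, 8000)) r[abs(x - c0) < 300] <- 15
  three <- detect_bulges(data.frame(x = x, radius = r))
  expect_equal(sum(three$bulges$sign > 0), 3)
  expect_equal(three$density_per_um, 0.3, tolerance = 1e-6)
  expect_equal(three$bulges$R_b[1], 15)
  expect_equal(three$bulges$baseline[1], 10)
  # two bulges closer than the merge distance collapse into one record
  r2 <- rep(10, length(x)); r2[abs(x - 3000) < 150] <- 15
  r2[abs(x - 3360) < 150] <- 15
  merged <- detect_bulges(data.frame(x = x, radius = r2),
                          merge_distance = 200)
  expect_equal(sum(merged$bulges$sign > 0), 1)
  # constriction reported with negative sign
  r3 <- rep(10, length(x)); r3[abs(x - 4000) < 300] <- 6
  con <- detect_bulges(data.frame(x = x, radius = r3))
  expect_equal(sum(con$bulges$sign < 0), 1)
  expect_error(detect_bulges(data.frame(x = 1:3, radius = 1:3)), "short")
})

test_that("fission kinetics build a non-decreasing cumulative curve", {
  none <- fission_kinetics(data.frame(onset = numeric(),
                                      scission = numeric()))
  expect_equal(none$curve(100), 0)
  ev <- data.frame(onset = c(10, 20, 5), scission = c(70, 50, 2))
  fk <- fission_kinetics(ev)
  expect_equal(fk$n_rejected, 1)            # scission before onset
  expect_equal(sort(fk$fission_times), c(30, 60))
  expect_true(all(diff(fk$curve(seq(0, 100, 1))) >= 0))
  expect_equal(fk$curve(60), 1)
  expect_equal(fk$curve(75), 2)
  # exponential fission times: fitted mean within 2 SE of the truth
  set.seed(31)
  n <- 200; lambda <- 1 / 40
  sim <- data.frame(onset = runif(n, 0, 10))
  sim$scission <- sim$onset + rexp(n, lambda)
  fk2 <- fission_kinetics(sim)
  expect_lt(abs(mean(fk2$fission_times) - 1 / lambda),
            2 * sd(fk2$fission_times) / sqrt(n))
})

test_that("remodeling probability bins with binomial intervals", {
  tubes <- data.frame(radius = c(5, 12, 18, 23, 35, 41, 8, 15),
                      remodeled = c(T, T, T, T, F, F, T, T),
                      cut = c(T, F, T, F, F, F, T, F))
  out <- remodeling_probability(tubes, breaks = c(0, 25, 60))
  expect_equal(out$p_remodeled[1], 1)
  expect_equal(out$p_remodeled[2], 0)
  # all-remodeled bin has probability 1; single-tube bins span [0,1]
  single <- remodeling_probability(data.frame(radius = 5, remodeled = TRUE,
                                              cut = FALSE),
                                   breaks = c(0, 10))
  expect_equal(single$p_remodeled[1], 1)
  expect_lt(single$lo[1], 0.05)
  expect_equal(single$hi[1], 1)
})

test_that("FRAP fits recover mobile fractions from synthetic traces", {
  # complete recovery -> mobile fraction ~ 1
  tr1 <- simulate_frap_trace(mobile_fraction = 1, noise_sd = 2, seed = 4,
                             n_points = 80)
  f1 <- fit_frap(tr1)
  expect_equal(f1$mobile_fraction, 1, tolerance = 0.05)
  # half recovery across several seeds
  est <- vapply(1:10, function(s)
    fit_frap(simulate_frap_trace(mobile_fraction = 0.5, seed = s,
                                 noise_sd = 5))$mobile_fraction, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
  # no bleach is an error
  bad <- simulate_frap_trace(F_p = 500, F_b = 500, mobile_fraction = 0.5)
  expect_error(fit_frap(bad), "F_b")
})

test_that("kymograph growth rates are recovered with correct sign", {
  ky <- simulate_kymograph(speed = 27, duration = 10,
                           cfg = render_config(seed = 9, read_noise = 3))
  out <- scaffold_growth_rate(ky)
  expect_false(out$low_confidence)
  expect_equal(out$rate_nm_per_s, 27, tolerance = 0.05 * 27)
  # static edge
  ky0 <- simulate_kymograph(speed = 0, duration = 10,
                            cfg = render_config(seed = 9))
  expect_equal(scaffold_growth_rate(ky0)$rate_nm_per_s, 0, tolerance = 1)
  # reversing the time axis flips the sign
  kyr <- ky[rev(seq_len(nrow(ky))), ]
  attr(kyr, "pixel_size") <- attr(ky, "pixel_size")
  attr(kyr, "frame_interval") <- attr(ky, "frame_interval")
  outr <- scaffold_growth_rate(kyr)
  expect_equal(outr$rate_nm_per_s, -out$rate_nm_per_s, tolerance = 2)
})
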