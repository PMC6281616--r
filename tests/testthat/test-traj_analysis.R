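make_bare_sys <- function(lumen = 6, len = 24) {
  build_tube(length = len, outer_diameter = lumen + 8, lumen_diameter = lumen,
             seed = 3, box_yz = 26)
}

test_that("lumen profile recovers a noise-free cylinder exactly", {
  sys <- make_bare_sys()
  sn <- cylinder_snapshot(sys, r_inner = 3)
  tr <- synthetic_traj(sys, list(sn, sn))
  prof <- lumen_radius_profile(tr, n_bins = 12, snapshot_window = 1:2)
  expect_lt(max(abs(prof$radius - 3)), 1e-9)
  expect_lt(max(prof$variance, na.rm = TRUE), 1e-18)
  # single-bin aggregation identity
  p1 <- lumen_radius_profile(tr, n_bins = 1, snapshot_window = 1:2)
  ih <- sys$class == "head" & sys$leaflet == "inner"
  yc <- mean(sn[!sys$frozen, 2]); zc <- mean(sn[!sys$frozen, 3])
  expect_equal(p1$radius,
               mean(sqrt((sn[ih, 2] - yc)^2 + (sn[ih, 3] - zc)^2)))
  # lipid count conserved through the analysis
  expect_equal(sum(prof$n) / attr(prof, "n_snapshots"), sum(ih))
})

test_that("thinning series finds an imposed neck", {
  sys <- make_bare_sys()
  sn <- cylinder_snapshot(sys, r_inner = 3)
  # impose a neck at x ~ 6 nm: pull inner heads there to radius 1.2
  ih <- which(sys$class == "head" & sys$leaflet == "inner")
  near <- ih[abs(sn[ih, 1] - 6) < 2]
  yc <- sys$meta$axis_yz[1]; zc <- sys$meta$axis_yz[2]
  phi <- atan2(sn[near, 3] - zc, sn[near, 2] - yc)
  sn[near, 2] <- yc + 1.2 * cos(phi)
  sn[near, 3] <- zc + 1.2 * sin(phi)
  tr <- synthetic_traj(sys, list(sn, sn, sn))
  ts <- thinning_timeseries(tr, n_bins = 12)
  expect_true(all(abs(ts$x_thinning - 6) < 2.5))
  expect_lt(ts$r_thinning[1], 2)
  expect_gt(ts$r_middle[1], 2.5)
  expect_equal(ts$time_1e4tau, ts$time / 1e4)
})

test_that("scission detection flags an inserted axial gap and not an intact tube", {
  sys <- make_bare_sys()
  sn <- cylinder_snapshot(sys, r_inner = 3)
  tr <- synthetic_traj(sys, list(sn, sn))
  rec <- detect_scission(tr)
  expect_false(rec$fission)
  # push everything within a 3 nm band far away in x (a lipid-free gap)
  sn2 <- sn
  band <- sn2[, 1] > 10 & sn2[, 1] < 13 & !sys$frozen
  lips_in_band <- unique(sys$lipid_id[band])
  rows <- sys$lipid_id %in% lips_in_band
  sn2[rows, 1] <- (sn2[rows, 1] + 10) %% sys$box[1]
  sn2[rows, 1][sn2[rows, 1] > 10 & sn2[rows, 1] < 13.5] <- 14
  tr2 <- synthetic_traj(sys, list(sn, sn2, sn2))
  rec2 <- detect_scission(tr2)
  expect_true(rec2$fission)
  expect_equal(rec2$time, tr2$times[2])
  expect_gt(rec2$position, 9)
  expect_lt(rec2$position, 14)
  expect_false(is.na(rec2$pre_scission_radius))
  # monotone: later frames still satisfy the gap criterion
  expect_false(is.null(cgtubes:::.frame_gaps(sn2, sys)))
})

test_that("interleaflet mixing counts exactly the flipped lipids", {
  sys <- make_bare_sys()
  sn <- cylinder_snapshot(sys, r_inner = 3)
  n <- lipid_count(sys)
  # flip k inner lipids: place their head radially inside their body
  inner_heads <- which(sys$class == "head" & sys$leaflet == "inner")
  k <- 7
  yc <- sys$meta$axis_yz[1]; zc <- sys$meta$axis_yz[2]
  sn2 <- sn
  for (h in inner_heads[seq_len(k)]) {
    b <- h + 1 # body row of the same lipid
    phi <- atan2(sn2[b, 3] - zc, sn2[b, 2] - yc)
    rb <- sqrt((sn2[b, 2] - yc)^2 + (sn2[b, 3] - zc)^2)
    sn2[h, 2] <- yc + (rb + 0.8) * cos(phi)
    sn2[h, 3] <- zc + (rb + 0.8) * sin(phi)
  }
  tr <- synthetic_traj(sys, list(sn, sn2))
  mx <- interleaflet_mixing(tr)
  expect_equal(mx$fraction_mixed[1], 0)
  expect_equal(mx$fraction_mixed[2], k / n)
})
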