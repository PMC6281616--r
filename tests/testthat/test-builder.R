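test_that("tube construction reproduces the printed bookkeeping numbers", {
  sys <- build_tube(length = 100, outer_diameter = 20, lumen_diameter = 11,
                    n_lipids = 14500, seed = 1)
  # 14,500 lipids carry 43,500 CG sites
  expect_equal(nrow(sys$pos), 43500)
  expect_equal(lipid_count(sys), 14500)
  # 40 mol% DOPS
  expect_equal(sum(sys$species == "DOPS") / 3, 0.40 * 14500)
  # geometric area per lipid from the head radii
  expect_equal(sys$meta$apl_geometric,
               2 * pi * 100 * (10 + 5.5) / 14500, tolerance = 1e-12)
  expect_equal(round(sys$meta$apl_geometric, 2), 0.67)
  # box matches the stated full-scale dimensions
  expect_equal(sys$box, c(100, 50, 50))
})

test_that("leaflet counts follow mid-surface areas and seeds only scramble", {
  sys <- build_tube(length = 30, outer_diameter = 13.5, lumen_diameter = 5.5,
                    seed = 7)
  p <- sys$params
  span <- 2 * p$bond_r0
  r_om <- 13.5 / 2 - span / 2
  r_im <- 5.5 / 2 + span / 2
  n <- lipid_count(sys)
  n_out <- sum(sys$leaflet == "outer") / 3
  expect_lt(abs(n_out - n * r_om / (r_om + r_im)), 1 + 1e-9)
  # determinism and seed scrambling
  again <- build_tube(length = 30, outer_diameter = 13.5,
                      lumen_diameter = 5.5, seed = 7)
  expect_identical(sys$pos, again$pos)
  expect_identical(sys$species, again$species)
  other <- build_tube(length = 30, outer_diameter = 13.5,
                      lumen_diameter = 5.5, seed = 8)
  expect_false(identical(sys$species, other$species))
  expect_false(identical(sys$pos, other$pos))
  expect_equal(lipid_count(other), n)  # only placement/species change
})

test_that("built systems contain no overlapping initial condition", {
  sys <- build_tube(length = 30, outer_diameter = 13.5, lumen_diameter = 5.5,
                    seed = 3)
  md <- cgtubes:::.cg_min_dist(sys$pos,
                               ifelse(is.na(sys$lipid_id), NA_integer_,
                                      sys$lipid_id),
                               sys$box)
  # no pair inside ~60% of the smallest repulsive core diameter
  expect_gt(md, 0.45)
})

test_that("bare-tube series rescales lipid count with geometry", {
  series <- build_bare_tube_series(2:10, length = 30, thickness = 4,
                                   seed = 1)
  expect_length(series, 9)
  apls <- vapply(series, function(s) s$meta$apl_geometric, numeric(1))
  expect_lt(max(abs(apls - apls[1]) / apls[1]), 0.02)
  expect_error(build_bare_tube_series(0), "lumen")
  expect_error(build_tube(lumen_diameter = -2), "lumen")
})

test_that("ring spacing follows the chord formula", {
  # the printed scaffold geometry: 25 nm ring, 35 sites -> 2.24 nm
  expect_equal(round(ring_site_spacing(25, 35), 2), 2.24)
  # antipodal degenerate case
  expect_equal(ring_site_spacing(7.3, 2), 7.3)
  # four sites on a 25 nm ring
  expect_equal(ring_site_spacing(25, 4), 25 * sin(pi / 4), tolerance = 1e-12)
  expect_error(ring_site_spacing(25, 1), "sites_per_ring")
})

test_that("scaffold site counts match the printed 4 nm and 20 nm scaffolds", {
  s4 <- build_scaffold(4, axial_center = 50)
  s20 <- build_scaffold(20, axial_center = 50)
  expect_equal(nrow(s4$sites), 560)
  expect_equal(nrow(s20$sites), 2800)
  expect_equal(s4$n_rings, 16)
  # single-ring degenerate case
  s1 <- build_scaffold(0.25, axial_center = 10)
  expect_equal(nrow(s1$sites), 35)
  # all sites on the stated circle, adjacent spacing constant
  rr <- sqrt(s4$sites[, 2]^2 + s4$sites[, 3]^2)
  expect_lt(max(abs(rr - 12.5)), 1e-9)
  ring1 <- s4$sites[1:35, ]
  d <- sqrt(rowSums((ring1 - ring1[c(2:35, 1), ])^2))
  expect_lt(diff(range(d)), 1e-9)
  expect_error(build_scaffold(0.1), "ring_spacing")
})

test_that("place_scaffold appends frozen sites without touching lipids", {
  sys <- build_tube(length = 30, outer_diameter = 13.5, lumen_diameter = 5.5,
                    seed = 2)
  sc <- build_scaffold(3, ring_diameter = 17, axial_center = 15)
  sys2 <- place_scaffold(sys, sc)
  expect_equal(sum(sys2$frozen), nrow(sc$sites))
  expect_identical(sys2$pos[seq_len(nrow(sys$pos)), ], sys$pos)
  rr <- sqrt((sys2$pos[sys2$frozen, 2] - sys2$meta$axis_yz[1])^2 +
               (sys2$pos[sys2$frozen, 3] - sys2$meta$axis_yz[2])^2)
  expect_lt(max(abs(rr - 8.5)), 1e-9)
  # scaffold outside the box is rejected
  sc_far <- build_scaffold(3, ring_diameter = 17, axial_center = 40)
  expect_error(place_scaffold(sys, sc_far), "box")
  # ring must clear the outer tube radius
  sc_small <- build_scaffold(3, ring_diameter = 12, axial_center = 15)
  expect_error(place_scaffold(sys, sc_small), "exceed")
})

test_that("extended-XYZ snapshots round-trip", {
  sys <- suppressWarnings(
    build_tube(length = 20, outer_diameter = 13.5, lumen_diameter = 5.5,
               n_lipids = 300, seed = 2))
  f <- tempfile(fileext = ".xyz")
  write_xyz(sys, f)
  back <- read_xyz(f)
  expect_equal(back$pos, unname(sys$pos), tolerance = 1e-4)
  expect_equal(back$box, sys$box)
  expect_equal(back$class, sys$class)
  expect_equal(back$lipid_id, sys$lipid_id)
})

test_that("presets describe the full-scale and desk-scale systems", {
  pf <- preset("paper_full")
  expect_equal(pf$build$n_lipids, 14500)
  expect_equal(pf$protocol$prod_steps, 1e7)
  expect_equal(pf$protocol$dump_interval, 10000)
  ds <- preset("desk_small")
  expect_lt(ds$build$length, pf$build$length)
})
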