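test_that("protocol validation enforces the stated invariants", {
  expect_error(run_protocol(ramp_start = 400), "ramp_start")
  expect_error(run_protocol(prod_steps = 1e5, dump_interval = 3000), "divide")
  p <- run_protocol()
  expect_equal(p$equil_steps, 1e6)
  expect_equal(p$prod_steps, 1e7)
  expect_equal(p$damping, 100)
  expect_equal(p$dump_interval, 10000)
  expect_equal(p$temperature, 310)
})

test_that("equilibration ramps to temperature and leaves frozen sites fixed", {
  sys <- suppressWarnings(
    build_tube(length = 16, outer_diameter = 13.5, lumen_diameter = 5.5,
               n_lipids = 500, seed = 2, box_yz = 24))
  sc <- build_scaffold(1.5, ring_diameter = 17, axial_center = 8)
  sys <- place_scaffold(sys, sc)
  frozen_pos <- sys$pos[sys$frozen, ]
  prot <- desk_protocol(equil_steps = 6000, prod_steps = 0, seed = 5)
  sys2 <- equilibrate(sys, prot)
  expect_equal(sys2$pos[sys2$frozen, ], frozen_pos)
  expect_lt(abs(attr(sys2, "T_kin") - 310) / 310, 0.10)
  # zero equilibration steps is a no-op
  sys3 <- equilibrate(sys, desk_protocol(equil_steps = 0, prod_steps = 0))
  expect_identical(sys3$pos, sys$pos)
})

test_that("production holds temperature and keeps frozen sites fixed", {
  sys <- suppressWarnings(
    build_tube(length = 16, outer_diameter = 13.5, lumen_diameter = 5.5,
               n_lipids = 500, seed = 2, box_yz = 24))
  sc <- build_scaffold(1.5, ring_diameter = 17, axial_center = 8)
  sys <- place_scaffold(sys, sc)
  frozen_pos <- sys$pos[sys$frozen, ]
  prot <- desk_protocol(equil_steps = 8000, prod_steps = 20000,
                        dump_interval = 1000, seed = 5)
  sys2 <- equilibrate(sys, prot)
  tr <- run_nvt(sys2, prot)
  expect_equal(length(tr$snapshots), 20)
  expect_equal(tr$times, (1:20) * 1000)
  expect_lt(abs(mean(tr$T_kin) - 310) / 310, 0.03)
  expect_equal(tr$final$pos[sys$frozen, ], frozen_pos)
  # frozen displacement across every snapshot is exactly zero
  for (k in c(1, 10, 20))
    expect_equal(tr$snapshots[[k]][sys$frozen, ], unname(frozen_pos),
                 tolerance = 1e-12)
})

test_that("microcanonical runs conserve energy", {
  sys2 <- equilibrated_patch()
  # NVE consistency: integrate at a half step for the drift oracle
  prot <- run_protocol(timestep = 0.25, equil_steps = 0, prod_steps = 10000,
                       dump_interval = 250, seed = 3)
  tr <- run_nvt(sys2, prot, thermostat = FALSE)
  nf <- 3 * nrow(sys2$pos)
  ke <- tr$T_kin * nf * cgtubes:::.kB / 2
  etot <- tr$pe + ke
  expect_lt((max(etot) - min(etot)) / abs(mean(etot)), 1e-3)
})

test_that("replicated runs are deterministic per seed and scrambled across", {
  config <- list(
    build = list(length = 14, outer_diameter = 13.2, lumen_diameter = 5.4,
                 n_lipids = 420, box_yz = 22),
    protocol = list(equil_steps = 1500, prod_steps = 2000,
                    dump_interval = 1000, seed = 11))
  reps <- suppressWarnings(replicate_runs(config, n_replicas = 3))
  expect_length(reps, 3)
  # identical configuration and seed reproduce bit-identical output
  reps2 <- suppressWarnings(replicate_runs(config, n_replicas = 1))
  expect_identical(reps[[1]]$snapshots[[2]], reps2[[1]]$snapshots[[2]])
  # distinct replicas start from distinct coordinates
  expect_false(identical(reps[[1]]$system$pos, reps[[2]]$system$pos))
  expect_false(identical(reps[[2]]$snapshots[[1]], reps[[3]]$snapshots[[1]]))
})
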