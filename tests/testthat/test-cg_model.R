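test_that("lipid pair potential honours its cutoff and well-depth contract", {
  p <- lipid_params()
  sig <- p$sigma_tail
  rmin <- 2^(1/6) * sig
  rc <- rmin + p$w_att
  # zero at and beyond the cutoff
  expect_equal(lipid_pair_energy("tail", "tail", c(rc, rc + 0.5, 5), p),
               c(0, 0, 0))
  # tail-tail at the attractive-well minimum equals minus the well depth
  expect_equal(lipid_pair_energy("tail", "tail", rmin, p), -p$eps_att,
               tolerance = 1e-12)
  # head pairs are purely repulsive: zero outside their contact radius
  rmin_hh <- 2^(1/6) * sig * p$head_scale
  expect_equal(lipid_pair_energy("head", "head", rmin_hh * 1.001, p), 0)
  expect_gt(lipid_pair_energy("head", "head", 0.8 * rmin_hh, p), 0)
  # domain errors
  expect_error(lipid_pair_energy("tail", "tail", 0, p), "distance")
  expect_error(lipid_pair_energy("tail", "tail", -1, p), "distance")
})

test_that("pair energy equals the integral of minus the force", {
  p <- lipid_params()
  rc <- 2^(1/6) * p$sigma_tail + p$w_att
  for (d in c(0.55, 0.7, 0.85, 1.1, 1.5)) {
    e_direct <- lipid_pair_energy("tail", "tail", d, p)
    e_int <- -stats::integrate(function(r)
      lipid_pair_force("tail", "tail", r, p), rc, d,
      rel.tol = 1e-10)$value
    expect_equal(e_direct, e_int, tolerance = 1e-6)
  }
})

test_that("force is minus the numerical derivative of energy everywhere", {
  p <- lipid_params()
  h <- 1e-6
  for (pair in list(c("tail", "tail"), c("head", "tail"), c("head", "head"),
                    c("body", "tail"))) {
    sig <- cgtubes:::.pair_sigma(p, pair[1], pair[2])
    rmin <- 2^(1/6) * sig
    rc <- if (cgtubes:::.pair_is_attractive(pair[1], pair[2]))
      rmin + p$w_att else rmin
    rs <- setdiff(seq(0.3, rc, length.out = 40), NA)
    rs <- rs[abs(rs - rmin) > 0.005]     # force kink is C0, not C1
    de <- (lipid_pair_energy(pair[1], pair[2], rs + h, p) -
             lipid_pair_energy(pair[1], pair[2], rs - h, p)) / (2 * h)
    f <- lipid_pair_force(pair[1], pair[2], rs, p)
    expect_lt(max(abs(f + de) / pmax(abs(f), 1)), 1e-5)
  }
})

test_that("protein-lipid LJ reproduces its printed parameter contract", {
  pot <- protein_lipid_potential()
  expect_equal(pot$sigma, 0.2)
  expect_equal(pot$epsilon, 1.0)
  # zero crossing at sigma, minimum -epsilon at 2^(1/6) sigma (unshifted)
  expect_equal(protein_lipid_energy(0.2, pot, shifted = FALSE), 0,
               tolerance = 1e-12)
  expect_equal(protein_lipid_energy(2^(1/6) * 0.2, pot, shifted = FALSE), -1,
               tolerance = 1e-12)
  # direct evaluation of the 12-6 form at r = 0.3 nm
  expect_equal(round(protein_lipid_energy(0.3, pot, shifted = FALSE), 3),
               -0.320)
  # shifted form is exactly zero at and beyond the cutoff
  expect_equal(protein_lipid_energy(c(pot$cutoff, 1), pot), c(0, 0))
  expect_error(protein_lipid_energy(0, pot), "distance")
})

test_that("R-level potentials agree with the engine energy on a dimer grid", {
  p <- lipid_params()
  pot <- protein_lipid_potential()
  # two isolated lipids at controlled separation: engine total energy
  # minus bonded terms equals the sum of R-level pair energies
  mk <- function(d) {
    pos <- rbind(c(5, 5, 5 + 2 * p$bond_r0), c(5, 5, 5 + p$bond_r0),
                 c(5, 5, 5),
                 c(5 + d, 5, 5 + 2 * p$bond_r0), c(5 + d, 5, 5 + p$bond_r0),
                 c(5 + d, 5, 5))
    sys <- cgtubes:::.new_system(pos, 2, leaflet = c("outer", "outer"),
                                 species = c("DOPC", "DOPC"),
                                 box = c(12, 10, 10), params = p, pot = pot)
    sys
  }
  for (d in c(0.7, 0.9, 1.2, 1.6)) {
    sys <- mk(d)
    e_engine <- cgtubes:::.cg_energy(cgtubes:::.engine_sys(sys),
                                     cgtubes:::.pair_table(p, pot))
    cls <- c("head", "body", "tail")
    e_ref <- 0
    for (a in 1:3) for (b in 1:3) {
      dd <- sqrt(d^2 + (abs(a - b) * p$bond_r0)^2)
      e_ref <- e_ref + lipid_pair_energy(cls[a], cls[b], dd, p)
    }
    expect_equal(e_engine, e_ref, tolerance = 1e-4)
  }
})

test_that("force-field files round-trip", {
  p <- lipid_params(eps_att = 1.23, w_att = 0.8)
  pot <- protein_lipid_potential(cutoff = 0.6)
  f <- tempfile(fileext = ".yaml")
  write_forcefield(f, p, pot)
  ff <- read_forcefield(f)
  expect_equal(ff$params$eps_att, 1.23)
  expect_equal(ff$params$w_att, 0.8)
  expect_equal(ff$pot$cutoff, 0.6)
})

test_that("a planar patch holds together as a fluid bilayer at 310 K", {
  p <- lipid_params()
  sys <- build_planar_patch(n_side = 10, seed = 4, params = p)
  expect_equal(sys$meta$apl_geometric, 0.67, tolerance = 0.2 * 0.67)
  prot <- desk_protocol(equil_steps = 8000, prod_steps = 5e4,
                        dump_interval = 5000, seed = 5)
  sys2 <- equilibrate(sys, prot)
  tr <- run_nvt(sys2, prot)
  sn <- tr$snapshots[[length(tr$snapshots)]]
  heads <- sys$class == "head"
  up <- heads & sys$leaflet == "outer"
  dn <- heads & sys$leaflet == "inner"
  tails <- sys$class == "tail"
  # recentre: the patch is free to drift across the periodic z boundary
  z <- recenter_z(sn[, 3], sys$box[3], ref = sn[tails, 3])
  # |z| spread of head sites bounded: no dissolution
  expect_lt(max(sd(z[up]), sd(z[dn])), 1.2)
  zc <- sys$box[3] / 2
  expect_lt(mean(abs(z[tails] - zc) > 2.8), 0.02)
  # thickness (head planes plus head-bead diameter) near the 5 nm target
  thick <- abs(mean(z[up]) - mean(z[dn])) + p$sigma_tail * p$head_scale
  expect_gt(thick, 0.8 * p$target_thickness)
  expect_lt(thick, 1.2 * p$target_thickness)
})
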