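# small shared fixtures, built in code at test time

small_patch <- function(seed = 2, n_side = 8) {
  build_planar_patch(n_side = n_side, seed = seed)
}

# an equilibrated desk patch, cached per session
equilibrated_patch <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prot <- desk_protocol(equil_steps = 8000, prod_steps = 0, seed = 3)
      cache <<- equilibrate(small_patch(), prot)
    }
    cache
  }
})

# a rigid synthetic "trajectory" wrapping hand-built snapshots around a
# bare-tube system, for analysis oracles
synthetic_traj <- function(sys, snapshots, dt_dump = 1000) {
  tr <- list(snapshots = snapshots,
             times = seq_along(snapshots) * dt_dump,
             T_kin = rep(310, length(snapshots)),
             pe = rep(NA_real_, length(snapshots)),
             system = sys, final = sys,
             protocol = run_protocol(equil_steps = 0, prod_steps = 0,
                                     dump_interval = dt_dump),
             stopped_on_gap = FALSE, stop_step = NA_integer_,
             gap_x = NA_real_,
             provenance = list(seed = 0, replica = 1, config_hash = "test"))
  class(tr) <- "cg_trajectory"
  tr
}

# noise-free cylinder snapshot rebuilt from scratch: each leaflet a
# uniform ring set (angles sum exactly to zero, so the lipid centre of
# mass sits exactly on the axis), heads exactly at the given radii,
# x positions jittered off any lattice
cylinder_snapshot <- function(sys, r_inner, r_outer = r_inner + 4) {
  set.seed(99)
  sn <- sys$pos
  yc <- sys$meta$axis_yz[1]; zc <- sys$meta$axis_yz[2]
  Lx <- sys$box[1]
  for (leaf in c("inner", "outer")) {
    heads <- which(sys$class == "head" & sys$leaflet %in% leaf)
    n <- length(heads)
    phi <- 2 * pi * (seq_len(n) - 1) / n
    x <- (seq_len(n) - 0.5) * Lx / n + runif(n, -0.2, 0.2)
    sgn <- if (leaf == "inner") 1 else -1
    rh <- if (leaf == "inner") r_inner else r_outer
    for (k in 0:2) {       # head, body, tail rows
      rr <- rh + sgn * 0.9 * k
      rows <- heads + k
      sn[rows, 1] <- x %% Lx
      sn[rows, 2] <- yc + rr * cos(phi)
      sn[rows, 3] <- zc + rr * sin(phi)
    }
  }
  sn
}

# recentre periodic coordinates so the structure is contiguous: circular
# mean of the reference rows becomes the box centre
recenter_z <- function(z, Lz, ref = z) {
  ang <- 2 * pi * ref / Lz
  zc <- atan2(mean(sin(ang)), mean(cos(ang))) * Lz / (2 * pi)
  (z - zc + Lz / 2) %% Lz
}
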