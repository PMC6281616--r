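#' Run protocol for equilibration and production dynamics
#'
#' Describes a complete run: an equilibration ramp in which the
#' thermostat target climbs linearly from `ramp_start` to `ramp_end`,
#' followed by NVT production at `temperature`.  Times are in the native
#' CG unit tau; the integrator step is 1 tau by default.  The full-scale
#' protocol uses a 1.0e6-step ramp from 10 K to 310 K, 1.0e7 production
#' steps at 310 K with thermostat damping 100 tau, and a trajectory dump
#' every 10,000 tau.
#'
#' @param timestep integrator step, tau.
#' @param equil_steps equilibration (ramp) steps.
#' @param ramp_start,ramp_end thermostat target at the start and end of
#'   the ramp, K.
#' @param prod_steps production steps.
#' @param temperature production thermostat target, K.
#' @param damping thermostat damping time, tau.
#' @param dump_interval trajectory dump interval, tau (must divide
#'   `prod_steps * timestep`).
#' @param seed seed for the initial velocity draw.
#' @param replica replica index (bookkeeping; see [replicate_runs()]).
#' @param ramp_timestep also ramp the integrator step alongside the
#'   temperature during equilibration (from `timestep/10` to `timestep`).
#' @return An object of class `run_protocol`.
#' @export
run_protocol <- function(timestep = 1, equil_steps = 1e6,
                         ramp_start = 10, ramp_end = 310,
                         prod_steps = 1e7, temperature = 310,
                         damping = 100, dump_interval = 10000,
                         seed = 1, replica = 1, ramp_timestep = FALSE) {
  stopifnot(timestep > 0, equil_steps >= 0, prod_steps >= 0,
            ramp_start < ramp_end, damping > 0, dump_interval > 0)
  if (prod_steps > 0 && (prod_steps * timestep) %% dump_interval != 0)
    stop("dump_interval must divide the production time")
  p <- list(timestep = timestep, equil_steps = equil_steps,
            ramp_start = ramp_start, ramp_end = ramp_end,
            prod_steps = prod_steps, temperature = temperature,
            damping = damping, dump_interval = dump_interval,
            seed = seed, replica = replica, ramp_timestep = ramp_timestep)
  class(p) <- "run_protocol"
  p
}

#' @export
print.run_protocol <- function(x, ...) {
  cat(sprintf(
    "run_protocol: ramp %g K -> %g K over %g steps; %g production steps at %g K\n",
    x$ramp_start, x$ramp_end, x$equil_steps, x$prod_steps, x$temperature))
  cat(sprintf("  dt %g tau, damping %g tau, dump every %g tau, seed %d replica %d\n",
              x$timestep, x$damping, x$dump_interval, x$seed, x$replica))
  invisible(x)
}

#' Desk-scale run protocol
#'
#' The scaled-down protocol used for test-bench runs: an 8e3-step ramp
#' and 2.5e4-step production with dumps every 1000 tau, with the same
#' thermostat settings as the full-scale protocol.  These sizes keep a
#' replicated desk study (several tubes, three seeds) within tens of
#' minutes on one CPU.
#'
#' @param ... overrides passed to [run_protocol()].
#' @return A `run_protocol`.
#' @export
desk_protocol <- function(...) {
  args <- modifyList(list(equil_steps = 8e3, prod_steps = 2.5e4,
                          dump_interval = 1000), list(...))
  do.call(run_protocol, args)
}

# engine-facing views -------------------------------------------------------

.engine_type_id <- function(system) {
  id <- integer(nrow(system$pos))
  head <- system$class == "head"
  id[head & system$species %in% "DOPS"] <- 1L
  id[head & !(system$species %in% "DOPS")] <- 0L
  id[system$class == "body"] <- 2L
  id[system$class == "tail"] <- 3L
  id[system$class == "protein"] <- 4L
  id
}

.bond_table <- function(system) {
  lip <- unique(system$lipid_id[!is.na(system$lipid_id)])
  # sites are laid out head, body, tail per lipid in construction order
  first <- match(lip, system$lipid_id)
  p <- system$params
  h <- first - 1L          # 0-based head index
  rbind(cbind(h, h + 1L, p$bond_k, p$bond_r0),
        cbind(h + 1L, h + 2L, p$bond_k, p$bond_r0),
        cbind(h, h + 2L, p$bend_k, 2 * p$bond_r0))
}

.engine_sys <- function(system) {
  list(pos = system$pos, vel = system$vel,
       type_id = .engine_type_id(system),
       frozen_i = as.integer(system$frozen),
       lipid_i = ifelse(is.na(system$lipid_id), -1L,
                        as.integer(system$lipid_id)),
       box = system$box,
       bond_tab = .bond_table(system))
}

.engine_ctl <- function(protocol, n_steps, T_start, T_end, dump_every,
                        thermostat = TRUE, stop_on_gap = FALSE,
                        gap_width = 1.5, check_every = 1000,
                        chain = NULL, dt_internal = NULL) {
  dt <- if (is.null(dt_internal)) protocol$timestep * .tau_internal else dt_internal
  ctl <- list(dt = dt, n_steps = as.integer(n_steps),
              dump_every = as.integer(dump_every), kB = .kB,
              T_start = T_start, T_end = T_end,
              damping = protocol$damping * .tau_internal,
              thermostat = as.integer(thermostat), stop_on_gap = stop_on_gap,
              gap_width = gap_width, check_every = as.integer(check_every),
              velocity_guard = 100)
  if (!is.null(chain)) ctl$chain <- chain
  ctl
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Assigns random velocities to all mobile sites at the given
#' temperature with zero net momentum; frozen sites keep zero velocity.
#'
#' @param system a `cg_system`.
#' @param temperature K.
#' @param seed RNG seed.
#' @return The system with velocities set.
#' @export
init_velocities <- function(system, temperature, seed = 1) {
  set.seed(seed)
  n <- nrow(system$pos)
  v <- matrix(rnorm(3 * n, sd = sqrt(.kB * temperature)), n, 3)
  mob <- !system$frozen
  v[mob, ] <- sweep(v[mob, , drop = FALSE], 2,
                    colMeans(v[mob, , drop = FALSE]))
  v[!mob, ] <- 0
  system$vel <- v
  system
}

#' Equilibrate a system with a temperature ramp
#'
#' Runs the equilibration leg of the protocol: velocities are drawn at
#' the ramp-start temperature and the Nose-Hoover target climbs linearly
#' to the ramp end.  Frozen scaffold sites do not move.  With zero
#' equilibration steps the system is returned unchanged.
#'
#' @param system a `cg_system`.
#' @param protocol a [run_protocol()].
#' @param minimize_iter displacement-capped quench iterations applied to
#'   the built lattice before the thermal ramp (0 to skip).
#' @return The equilibrated system, with attributes `T_kin` (final
#'   kinetic temperature, K) and `chain` (thermostat chain state).
#' @export
equilibrate <- function(system, protocol = run_protocol(),
                        minimize_iter = 500) {
  if (protocol$equil_steps == 0) return(system)
  ff <- .pair_table(system$params, system$pot)
  if (minimize_iter > 0) {
    mn <- .cg_minimize(.engine_sys(system), ff, as.integer(minimize_iter),
                       0.02)
    system$pos <- mn$pos
  }
  system <- init_velocities(system, protocol$ramp_start,
                            seed = protocol$seed + 1000 * protocol$replica)
  esys <- .engine_sys(system)
  # the ramp integrates with a timestep that climbs alongside the
  # temperature: freshly built lattices host stiff contacts that relax
  # during the early ramp and would be unstable at the production step
  segs_dt <- if (isTRUE(protocol$ramp_timestep)) c(0.1, 0.25, 0.5, 0.75, 1)
             else c(0.25, 0.25, 0.5, 0.75, 1)
  segs <- length(segs_dt)
  dt_full <- protocol$timestep * .tau_internal
  Ts <- seq(protocol$ramp_start, protocol$ramp_end, length.out = segs + 1)
  for (s in seq_len(segs)) {
    ctl <- .engine_ctl(protocol, round(protocol$equil_steps / segs),
                       Ts[s], Ts[s + 1], dump_every = 0,
                       thermostat = 2L,
                       dt_internal = dt_full * segs_dt[s])
    out <- .cg_md_run(esys, ff, ctl)
    esys$pos <- out$pos
    esys$vel <- out$vel
  }
  if (isTRUE(out$diverged))
    stop("equilibration diverged: site velocity exceeded the guard")
  system$pos <- out$pos
  system$vel <- out$vel
  attr(system, "T_kin") <- out$T_kin
  attr(system, "chain") <- out$chain
  system
}

#' Run production NVT dynamics
#'
#' Integrates the system at the protocol's production temperature with a
#' Nose-Hoover chain thermostat (chain length 3, damping 100 tau by
#' default), dumping a snapshot every `dump_interval` tau.  Runs are
#' bit-reproducible for a given built and equilibrated system.
#'
#' @param system an equilibrated `cg_system`.
#' @param protocol a [run_protocol()].
#' @param thermostat set `FALSE` for a microcanonical (NVE) check run.
#' @param stop_on_scission stop integration early when an axial window
#'   empties of hydrophobic sites (a scission guard used by long scans;
#'   the definitive call is made by [detect_scission()]).
#' @return An object of class `cg_trajectory`: snapshot list, timestamps
#'   (tau), per-snapshot kinetic temperature and potential energy, the
#'   system metadata, and run provenance.
#' @export
run_nvt <- function(system, protocol = run_protocol(), thermostat = TRUE,
                    stop_on_scission = FALSE) {
  esys <- .engine_sys(system)
  dump_every <- max(1L, round(protocol$dump_interval / protocol$timestep))
  ctl <- .engine_ctl(protocol, protocol$prod_steps,
                     protocol$temperature, protocol$temperature,
                     dump_every = dump_every,
                     thermostat = thermostat,
                     stop_on_gap = stop_on_scission,
                     chain = attr(system, "chain"))
  out <- .cg_md_run(esys, .pair_table(system$params, system$pot), ctl)
  if (isTRUE(out$diverged))
    stop("dynamics diverged at step ", out$stop_step,
         "; last good snapshot retained in the return value")
  final <- system
  final$pos <- out$pos
  final$vel <- out$vel
  attr(final, "chain") <- out$chain
  traj <- list(
    snapshots = out$snapshots,
    times = out$snap_step * protocol$timestep,
    T_kin = out$snap_T,
    pe = out$snap_pe,
    system = system,
    final = final,
    protocol = protocol,
    stopped_on_gap = isTRUE(out$stopped_on_gap),
    stop_step = if (out$stop_step > 0) out$stop_step else NA_integer_,
    gap_x = out$gap_x,
    provenance = list(seed = protocol$seed, replica = protocol$replica,
                      config_hash = .config_hash(system, protocol)))
  class(traj) <- "cg_trajectory"
  traj
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d snapshots, %d sites, t = %s tau\n",
              length(x$snapshots), nrow(x$system$pos),
              if (length(x$times)) format(max(x$times), big.mark = ",") else "0"))
  cat(sprintf("  mean kinetic T %.1f K; seed %d replica %d\n",
              mean(x$T_kin), x$provenance$seed, x$provenance$replica))
  if (x$stopped_on_gap)
    cat(sprintf("  stopped early on axial gap at step %d (x ~ %.1f nm)\n",
                x$stop_step, x$gap_x))
  invisible(x)
}

.config_hash <- function(system, protocol) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(params = system$params, pot = system$pot,
               meta = system$meta, protocol = unclass(protocol)), f)
  unname(tools::md5sum(f))
}

#' Run replicated simulations
#'
#' Builds, equilibrates and runs `n_replicas` independent copies of a
#' system.  Replicas differ only in the seed used to scramble the
#' initial condition (species assignment, placement jitter and the
#' velocity draw).
#'
#' @param config a list with elements `build` (arguments for
#'   [build_tube()]), optional `scaffold` (arguments for
#'   [build_scaffold()], placed with [place_scaffold()]) and `protocol`
#'   (arguments for [run_protocol()]).
#' @param n_replicas number of replicas (>= 1).
#' @param stop_on_scission passed to [run_nvt()].
#' @return A list of `cg_trajectory` objects.
#' @export
replicate_runs <- function(config, n_replicas = 3, stop_on_scission = FALSE) {
  stopifnot(n_replicas >= 1)
  base_seed <- config$protocol$seed %||% 1
  lapply(seq_len(n_replicas), function(k) {
    bargs <- config$build
    bargs$seed <- (bargs$seed %||% base_seed) + 7919L * (k - 1L)
    sys <- do.call(build_tube, bargs)
    if (!is.null(config$scaffold)) {
      sc <- do.call(build_scaffold, config$scaffold)
      sys <- place_scaffold(sys, sc)
    }
    pargs <- config$protocol %||% list()
    pargs$seed <- base_seed + 104729L * (k - 1L)
    pargs$replica <- k
    prot <- do.call(run_protocol, pargs)
    sys <- equilibrate(sys, prot)
    run_nvt(sys, prot, stop_on_scission = stop_on_scission)
  })
}
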