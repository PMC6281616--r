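# classify each lipid's leaflet from the instantaneous geometry: sign of
# the radial component of head minus body (prior label kept in the
# +-0.05 nm dead zone).  Returns a character vector over lipids.
.frame_leaflets <- function(sys, sn, yc, zc, prior) {
  heads <- which(sys$class == "head")
  bodies <- heads + 1L
  hy <- sn[bodies, 2] - yc; hz <- sn[bodies, 3] - zc
  rr <- sqrt(hy^2 + hz^2)
  ur_y <- ifelse(rr > 0, hy / rr, 0)
  ur_z <- ifelse(rr > 0, hz / rr, 0)
  comp <- (sn[heads, 2] - sn[bodies, 2]) * ur_y +
    (sn[heads, 3] - sn[bodies, 3]) * ur_z
  ifelse(comp > 0.05, "outer", ifelse(comp < -0.05, "inner", prior))
}

#' Axially binned lumen-radius profile
#'
#' For each snapshot in the window, the tube axis is taken as the line
#' along x through the centre of mass of all lipid sites, and the lumen
#' radius in each axial bin is the mean radial distance of inner-leaflet
#' head sites from that axis.  The profile reports the mean and variance
#' over the snapshot window (the last 20 dumped snapshots by default,
#' matching how simulation profiles are averaged).
#'
#' @param traj a `cg_trajectory` from [run_nvt()].
#' @param n_bins number of axial bins; default one bin per nm of tube.
#' @param snapshot_window indices of snapshots to average (default the
#'   last 20, or all if fewer).
#' @return A `lumen_profile`: data frame with `x` (bin centre, nm),
#'   `radius` (nm), `variance` (nm^2), `n` (site count); empty bins carry
#'   `NA` radius.  Scaffold boundaries, if any, are in
#'   `attr(, "scaffold_bounds")`.
#' @export
lumen_radius_profile <- function(traj, n_bins = NULL,
                                 snapshot_window = NULL) {
  sys <- traj$system
  Lx <- sys$box[1]
  if (is.null(n_bins)) n_bins <- max(10L, round(Lx))
  ns <- length(traj$snapshots)
  if (ns == 0) stop("trajectory has no snapshots")
  if (is.null(snapshot_window))
    snapshot_window <- seq.int(max(1L, ns - 19L), ns)
  heads <- which(sys$class == "head")
  lip <- !sys$frozen
  prior <- sys$leaflet[heads]
  edges <- seq(0, Lx, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  acc <- matrix(NA_real_, length(snapshot_window), n_bins)
  cnt <- matrix(0L, length(snapshot_window), n_bins)
  for (k in seq_along(snapshot_window)) {
    sn <- traj$snapshots[[snapshot_window[k]]]
    yc <- mean(sn[lip, 2])
    zc <- mean(sn[lip, 3])
    lab <- .frame_leaflets(sys, sn, yc, zc, prior)
    prior <- lab
    ih <- heads[lab == "inner"]
    r <- sqrt((sn[ih, 2] - yc)^2 + (sn[ih, 3] - zc)^2)
    b <- pmin(n_bins, pmax(1L, findInterval(sn[ih, 1], edges,
                                            rightmost.closed = TRUE)))
    acc[k, ] <- vapply(seq_len(n_bins), function(j) {
      v <- r[b == j]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    cnt[k, ] <- tabulate(b, n_bins)
  }
  prof <- data.frame(
    x = centers,
    radius = colMeans(acc, na.rm = TRUE),
    variance = apply(acc, 2, var, na.rm = TRUE),
    n = colSums(cnt))
  prof$radius[prof$n == 0] <- NA_real_
  attr(prof, "n_heads") <- length(heads)
  attr(prof, "n_snapshots") <- length(snapshot_window)
  attr(prof, "scaffold_bounds") <- sys$meta$scaffold_bounds
  class(prof) <- c("lumen_profile", "data.frame")
  prof
}

#' @export
print.lumen_profile <- function(x, ...) {
  cat(sprintf("lumen_profile: %d bins, %d snapshots; radius %.2f-%.2f nm\n",
              nrow(x), attr(x, "n_snapshots"),
              min(x$radius, na.rm = TRUE), max(x$radius, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.lumen_profile <- function(x, ...) {
  graphics::plot(x$x, x$radius, type = "l", xlab = "axial position (nm)",
                 ylab = "lumen radius (nm)", ...)
  v <- sqrt(x$variance)
  graphics::polygon(c(x$x, rev(x$x)),
                    c(x$radius - v, rev(x$radius + v)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$x, x$radius)
  sb <- attr(x, "scaffold_bounds")
  if (!is.null(sb)) graphics::abline(v = sb, col = "grey40", lty = 2)
  invisible(x)
}

#' Lumen-radius time series at the middle and at maximum thinning
#'
#' Tracks the lumen radius per snapshot at the tube middle (under a
#' centred scaffold) and at the axial bin with the smallest radius
#' outside the scaffold boundaries.  Snapshots after scission are
#' reported as `NA` and flagged.
#'
#' @param traj a `cg_trajectory`.
#' @param n_bins axial bins (default one per nm).
#' @return A data frame with `time` (tau), `time_1e4tau` (time in units
#'   of 10,000 tau), `r_middle`, `r_thinning` (nm), `post_scission`
#'   (logical), and the thinning-site position `x_thinning` (nm).
#' @export
thinning_timeseries <- function(traj, n_bins = NULL) {
  sys <- traj$system
  Lx <- sys$box[1]
  if (is.null(n_bins)) n_bins <- max(10L, round(Lx))
  ns <- length(traj$snapshots)
  heads <- which(sys$class == "head")
  prior <- sys$leaflet[heads]
  lip <- !sys$frozen
  edges <- seq(0, Lx, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  sb <- sys$meta$scaffold_bounds
  inside <- if (!is.null(sb)) centers >= sb[1] & centers <= sb[2]
            else rep(FALSE, n_bins)
  fis <- detect_scission(traj)
  out <- data.frame(time = traj$times,
                    time_1e4tau = traj$times / 1e4,
                    r_middle = NA_real_, r_thinning = NA_real_,
                    x_thinning = NA_real_,
                    post_scission = FALSE)
  mid_bin <- findInterval(Lx / 2, edges, rightmost.closed = TRUE)
  for (k in seq_len(ns)) {
    if (fis$fission && traj$times[k] >= fis$time) {
      out$post_scission[k] <- TRUE
      next
    }
    sn <- traj$snapshots[[k]]
    yc <- mean(sn[lip, 2]); zc <- mean(sn[lip, 3])
    lab <- .frame_leaflets(sys, sn, yc, zc, prior)
    prior <- lab
    ih <- heads[lab == "inner"]
    r <- sqrt((sn[ih, 2] - yc)^2 + (sn[ih, 3] - zc)^2)
    b <- pmin(n_bins, pmax(1L, findInterval(sn[ih, 1], edges,
                                            rightmost.closed = TRUE)))
    rb <- vapply(seq_len(n_bins), function(j) {
      v <- r[b == j]; if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    out$r_middle[k] <- rb[mid_bin]
    cand <- which(!inside & !is.na(rb))
    if (length(cand)) {
      jm <- cand[which.min(rb[cand])]
      out$r_thinning[k] <- rb[jm]
      out$x_thinning[k] <- centers[jm]
    }
  }
  attr(out, "fission") <- fis
  out
}

# hydrophobic axial occupancy gap / contact test for one frame.
# Returns NULL if the bilayer spans every axial plane, otherwise the
# axial positions (nm) where it is severed.
.frame_gaps <- function(sn, sys, bin = 0.5, contact = 1.2) {
  Lx <- sys$box[1]
  hyd <- sys$class %in% c("body", "tail")
  x <- sn[hyd, 1] %% Lx
  nb <- max(8L, floor(Lx / bin))
  occ <- tabulate(pmin(nb, pmax(1L, floor(x / Lx * nb) + 1L)), nb)
  med <- stats::median(occ)
  gaps <- numeric(0)
  centers <- (seq_len(nb) - 0.5) * Lx / nb
  for (j in seq_len(nb)) {
    if (occ[j] == 0) {
      gaps <- c(gaps, centers[j])
    } else if (occ[j] < 0.25 * med) {
      # sparse window: check for a genuine straddling hydrophobic contact
      x0 <- centers[j]
      d <- (x - x0 + Lx / 2) %% Lx - Lx / 2
      left <- which(d < 0 & d > -contact)
      right <- which(d >= 0 & d < contact)
      if (length(left) == 0 || length(right) == 0) {
        gaps <- c(gaps, x0)
        next
      }
      pl <- sn[hyd, , drop = FALSE][left, , drop = FALSE]
      pr <- sn[hyd, , drop = FALSE][right, , drop = FALSE]
      ok <- FALSE
      for (a in seq_len(nrow(pl))) {
        dd <- sweep(pr, 2, pl[a, ])
        for (q in 1:3) dd[, q] <- dd[, q] - sys$box[q] * round(dd[, q] / sys$box[q])
        if (any(rowSums(dd^2) < contact^2)) { ok <- TRUE; break }
      }
      if (!ok) gaps <- c(gaps, x0)
    }
  }
  if (length(gaps)) gaps else NULL
}

#' Detect membrane scission in a trajectory
#'
#' Scission is called at the first snapshot in which some axial plane is
#' no longer spanned by a continuous hydrophobic body: either an axial
#' window holds no body/tail sites at all, or a sparse window holds no
#' hydrophobic contact pair straddling the plane.  The record carries
#' the time and axial position of the first cut and the lumen radius
#' near the cut in the last intact snapshot.
#'
#' @param traj a `cg_trajectory`.
#' @param contact hydrophobic contact distance, nm.
#' @return A `sim_fission_record`: list with `fission` (flag), `time`
#'   (tau), `position` (nm), `pre_scission_radius` (nm), and
#'   `all_positions` for multi-site scission.
#' @export
detect_scission <- function(traj, contact = 1.2) {
  sys <- traj$system
  rec <- list(fission = FALSE, time = NA_real_, position = NA_real_,
              pre_scission_radius = NA_real_, all_positions = NULL)
  class(rec) <- "sim_fission_record"
  ns <- length(traj$snapshots)
  for (k in seq_len(ns)) {
    gaps <- .frame_gaps(traj$snapshots[[k]], sys, contact = contact)
    if (!is.null(gaps)) {
      rec$fission <- TRUE
      rec$time <- traj$times[k]
      rec$position <- min(gaps)
      rec$all_positions <- gaps
      if (k > 1) {
        sn <- traj$snapshots[[k - 1]]
        lip <- !sys$frozen
        yc <- mean(sn[lip, 2]); zc <- mean(sn[lip, 3])
        heads <- which(sys$class == "head")
        lab <- .frame_leaflets(sys, sn, yc, zc, sys$leaflet[heads])
        ih <- heads[lab == "inner"]
        dx <- (sn[ih, 1] - rec$position + sys$box[1] / 2) %% sys$box[1] -
          sys$box[1] / 2
        near <- abs(dx) < 2.5
        if (any(near)) {
          r <- sqrt((sn[ih, 2][near] - yc)^2 + (sn[ih, 3][near] - zc)^2)
          rec$pre_scission_radius <- mean(r)
        }
      }
      break
    }
  }
  # engine early-stop information supplements frame evidence
  if (!rec$fission && isTRUE(traj$stopped_on_gap)) {
    rec$fission <- TRUE
    rec$time <- traj$stop_step * traj$protocol$timestep
    rec$position <- traj$gap_x
  }
  rec
}

#' @export
print.sim_fission_record <- function(x, ...) {
  if (x$fission)
    cat(sprintf(
      "scission at t = %s tau, x = %.1f nm (pre-scission lumen radius %.2f nm)\n",
      format(x$time, big.mark = ","), x$position, x$pre_scission_radius))
  else cat("no scission detected\n")
  invisible(x)
}

#' Interleaflet mixing over a trajectory
#'
#' Reassigns every lipid's leaflet per snapshot from the sign of the
#' radial component of its head-minus-body vector (relative to the
#' instantaneous tube axis); lipids with |radial component| < 0.05 nm
#' keep their previous label.  Reports the fraction of lipids whose
#' assignment differs from the built labels.
#'
#' @param traj a `cg_trajectory`.
#' @return A data frame with `time` (tau) and `fraction_mixed`.
#' @export
interleaflet_mixing <- function(traj) {
  sys <- traj$system
  lip_rows <- which(!sys$frozen)
  heads <- which(sys$class == "head")
  bodies <- which(sys$class == "body")
  lab0 <- sys$leaflet[heads]
  prev <- lab0
  ns <- length(traj$snapshots)
  frac <- numeric(ns)
  for (k in seq_len(ns)) {
    sn <- traj$snapshots[[k]]
    yc <- mean(sn[lip_rows, 2]); zc <- mean(sn[lip_rows, 3])
    cur <- .frame_leaflets(traj$system, sn, yc, zc, prev)
    frac[k] <- mean(cur != lab0)
    prev <- cur
  }
  data.frame(time = traj$times, fraction_mixed = frac)
}

#' Export a profile or series as CSV with provenance header
#'
#' @param x a data frame (e.g. a `lumen_profile`).
#' @param path output file.
#' @param provenance optional named list written as `# key: value`
#'   comment lines before the table.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    for (nm in names(provenance))
      writeLines(sprintf("# %s: %s", nm, provenance[[nm]]), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}
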