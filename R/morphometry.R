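#' Background-correct an image
#'
#' Subtracts the median intensity of a user-designated empty region (or
#' a constant) from every pixel.
#'
#' @param img image matrix.
#' @param background either a constant, or a rectangle
#'   `list(x = c(x0, x1), y = c(y0, y1))` in pixel indices designating an
#'   empty region whose median is used.
#' @return The corrected image (attributes preserved).
#' @export
background_correct <- function(img, background) {
  b <- if (is.list(background)) {
    stats::median(img[background$y[1]:background$y[2],
                      background$x[1]:background$x[2]])
  } else background
  out <- img - b
  attributes(out) <- attributes(img)
  out
}

.roi_id <- function(img, roi) {
  sum(img[roi$y[1]:roi$y[2], roi$x[1]:roi$x[2]])
}

.roi_area_nm2 <- function(img, roi) {
  px <- attr(img, "pixel_size")
  (roi$y[2] - roi$y[1] + 1) * (roi$x[2] - roi$x[1] + 1) * px^2
}

#' Calibrate the intensity-per-area slope k1
#'
#' Integrated fluorescence densities (IDs) of ROIs of different sizes on
#' a background-corrected supported-bilayer image are regressed against
#' the ROI areas; k1 is the slope of the least-squares line through the
#' origin.
#'
#' @param slb_image background-corrected SLB image (with `pixel_size`
#'   attribute).
#' @param rois list of >= 3 rectangles `list(x = c(x0, x1), y = c(y0,
#'   y1))` (pixel indices) of different sizes.
#' @return A `calibration` object holding `k1` (a.u. per nm^2), the ROI
#'   table, and fit residuals.
#' @export
calibrate_k1 <- function(slb_image, rois) {
  if (length(rois) < 3) stop("need at least 3 ROIs")
  ids <- vapply(rois, function(r) .roi_id(slb_image, r), numeric(1))
  areas <- vapply(rois, function(r) .roi_area_nm2(slb_image, r), numeric(1))
  if (length(unique(round(areas, 6))) < 2)
    stop("ROI areas are all identical: calibration design is rank-deficient")
  k1 <- sum(ids * areas) / sum(areas^2)
  if (k1 <= 0) stop("calibration error: non-positive intensity-per-area slope")
  res <- ids - k1 * areas
  out <- list(k1 = k1, k2 = NULL,
              provenance = list(n_roi = length(rois), areas = areas,
                                ids = ids, residual_sd = sd(res)))
  class(out) <- "calibration"
  out
}

#' @export
print.calibration <- function(x, ...) {
  cat("calibration:")
  if (!is.null(x$k1)) cat(sprintf(" k1 = %.4g a.u./nm^2", x$k1))
  if (!is.null(x$k2)) cat(sprintf(" k2 = %.4g a.u./nm", x$k2))
  cat("\n")
  invisible(x)
}

#' Tube radius from integrated fluorescence density
#'
#' Converts the integrated density of a tube segment of length `l` to a
#' radius via \eqn{r = ID / (k_1 2 \pi l)}.  The estimate reflects the
#' distance from the lumen to the centre of the bilayer.
#'
#' @param ID integrated density, a.u. (>= 0; vectorised).
#' @param l segment length, nm (> 0).
#' @param k1 intensity-per-area slope (> 0), or a `calibration`.
#' @return Radius in nm.
#' @export
radius_from_integrated_density <- function(ID, l, k1) {
  if (inherits(k1, "calibration")) k1 <- k1$k1
  if (any(ID < 0)) stop("ID must be >= 0")
  if (l <= 0) stop("segment length must be > 0")
  if (k1 <= 0) stop("k1 must be > 0")
  ID / (k1 * 2 * pi * l)
}

#' Calibrate the peak-intensity-per-radius slope k2
#'
#' Peak intensities of tubes of known radii are regressed through the
#' origin against radius.
#'
#' @param tube_images list of >= 3 background-corrected tube images.
#' @param radii their radii, nm (from
#'   [radius_from_integrated_density()]); should span at least a 2-fold
#'   range.
#' @return A `calibration` with `k2` (a.u. per nm).
#' @export
calibrate_k2 <- function(tube_images, radii) {
  if (length(tube_images) < 3 || length(radii) != length(tube_images))
    stop("need >= 3 tubes with matching radii: design is rank-deficient")
  if (max(radii) / min(radii) < 2)
    warning("tube radius range below 2-fold; k2 is poorly constrained")
  peaks <- vapply(tube_images, max, numeric(1))
  k2 <- sum(peaks * radii) / sum(radii^2)
  out <- list(k1 = NULL, k2 = k2,
              provenance = list(n_tubes = length(radii), radii = radii,
                                peaks = peaks))
  class(out) <- "calibration"
  out
}

#' Per-pixel radius profile from a tube intensity trace
#'
#' Divides a background-corrected peak-intensity trace by k2.  Negative
#' corrected intensities are clipped to zero and flagged.
#'
#' @param trace background-corrected peak intensity per axial pixel.
#' @param k2 peak-intensity-per-radius slope, or a `calibration`.
#' @param pixel_size nm per pixel (used for the `x` coordinate).
#' @return Data frame with `x` (nm) and `radius` (nm);
#'   `attr(, "clipped")` gives the count of clipped pixels.
#' @export
radius_profile_from_trace <- function(trace, k2, pixel_size = 1) {
  if (inherits(k2, "calibration")) k2 <- k2$k2
  stopifnot(k2 > 0)
  r <- trace / k2
  clipped <- sum(r < 0)
  r[r < 0] <- 0
  out <- data.frame(x = (seq_along(r) - 0.5) * pixel_size, radius = r)
  attr(out, "clipped") <- clipped
  out
}

#' Protein:membrane fluorescence ratio in an ROI
#'
#' @param protein_img,membrane_img background-corrected, co-registered
#'   channel images.
#' @param roi rectangle `list(x = c(x0, x1), y = c(y0, y1))`.
#' @return Ratio of mean protein to mean membrane intensity.
#' @export
protein_membrane_ratio <- function(protein_img, membrane_img, roi) {
  pm <- mean(protein_img[roi$y[1]:roi$y[2], roi$x[1]:roi$x[2]])
  mm <- mean(membrane_img[roi$y[1]:roi$y[2], roi$x[1]:roi$x[2]])
  if (mm <= 0) stop("mean membrane intensity is not positive: ratio undefined")
  pm / mm
}

#' Pearson correlation between protein and membrane fluorescence
#'
#' Product-moment correlation of paired intensity traces along one tube.
#' Scaffolds that bulge the membrane correlate positively with membrane
#' fluorescence; constricting scaffolds correlate negatively.
#'
#' @param protein_trace,membrane_trace equal-length traces (n >= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_protein_membrane <- function(protein_trace, membrane_trace) {
  if (length(protein_trace) != length(membrane_trace) ||
      length(protein_trace) < 3)
    stop("need equal-length traces with n >= 3")
  if (sd(protein_trace) == 0 || sd(membrane_trace) == 0)
    stop("zero variance in a trace: correlation undefined")
  cor(protein_trace, membrane_trace)
}

#' Detect bulges on a calibrated radius profile
#'
#' Contiguous runs where the radius exceeds the baseline by more than
#' `threshold_fraction` are bulge records; runs closer than
#' `merge_distance` are merged.  The baseline is the median radius of
#' the profile.  Constrictions (runs below baseline by the same
#' fraction) are reported with `sign = -1`.
#'
#' @param profile data frame with `x` (nm) and `radius` (nm) (e.g. from
#'   [radius_profile_from_trace()]).
#' @param threshold_fraction fractional excursion defining a bulge
#'   (default 0.2).
#' @param merge_distance nm; nearby runs merge into one record.
#' @param min_extent minimum bulge footprint, nm.
#' @return A list with `bulges` (data frame: position, extent, R_b,
#'   baseline, sign) and `density_per_um`.
#' @export
detect_bulges <- function(profile, threshold_fraction = 0.2,
                          merge_distance = 200, min_extent = 0) {
  x <- profile$x
  r <- profile$radius
  if (length(x) < 5) stop("profile shorter than the baseline window")
  base <- stats::median(r[r > 0], na.rm = TRUE)
  recs <- list()
  for (sign in c(1, -1)) {
    above <- if (sign > 0) r > base * (1 + threshold_fraction)
             else r < base * (1 - threshold_fraction) & r > 0
    above[is.na(above)] <- FALSE
    if (!any(above)) next
    rl <- rle(above)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    runs <- data.frame(s = starts[rl$values], e = ends[rl$values])
    # merge runs separated by less than merge_distance
    if (nrow(runs) > 1) {
      keep <- list(runs[1, ])
      for (i in 2:nrow(runs)) {
        last <- keep[[length(keep)]]
        if (x[runs$s[i]] - x[last$e] < merge_distance)
          keep[[length(keep)]]$e <- runs$e[i]
        else keep[[length(keep) + 1]] <- runs[i, ]
      }
      runs <- do.call(rbind, keep)
    }
    for (i in seq_len(nrow(runs))) {
      seg <- runs$s[i]:runs$e[i]
      if (diff(range(x[seg])) < min_extent && length(seg) > 1) next
      peak <- if (sign > 0) max(r[seg]) else min(r[seg])
      recs[[length(recs) + 1]] <- data.frame(
        position = x[seg][which.max(sign * r[seg])],
        extent = diff(range(x[seg])) + diff(x[1:2]),
        R_b = peak, baseline = base, sign = sign)
    }
  }
  bulges <- if (length(recs)) do.call(rbind, recs)
            else data.frame(position = numeric(), extent = numeric(),
                            R_b = numeric(), baseline = numeric(),
                            sign = numeric())
  tube_len_um <- diff(range(x)) / 1000
  list(bulges = bulges,
       density_per_um = sum(bulges$sign > 0) / tube_len_um)
}

#' Cumulative fission kinetics
#'
#' Builds the right-continuous cumulative-cuts curve and per-event
#' fission times (scission minus bulge onset).  Records with scission
#' before onset are rejected.
#'
#' @param events data frame with `onset` and `scission` times (s).
#' @param observation_window `c(t0, t1)`; events outside are dropped.
#' @return List with `fission_times`, `curve` (a [stats::stepfun()]),
#'   `times`, `cumulative`, and `n_rejected`.
#' @export
fission_kinetics <- function(events, observation_window = NULL) {
  bad <- events$scission < events$onset
  n_rejected <- sum(bad)
  ev <- events[!bad, , drop = FALSE]
  if (!is.null(observation_window))
    ev <- ev[ev$scission >= observation_window[1] &
               ev$scission <= observation_window[2], , drop = FALSE]
  ft <- ev$scission - ev$onset
  ts <- sort(ev$scission)
  curve <- if (length(ts))
    stats::stepfun(ts, c(0, seq_along(ts)), right = FALSE)
  else stats::stepfun(0, c(0, 0), right = FALSE)
  list(fission_times = ft, curve = curve, times = ts,
       cumulative = seq_along(ts), n_rejected = n_rejected)
}

#' Remodeling and fission probability vs starting radius
#'
#' Bins tubes by starting radius and reports per-bin fractions of
#' remodeled and cut tubes with exact binomial confidence intervals.
#'
#' @param tubes data frame with `radius` (nm), `remodeled` (logical),
#'   `cut` (logical).
#' @param breaks bin boundaries, nm.
#' @return Data frame with per-bin counts, probabilities and 95% CIs;
#'   empty bins carry `NA` probabilities.
#' @export
remodeling_probability <- function(tubes,
                                   breaks = seq(0, 60, by = 10)) {
  b <- cut(tubes$radius, breaks, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(b), function(lv) {
    sel <- which(b == lv)
    n <- length(sel)
    row <- data.frame(bin = lv, n = n,
                      p_remodeled = NA_real_, lo = NA_real_, hi = NA_real_,
                      p_cut = NA_real_)
    if (n > 0) {
      k <- sum(tubes$remodeled[sel])
      bt <- stats::binom.test(k, n)
      row$p_remodeled <- k / n
      row$lo <- bt$conf.int[1]
      row$hi <- bt$conf.int[2]
      row$p_cut <- mean(tubes$cut[sel])
    }
    row
  }))
  out
}

#' Fit a FRAP recovery curve
#'
#' Fits the model-independent hyperbolic recovery
#' `F(t) = F_b + (F_inf - F_b) * t / (t_half + t)` and reports the
#' mobile fraction `(F_inf - F_b) / (F_p - F_b)` and half-time.  An
#' exponential recovery `F_b + (F_inf - F_b) * (1 - exp(-t/tau))` is
#' available via `model = "exponential"`.
#'
#' @param trace a `frap_trace` (or list with `t`, `F`, `F_p`, `F_b`).
#' @param model recovery model.
#' @return List with `mobile_fraction`, `t_half`, `F_inf`, and the fit.
#' @export
fit_frap <- function(trace, model = c("hyperbolic", "exponential")) {
  model <- match.arg(model)
  if (trace$F_b >= trace$F_p)
    stop("F_b must be below F_p: no bleach to recover from")
  if (length(trace$t) < 10) stop("need >= 10 post-bleach points")
  df <- data.frame(t = trace$t, f = trace$F)
  Fb <- trace$F_b
  start <- list(Finf = max(df$f), th = stats::median(df$t) / 2)
  fml <- if (model == "hyperbolic")
    f ~ Fb + (Finf - Fb) * t / (th + t)
  else f ~ Fb + (Finf - Fb) * (1 - exp(-t / th))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df, start = start,
                      lower = c(Finf = Fb, th = 1e-6)),
    error = function(e)
      stop("FRAP fit did not converge: ", conditionMessage(e),
           "; residual sd of constant model = ", signif(sd(df$f), 3)))
  cf <- coef(fit)
  mf <- (cf[["Finf"]] - Fb) / (trace$F_p - Fb)
  list(mobile_fraction = unname(mf), t_half = unname(cf[["th"]]),
       F_inf = unname(cf[["Finf"]]), fit = fit, model = model)
}

#' Apparent scaffold growth rate from a kymograph
#'
#' Thresholds each time row at half its dynamic range to find the
#' scaffold edge and fits a robust line (M-estimator) to edge position
#' versus time; the slope is the apparent growth rate.
#'
#' @param kymograph matrix (time rows x position columns) with
#'   attributes `pixel_size` (nm) and `frame_interval` (s), as produced
#'   by [simulate_kymograph()].
#' @param min_range intensity dynamic range below which no edge is
#'   called.
#' @return List with `rate_nm_per_s`, `edge` (data frame), and
#'   `low_confidence` (TRUE when no edge motion was detected).
#' @export
scaffold_growth_rate <- function(kymograph, min_range = 10) {
  px <- attr(kymograph, "pixel_size")
  dt <- attr(kymograph, "frame_interval")
  nt <- nrow(kymograph)
  x <- (seq_len(ncol(kymograph)) - 0.5) * px
  edge <- rep(NA_real_, nt)
  for (k in seq_len(nt)) {
    row <- kymograph[k, ]
    rng <- max(row) - min(row)
    if (rng < min_range) next
    thr <- min(row) + rng / 2
    ab <- which(row > thr)
    if (length(ab)) edge[k] <- x[max(ab)]
  }
  t <- (seq_len(nt) - 1) * dt
  ok <- !is.na(edge)
  if (sum(ok) < 3)
    return(list(rate_nm_per_s = 0, edge = data.frame(t = t, edge = edge),
                low_confidence = TRUE))
  fit <- MASS::rlm(edge[ok] ~ t[ok], maxit = 50)
  rate <- unname(coef(fit)[2])
  # an edge that moves less than ~2 pixels over the record is static
  if (abs(rate) * diff(range(t[ok])) < 2 * px)
    return(list(rate_nm_per_s = 0, edge = data.frame(t = t, edge = edge),
                low_confidence = TRUE))
  list(rate_nm_per_s = rate,
       edge = data.frame(t = t, edge = edge),
       low_confidence = FALSE)
}

#' Detect remodeling events in a synthetic tube movie
#'
#' Converts every frame to a radius profile (per-column integrated
#' density through k1), then finds bulge onsets (first frame a scaffold
#' site exceeds 20% above baseline) and scission (first frame with a
#' contiguous tube-interior gap of near-zero radius).
#'
#' @param movie a `tube_movie`.
#' @param k1 intensity-per-area slope of the movie's renderer (a
#'   `calibration` or number); defaults to the generator's brightness
#'   constant.
#' @param bulge_threshold fractional excursion for bulge calls.
#' @param gap_radius_fraction radius below this fraction of baseline
#'   counts as a gap.
#' @return Data frame of detected events (`event`, `time`, `position`).
#' @export
detect_movie_events <- function(movie, k1 = NULL, bulge_threshold = 0.2,
                                gap_radius_fraction = 0.25) {
  if (is.null(k1)) k1 <- movie$cfg$brightness
  if (inherits(k1, "calibration")) k1 <- k1$k1
  px <- movie$pixel_size
  nx <- ncol(movie$frames[[1]])
  x <- (seq_len(nx) - 0.5) * px
  base <- movie$params$baseline_radius
  events <- data.frame(event = character(), time = numeric(),
                       position = numeric())
  onset_done <- FALSE
  cut_done <- FALSE
  for (k in seq_along(movie$frames)) {
    img <- movie$frames[[k]]
    ids <- colSums(img - movie$cfg$background)
    r <- radius_from_integrated_density(pmax(ids, 0), px, k1)
    if (!onset_done) {
      hot <- r > base * (1 + bulge_threshold)
      if (any(hot)) {
        events <- rbind(events, data.frame(
          event = "onset", time = movie$times[k],
          position = mean(x[hot])))
        onset_done <- TRUE
      }
    }
    if (!cut_done) {
      # interior gap: a run of near-zero radius flanked by tube on both
      # sides
      low <- r < base * gap_radius_fraction
      rl <- rle(low)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1
      runs <- which(rl$values & starts > 1 & ends < nx)
      runs <- runs[rl$lengths[runs] >= 2]
      if (length(runs)) {
        j <- runs[1]
        events <- rbind(events, data.frame(
          event = "scission", time = movie$times[k],
          position = mean(x[starts[j]:ends[j]])))
        cut_done <- TRUE
      }
    }
    if (onset_done && cut_done) break
  }
  events
}
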