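#' Rendering configuration for synthetic fluorescence data
#'
#' Controls how synthetic membranes are turned into images: the physical
#' pixel size, a Gaussian point-spread function, the brightness constant
#' (intensity per nm^2 of membrane), a constant background, and a
#' Poisson-Gaussian noise model.
#'
#' Membrane tubes are diffraction-limited objects, so their rendered
#' brightness is proportional to the membrane area inside the focal
#' column: a tube of radius r contributes `brightness * 2 * pi * r` per
#' nm of axial length, spread over the PSF.
#'
#' @param pixel_size nm per pixel.
#' @param psf_sigma Gaussian PSF sigma, nm.
#' @param brightness intensity (a.u.) per nm^2 of membrane.
#' @param background constant offset per pixel, a.u.
#' @param gain Poisson gain; 0 disables shot noise.
#' @param read_noise Gaussian read noise sd, a.u.; 0 disables.
#' @param seed RNG seed used by the renderers.
#' @return A `render_config` list.
#' @export
render_config <- function(pixel_size = 80, psf_sigma = 120, brightness = 5,
                          background = 100, gain = 1, read_noise = 2,
                          seed = 1) {
  stopifnot(pixel_size > 0, psf_sigma > 0, brightness > 0)
  cfg <- list(pixel_size = pixel_size, psf_sigma = psf_sigma,
              brightness = brightness, background = background,
              gain = gain, read_noise = read_noise, seed = seed)
  class(cfg) <- "render_config"
  cfg
}

# separable Gaussian blur with edge renormalisation
.gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  hw <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-hw:hw, sd = sigma_px)
  k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    vp <- c(rep(0, hw), v, rep(0, hw))
    wp <- c(rep(0, hw), rep(1, n), rep(0, hw))
    num <- stats::filter(vp, k, sides = 2)[(hw + 1):(hw + n)]
    den <- stats::filter(wp, k, sides = 2)[(hw + 1):(hw + n)]
    as.numeric(num) / as.numeric(den)
  }
  img <- t(apply(img, 1, blur1))
  apply(img, 2, blur1)
}

.add_noise <- function(img, cfg) {
  if (cfg$gain > 0) img <- cfg$gain * matrix(rpois(length(img),
                                                   pmax(img, 0) / cfg$gain),
                                             nrow(img))
  if (cfg$read_noise > 0) img <- img + matrix(rnorm(length(img),
                                                    sd = cfg$read_noise),
                                              nrow(img))
  img
}

.as_image <- function(mat, cfg, channel = "membrane") {
  attr(mat, "pixel_size") <- cfg$pixel_size
  attr(mat, "channel") <- channel
  mat
}

#' Render a supported lipid bilayer image
#'
#' A uniform field of the given membrane-intensity density plus
#' background and noise; the calibration substrate for the
#' intensity-per-area slope k1.
#'
#' @param density membrane intensity density, a.u. per nm^2.
#' @param shape image dimensions `c(ny, nx)` in pixels.
#' @param cfg a [render_config()].
#' @return An image matrix with a `pixel_size` attribute.
#' @export
render_slb <- function(density, shape = c(64, 64), cfg = render_config()) {
  stopifnot(density >= 0)
  set.seed(cfg$seed)
  img <- matrix(density * cfg$pixel_size^2, shape[1], shape[2])
  img <- .add_noise(img + cfg$background, cfg)
  .as_image(img, cfg)
}

#' Render a membrane tube image from a radius profile
#'
#' The tube runs horizontally through the image centre.  Each axial
#' pixel column receives integrated intensity
#' `brightness * 2 * pi * r(x) * pixel_size` (tube membrane area in the
#' focal column), which is then spread with the Gaussian PSF, offset by
#' the background, and subjected to the noise model.
#'
#' @param radius_profile radius per axial pixel (nm); recycled if a
#'   single value.  Zero marks tube-free pixels.
#' @param nx,ny image size in pixels; `radius_profile` is padded or
#'   truncated to `nx`.
#' @param cfg a [render_config()].
#' @param brightness override of `cfg$brightness` (used to render
#'   calibration series).
#' @return An image matrix with attributes `pixel_size` and
#'   `radius_profile` (the ground truth used).
#' @export
render_tube <- function(radius_profile, nx = 128, ny = 32,
                        cfg = render_config(), brightness = NULL) {
  if (any(radius_profile < 0)) stop("radius profile must be >= 0")
  if (is.null(brightness)) brightness <- cfg$brightness
  r <- rep_len(radius_profile, nx)
  if (max(r) > ny * cfg$pixel_size / 2)
    stop("tube radius exceeds the field of view")
  set.seed(cfg$seed)
  img <- matrix(0, ny, nx)
  y0 <- ceiling(ny / 2)
  img[y0, ] <- brightness * 2 * pi * r * cfg$pixel_size
  img <- .gauss_blur(img, cfg$psf_sigma / cfg$pixel_size)
  img <- .add_noise(img + cfg$background, cfg)
  img <- .as_image(img, cfg)
  attr(img, "radius_profile") <- r
  img
}

#' Simulate a tube remodeling movie with ground truth
#'
#' Scaffolded regions of the tube grow in radius at `growth_rate` while
#' the membrane area `integral 2 pi r dx` is held constant by uniformly
#' thinning the regions outside the scaffolds.  When the thinned radius
#' reaches `fission_radius`, a scission event is logged at the midpoint
#' of the longest bare segment and the tube retracts into two capped
#' ends rendered as bright puncta.  Bulge onset is logged at the first
#' frame a scaffold region exceeds the detection criterion (20% above
#' the running baseline), which makes the log directly comparable with
#' the detector.
#'
#' @param tube_length nm.
#' @param baseline_radius starting tube radius, nm (remodeling scenarios
#'   use values below 25 nm).
#' @param scaffold_centers axial positions of scaffolds, nm.
#' @param scaffold_width scaffold footprint, nm.
#' @param growth_rate scaffold radius growth, nm/s.
#' @param fission_radius scission threshold for the thinned regions, nm.
#' @param n_frames,frame_interval movie length and frame spacing (s).
#' @param cfg a [render_config()].
#' @param protein_channel also render a protein channel proportional to
#'   scaffold occupancy.
#' @return A `tube_movie`: list with `frames` (list of image matrices),
#'   `times` (s), `pixel_size`, `profiles` (ground-truth radius per
#'   frame), `events` (data frame: event, time, position) and the
#'   generator parameters.
#' @export
simulate_remodeling_movie <- function(tube_length = 10000,
                                      baseline_radius = 10,
                                      scaffold_centers = tube_length / 2,
                                      scaffold_width = 500,
                                      growth_rate = 2,
                                      fission_radius = 5,
                                      n_frames = 60, frame_interval = 1,
                                      cfg = render_config(),
                                      protein_channel = FALSE) {
  stopifnot(baseline_radius > 0, fission_radius >= 0, growth_rate >= 0)
  set.seed(cfg$seed)
  px <- cfg$pixel_size
  nx <- ceiling(tube_length / px)
  x <- (seq_len(nx) - 0.5) * px
  scaf <- rep(FALSE, nx)
  for (s0 in scaffold_centers)
    scaf <- scaf | abs(x - s0) <= scaffold_width / 2
  area0 <- 2 * pi * baseline_radius * px * nx
  times <- (seq_len(n_frames) - 1) * frame_interval
  profiles <- vector("list", n_frames)
  frames <- vector("list", n_frames)
  pframes <- if (protein_channel) vector("list", n_frames) else NULL
  events <- data.frame(event = character(), time = numeric(),
                       position = numeric())
  onset_logged <- rep(FALSE, length(scaffold_centers))
  cut_time <- NA_real_
  cut_pos <- NA_real_
  # midpoint of the longest bare segment: the deterministic cut site
  bare <- rle(scaf)
  ends <- cumsum(bare$lengths)
  starts <- ends - bare$lengths + 1
  bi <- which(!bare$values)
  bl <- bare$lengths[bi]
  jb <- bi[which.max(bl)]
  cut_site <- x[floor((starts[jb] + ends[jb]) / 2)]
  retract_speed <- 400 # nm/s of the cut ends after scission
  for (k in seq_len(n_frames)) {
    t <- times[k]
    r <- rep(baseline_radius, nx)
    if (is.na(cut_time)) {
      r[scaf] <- baseline_radius + growth_rate * t
      # conserve total membrane area by thinning the bare regions
      excess <- 2 * pi * sum(r * px) - area0
      nb <- sum(!scaf)
      if (nb > 0) r[!scaf] <- r[!scaf] - excess / (2 * pi * nb * px)
      if (any(r[!scaf] <= fission_radius)) {
        cut_time <- t
        cut_pos <- cut_site
        events <- rbind(events, data.frame(event = "scission", time = t,
                                           position = cut_pos))
      }
      for (si in seq_along(scaffold_centers)) {
        if (!onset_logged[si]) {
          in_s <- abs(x - scaffold_centers[si]) <= scaffold_width / 2
          if (mean(r[in_s]) > 1.2 * baseline_radius) {
            onset_logged[si] <- TRUE
            events <- rbind(events, data.frame(
              event = "onset", time = t,
              position = scaffold_centers[si]))
          }
        }
      }
    }
    if (!is.na(cut_time)) {
      r[scaf] <- baseline_radius + growth_rate * cut_time
      excess <- 2 * pi * sum(r * px) - area0
      nb <- sum(!scaf)
      if (nb > 0) r[!scaf] <- pmax(r[!scaf] - excess / (2 * pi * nb * px),
                                   fission_radius)
      # the gap opens two pixels wide at the cut frame so the scission is
      # optically resolvable through the PSF from its first frame
      gap_half <- retract_speed * (t - cut_time) / 2 + 2 * px
      gone <- abs(x - cut_pos) < gap_half
      r[gone] <- 0
    }
    r <- pmax(r, 0)
    profiles[[k]] <- r
    img <- matrix(0, 24, nx)
    y0 <- 12
    img[y0, ] <- cfg$brightness * 2 * pi * r * px
    if (!is.na(cut_time) && t > cut_time) {
      # capped, retracting ends show up as bright puncta
      for (sgn in c(-1, 1)) {
        xe <- cut_pos + sgn * (retract_speed * (t - cut_time) / 2 + px)
        je <- max(1, min(nx, round(xe / px)))
        if (r[je] > 0 || TRUE)
          img[y0, je] <- img[y0, je] + cfg$brightness * 4 * pi *
            baseline_radius * px
      }
    }
    img <- .gauss_blur(img, cfg$psf_sigma / px)
    frames[[k]] <- .as_image(.add_noise(img + cfg$background, cfg), cfg)
    if (protein_channel) {
      p <- matrix(0, 24, nx)
      p[y0, scaf] <- cfg$brightness * 2 * pi * r[scaf] * px
      p <- .gauss_blur(p, cfg$psf_sigma / px)
      pframes[[k]] <- .as_image(.add_noise(p + cfg$background, cfg), cfg,
                                channel = "protein")
    }
  }
  mv <- list(frames = frames, protein_frames = pframes, times = times,
             pixel_size = px, profiles = profiles, events = events,
             params = list(tube_length = tube_length,
                           baseline_radius = baseline_radius,
                           scaffold_centers = scaffold_centers,
                           scaffold_width = scaffold_width,
                           growth_rate = growth_rate,
                           fission_radius = fission_radius,
                           frame_interval = frame_interval,
                           seed = cfg$seed),
             cfg = cfg)
  class(mv) <- "tube_movie"
  mv
}

#' @export
print.tube_movie <- function(x, ...) {
  cat(sprintf("tube_movie: %d frames, %d px (%.0f nm/px), %d events\n",
              length(x$frames), ncol(x$frames[[1]]), x$pixel_size,
              nrow(x$events)))
  invisible(x)
}

#' Simulate a FRAP trace with known mobile fraction
#'
#' Hyperbolic recovery toward `F_b + mobile_fraction * (F_p - F_b)` with
#' half-time `t_half`, preceded by a short prebleach plateau.
#'
#' @param F_p prebleach fluorescence.
#' @param F_b fluorescence at bleach.
#' @param mobile_fraction in `[0, 1]`.
#' @param t_half recovery half-time, s.
#' @param n_points post-bleach samples.
#' @param dt sampling interval, s.
#' @param noise_sd Gaussian noise sd.
#' @param seed RNG seed.
#' @return A `frap_trace`: list with `t`, `F` (post-bleach), `F_p`,
#'   `F_b`, `prebleach` and the ground-truth parameters.
#' @export
simulate_frap_trace <- function(F_p = 1000, F_b = 200,
                                mobile_fraction = 0.5, t_half = 5,
                                n_points = 60, dt = 0.5, noise_sd = 5,
                                seed = 1) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1, F_b <= F_p)
  set.seed(seed)
  t <- seq_len(n_points) * dt
  Finf <- F_b + mobile_fraction * (F_p - F_b)
  f <- F_b + (Finf - F_b) * t / (t_half + t)
  tr <- list(t = t,
             F = f + rnorm(n_points, sd = noise_sd),
             F_p = F_p, F_b = F_b,
             prebleach = F_p + rnorm(5, sd = noise_sd),
             truth = list(mobile_fraction = mobile_fraction,
                          t_half = t_half, seed = seed))
  class(tr) <- "frap_trace"
  tr
}

#' Simulate a kymograph with an advancing edge
#'
#' A bright wedge whose edge advances linearly at `speed` from a fixed
#' starting position: rows are time points, columns axial position.
#'
#' @param speed edge speed, nm/s (>= 0).
#' @param duration s.
#' @param frame_interval s per row.
#' @param tube_length nm (columns span this length).
#' @param start_x initial edge position, nm.
#' @param cfg a [render_config()].
#' @return A kymograph matrix (time x position) with attributes
#'   `pixel_size`, `frame_interval`, and `speed` (ground truth).
#' @export
simulate_kymograph <- function(speed = 27, duration = 10,
                               frame_interval = 0.25, tube_length = 2000,
                               start_x = 200, cfg = render_config()) {
  stopifnot(speed >= 0)
  set.seed(cfg$seed)
  px <- cfg$pixel_size
  nx <- ceiling(tube_length / px)
  nt <- floor(duration / frame_interval) + 1
  x <- (seq_len(nx) - 0.5) * px
  ky <- matrix(0, nt, nx)
  amp <- cfg$brightness * 2 * pi * 10 * px
  for (k in seq_len(nt)) {
    t <- (k - 1) * frame_interval
    edge <- start_x + speed * t
    # bright wedge with the edge softened over roughly one PSF width
    ky[k, ] <- amp * stats::pnorm(edge - x, sd = cfg$psf_sigma / 2)
  }
  ky <- ky + cfg$background
  ky <- .add_noise(ky, cfg)
  attr(ky, "pixel_size") <- px
  attr(ky, "frame_interval") <- frame_interval
  attr(ky, "speed") <- speed
  ky
}

#' Write a movie or image stack as multi-page TIFF
#'
#' @param movie a `tube_movie` or list of image matrices.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- if (inherits(movie, "tube_movie")) movie$frames else movie
  mx <- max(vapply(frames, max, numeric(1)))
  imgs <- lapply(frames, function(f) f / mx)
  tiff::writeTIFF(imgs, path)
  invisible(path)
}

#' Read a multi-page TIFF as an image list
#'
#' @param path TIFF file.
#' @param pixel_size nm per pixel to attach to each frame.
#' @return List of image matrices.
#' @export
read_movie_tiff <- function(path, pixel_size = 80) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(f) {
    attr(f, "pixel_size") <- pixel_size
    f
  })
}
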