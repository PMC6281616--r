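#' Build a coarse-grained bilayer tube
#'
#' Constructs a membrane nanotube as two concentric cylindrical leaflets
#' of three-site lipids in a periodic box.  The tube axis runs along x
#' and spans the box, so the tube is continuous through its periodic
#' image.  Tails point inward toward the bilayer midplane.  Species
#' (DOPS/DOPC) are assigned randomly at `ps_fraction` under `seed`, and
#' lipids are divided between leaflets in proportion to the leaflet
#' mid-surface areas.
#'
#' The default geometry of the full-scale system is a 100 nm tube with a
#' 20 nm outer diameter and ~11 nm lumen diameter holding 14,500 lipids
#' (43,500 CG sites).  Lumen diameter refers to the inner-leaflet
#' head-site circle, so the bilayer thickness is
#' `(outer_diameter - lumen_diameter) / 2`.
#'
#' @param length tube length (= periodic box length along x), nm.
#' @param outer_diameter diameter of the outer-leaflet head-site circle, nm.
#' @param lumen_diameter diameter of the inner-leaflet head-site circle, nm.
#' @param n_lipids total lipid count; default chosen from the geometric
#'   area per lipid target in `params`.
#' @param ps_fraction DOPS mole fraction (default 0.40).
#' @param seed integer seed controlling species assignment and in-leaflet
#'   placement jitter only.
#' @param params a [lipid_params()] object.
#' @param pot a [protein_lipid_potential()] object (kept with the system
#'   for later scaffold placement).
#' @param box_yz transverse box size, nm; default 2.5 x the outer
#'   diameter, floored at outer diameter + 12 nm.
#' @return An object of class `cg_system`.
#' @export
build_tube <- function(length = 100, outer_diameter = 20,
                       lumen_diameter = 11, n_lipids = NULL,
                       ps_fraction = 0.40, seed = 1,
                       params = lipid_params(),
                       pot = protein_lipid_potential(),
                       box_yz = NULL) {
  if (lumen_diameter <= 0) stop("infeasible geometry: lumen diameter must be > 0")
  if (outer_diameter <= lumen_diameter)
    stop("infeasible geometry: outer diameter must exceed lumen diameter")
  r_oh <- outer_diameter / 2
  r_ih <- lumen_diameter / 2
  thick <- r_oh - r_ih
  if (thick < 2 * params$bond_r0)
    stop("infeasible geometry: bilayer thinner than one extended lipid")
  if (is.null(box_yz)) box_yz <- max(2.5 * outer_diameter, outer_diameter + 12)
  apl_target <- params$target_apl
  if (is.null(n_lipids))
    n_lipids <- round(2 * pi * length * (r_oh + r_ih) / apl_target)
  apl_geom <- 2 * pi * length * (r_oh + r_ih) / n_lipids
  if (apl_geom < 0.75 * apl_target || apl_geom > 1.35 * apl_target)
    warning(sprintf(
      "n_lipids gives geometric area per lipid %.3f nm^2, outside [%.3f, %.3f]",
      apl_geom, 0.75 * apl_target, 1.35 * apl_target))

  # leaflet split proportional to leaflet mid-surface areas
  span <- 2 * params$bond_r0          # head-to-tail extent of one lipid
  r_om <- r_oh - span / 2
  r_im <- r_ih + span / 2
  n_out <- round(n_lipids * r_om / (r_om + r_im))
  n_in <- n_lipids - n_out

  set.seed(seed)
  yc <- box_yz / 2
  zc <- box_yz / 2
  # radial placement span per monolayer; compresses when the bilayer is
  # built thinner than two fully extended lipids (tails relax/tilt later)
  r0_place <- min(params$bond_r0, (thick - 1.2 * params$sigma_tail) / 4)
  out_lf <- .cyl_leaflet(n_out, r_oh, -1, length, span, r0_place)
  in_lf <- .cyl_leaflet(n_in, r_ih, +1, length, span, r0_place)
  pos <- rbind(out_lf, in_lf)
  pos[, 2] <- pos[, 2] + yc
  pos[, 3] <- pos[, 3] + zc

  n_ps <- round(ps_fraction * n_lipids)
  species <- rep("DOPC", n_lipids)
  species[sample.int(n_lipids, n_ps)] <- "DOPS"

  sys <- .new_system(pos, n_lipids,
                     leaflet = rep(c("outer", "inner"), c(n_out, n_in)),
                     species = species,
                     box = c(length, box_yz, box_yz),
                     params = params, pot = pot)
  sys$meta <- list(kind = "tube", length = length,
                   r_outer_head = r_oh, r_inner_head = r_ih,
                   thickness = thick, apl_geometric = apl_geom,
                   axis_yz = c(yc, zc), seed = seed,
                   ps_fraction = ps_fraction)
  sys
}

# one cylindrical leaflet; direction = -1 tails point inward (outer
# leaflet), +1 tails point outward from the head circle (inner leaflet).
# Returns 3 rows per lipid (head, body, tail) about axis y = z = 0.
.cyl_leaflet <- function(n, r_head, direction, length, span, r0) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  # near-square grid on the head cylinder
  n_x <- max(1L, round(sqrt(n * length / (2 * pi * r_head))))
  n_phi <- ceiling(n / n_x)
  idx <- seq_len(n) - 1L
  ix <- idx %% n_x
  iphi <- idx %/% n_x
  x <- (ix + 0.5) * length / n_x + runif(n, -0.05, 0.05)
  phi <- (iphi + 0.5 * (ix %% 2)) * 2 * pi / n_phi + runif(n, -0.02, 0.02)
  ux <- cos(phi)
  uz <- sin(phi)
  # per-lipid radial stagger breaks the concentric-ring symmetry so
  # crowded leaflets (small lumen radii) can relax instead of jamming;
  # the amplitude stays below half the inter-shell clearance
  rjit <- runif(n, -0.2, 0.2)
  rh <- r_head + rjit
  rb <- r_head + direction * r0 + rjit
  rt <- r_head + direction * 2 * r0 + rjit
  pos <- matrix(0, 3 * n, 3)
  for (k in 1:3) {
    rr <- list(rh, rb, rt)[[k]]
    rows <- seq(k, 3 * n, by = 3)
    pos[rows, 1] <- x
    pos[rows, 2] <- rr * ux
    pos[rows, 3] <- rr * uz
  }
  pos
}

# assemble a cg_system from per-lipid layout (3 rows/lipid: head, body, tail)
.new_system <- function(pos, n_lipids, leaflet, species, box, params, pot) {
  n_sites <- 3 * n_lipids
  stopifnot(nrow(pos) == n_sites)
  cls <- rep(c("head", "body", "tail"), n_lipids)
  lipid_id <- rep(seq_len(n_lipids), each = 3)
  sys <- list(
    pos = pos,
    vel = matrix(0, n_sites, 3),
    class = cls,
    species = rep(species, each = 3),
    leaflet = rep(leaflet, each = 3),
    lipid_id = lipid_id,
    frozen = rep(FALSE, n_sites),
    box = box,
    params = params,
    pot = pot,
    scaffold = NULL,
    meta = list())
  class(sys) <- "cg_system"
  sys
}

#' @export
print.cg_system <- function(x, ...) {
  nl <- length(unique(x$lipid_id[!is.na(x$lipid_id)]))
  cat(sprintf("cg_system: %d sites (%d lipids, %d frozen protein sites)\n",
              nrow(x$pos), nl, sum(x$frozen)))
  cat(sprintf("  box %.1f x %.1f x %.1f nm\n", x$box[1], x$box[2], x$box[3]))
  if (!is.null(x$meta$kind))
    cat(sprintf("  %s, length %.1f nm, head radii %.2f / %.2f nm\n",
                x$meta$kind, x$meta$length %||% NA,
                x$meta$r_outer_head %||% NA, x$meta$r_inner_head %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of lipids in a system
#' @param system a `cg_system`.
#' @return Integer lipid count.
#' @export
lipid_count <- function(system) {
  length(unique(system$lipid_id[!is.na(system$lipid_id)]))
}

#' Build a series of bare tubes with varying lumen diameter
#'
#' One system per lumen diameter, identical in length, bilayer thickness
#' and area per lipid; the lipid count is rescaled with the geometry so
#' the area per lipid stays fixed.
#'
#' @param lumen_diameters lumen diameters, nm.
#' @param length tube length, nm.
#' @param thickness bilayer (head-to-head) thickness, nm.
#' @param ... further arguments passed to [build_tube()].
#' @return A list of `cg_system` objects.
#' @export
build_bare_tube_series <- function(lumen_diameters, length = 100,
                                   thickness = 4.5, ...) {
  if (any(lumen_diameters <= 0)) stop("lumen diameter must be > 0")
  lapply(lumen_diameters, function(d)
    build_tube(length = length, outer_diameter = d + 2 * thickness,
               lumen_diameter = d, n_lipids = NULL, ...))
}

#' Chord spacing of adjacent ring sites
#'
#' Centre-to-centre distance of adjacent sites evenly spaced on a circle:
#' the chord of angle `2*pi/sites_per_ring` on a circle of the given
#' diameter.  With the default scaffold geometry (25 nm ring, 35 sites)
#' this is 2.24 nm.
#'
#' @param ring_diameter ring diameter, nm.
#' @param sites_per_ring number of sites on the ring (>= 2).
#' @return Spacing in nm.
#' @export
ring_site_spacing <- function(ring_diameter, sites_per_ring) {
  if (sites_per_ring < 2) stop("sites_per_ring must be >= 2")
  ring_diameter * sin(pi / sites_per_ring)
}

#' Build a frozen ring scaffold
#'
#' Stacks rings of protein sites along the tube axis.  A single ring has
#' 35 sites on a 25 nm circle by default; rings are spaced 0.25 nm apart,
#' so a 4 nm scaffold has 16 rings (560 sites) and a 20 nm scaffold 80
#' rings (2800 sites).  The number of rings is
#' `round(scaffold_length / ring_spacing)`; the physical span of the
#' stack is `(n_rings - 1) * ring_spacing`.
#'
#' @param scaffold_length nominal scaffold length, nm (>= `ring_spacing`).
#' @param ring_diameter ring diameter, nm.
#' @param sites_per_ring sites per ring (>= 3).
#' @param ring_spacing axial distance between adjacent rings, nm.
#' @param axial_center axial position of the scaffold centre, nm.
#' @param staggered offset alternate rings by half an azimuthal step
#'   (default `FALSE`: rings azimuthally aligned).
#' @return An object of class `cg_scaffold` with fields `sites` (n x 3,
#'   axis at y = z = 0), `n_rings`, and the construction parameters.
#' @export
build_scaffold <- function(scaffold_length, ring_diameter = 25,
                           sites_per_ring = 35, ring_spacing = 0.25,
                           axial_center = 0, staggered = FALSE) {
  if (scaffold_length < ring_spacing)
    stop("scaffold_length must be >= ring_spacing")
  if (sites_per_ring < 3) stop("sites_per_ring must be >= 3")
  n_rings <- round(scaffold_length / ring_spacing)
  xs <- axial_center + (seq_len(n_rings) - (n_rings + 1) / 2) * ring_spacing
  r <- ring_diameter / 2
  ang0 <- 2 * pi * (seq_len(sites_per_ring) - 1) / sites_per_ring
  sites <- do.call(rbind, lapply(seq_len(n_rings), function(k) {
    ang <- ang0 + if (staggered && k %% 2 == 0) pi / sites_per_ring else 0
    cbind(xs[k], r * cos(ang), r * sin(ang))
  }))
  sc <- list(sites = sites, n_rings = n_rings,
             scaffold_length = scaffold_length,
             ring_diameter = ring_diameter,
             sites_per_ring = sites_per_ring,
             ring_spacing = ring_spacing,
             axial_center = axial_center, staggered = staggered)
  class(sc) <- "cg_scaffold"
  sc
}

#' @export
print.cg_scaffold <- function(x, ...) {
  cat(sprintf(
    "cg_scaffold: %d rings x %d sites = %d sites; diameter %.1f nm, span %.2f nm\n",
    x$n_rings, x$sites_per_ring, nrow(x$sites), x$ring_diameter,
    (x$n_rings - 1) * x$ring_spacing))
  invisible(x)
}

#' Place a scaffold on a tube
#'
#' Appends the scaffold sites to the system as frozen protein sites,
#' coaxial with the tube.  Lipid positions are untouched.  The scaffold
#' must lie within the box along the axis, its ring radius must exceed
#' the outer head radius of the tube, and no protein site may fall closer
#' than the protein LJ sigma to a lipid site.
#'
#' @param system a `cg_system` built by [build_tube()].
#' @param scaffold a `cg_scaffold`.
#' @return The system with frozen scaffold sites appended.
#' @export
place_scaffold <- function(system, scaffold) {
  stopifnot(inherits(system, "cg_system"), inherits(scaffold, "cg_scaffold"))
  xs <- scaffold$sites[, 1]
  if (min(xs) < 0 || max(xs) > system$box[1])
    stop("scaffold axial extent exceeds the box")
  if (scaffold$ring_diameter / 2 <= system$meta$r_outer_head)
    stop("scaffold ring radius must exceed the outer tube radius")
  sites <- scaffold$sites
  sites[, 2] <- sites[, 2] + system$meta$axis_yz[1]
  sites[, 3] <- sites[, 3] + system$meta$axis_yz[2]
  # overlap guard: no protein site may sit closer than sigma to a lipid
  lip <- system$pos
  near <- which(abs(((lip[, 1] - scaffold$axial_center + system$box[1] / 2) %%
                       system$box[1]) - system$box[1] / 2) <
                  scaffold$scaffold_length / 2 + 1)
  if (length(near) > 0) {
    sub <- lip[near, , drop = FALSE]
    mind <- Inf
    for (k in seq_len(nrow(sites))) {
      d2 <- (sub[, 1] - sites[k, 1])^2 + (sub[, 2] - sites[k, 2])^2 +
        (sub[, 3] - sites[k, 3])^2
      mind <- min(mind, min(d2))
    }
    if (sqrt(mind) < system$pot$sigma)
      stop("protein site overlaps a lipid site closer than sigma; ",
           "increase the ring diameter or rebuild the tube with a ",
           "smaller outer radius")
  }
  n_new <- nrow(sites)
  system$pos <- rbind(system$pos, sites)
  system$vel <- rbind(system$vel, matrix(0, n_new, 3))
  system$class <- c(system$class, rep("protein", n_new))
  system$species <- c(system$species, rep(NA_character_, n_new))
  system$leaflet <- c(system$leaflet, rep(NA_character_, n_new))
  system$lipid_id <- c(system$lipid_id, rep(NA_integer_, n_new))
  system$frozen <- c(system$frozen, rep(TRUE, n_new))
  system$scaffold <- scaffold
  system$meta$scaffold_bounds <- scaffold$axial_center +
    c(-1, 1) * (scaffold$n_rings - 1) * scaffold$ring_spacing / 2
  system
}

#' Build a planar bilayer patch
#'
#' A flat bilayer spanning the periodic box in x and y with its normal
#' along z, used to verify that the lipid parameterization holds a
#' bilayer together at temperature.
#'
#' @param n_side lipids per leaflet edge (patch has `n_side^2` lipids per
#'   leaflet).
#' @param apl area per lipid the box is sized for, nm^2.
#' @param ps_fraction DOPS fraction.
#' @param seed placement/species seed.
#' @param params,pot force-field objects.
#' @return A `cg_system`.
#' @export
build_planar_patch <- function(n_side = 14, apl = 0.67, ps_fraction = 0.40,
                               seed = 1, params = lipid_params(),
                               pot = protein_lipid_potential()) {
  stopifnot(n_side >= 3, apl > 0)
  set.seed(seed)
  s <- sqrt(apl)
  L <- n_side * s
  n_leaf <- n_side^2
  n_lipids <- 2L * n_leaf
  r0 <- params$bond_r0
  zt <- 0.45 * params$sigma_tail        # tail plane offset from midplane
  Lz <- max(6 * (zt + 2 * r0), 12)
  zc <- Lz / 2
  grid <- expand.grid(ix = seq_len(n_side) - 1, iy = seq_len(n_side) - 1)
  gx <- (grid$ix + 0.5) * s + runif(n_leaf, -0.03, 0.03)
  gy <- (grid$iy + 0.5) * s + runif(n_leaf, -0.03, 0.03)
  leaf <- function(sign) {
    pos <- matrix(0, 3 * n_leaf, 3)
    zs <- zc + sign * c(zt + 2 * r0, zt + r0, zt)  # head, body, tail
    for (k in 1:3) {
      rows <- seq(k, 3 * n_leaf, by = 3)
      pos[rows, 1] <- gx
      pos[rows, 2] <- gy
      pos[rows, 3] <- zs[k]
    }
    pos
  }
  pos <- rbind(leaf(+1), leaf(-1))
  species <- rep("DOPC", n_lipids)
  species[sample.int(n_lipids, round(ps_fraction * n_lipids))] <- "DOPS"
  sys <- .new_system(pos, n_lipids,
                     leaflet = rep(c("outer", "inner"), each = n_leaf),
                     species = species, box = c(L, L, Lz),
                     params = params, pot = pot)
  sys$meta <- list(kind = "planar_patch", apl_geometric = apl,
                   midplane_z = zc, seed = seed)
  sys
}

#' Named system presets
#'
#' `preset("paper_full")` is the full-scale tube system (100 nm tube,
#' 14,500 lipids, 10^7 production steps); `preset("desk_small")` is the
#' scaled-down configuration used by the test-bench runs (30 nm tube,
#' 2 x 10^5 production steps).  The returned list holds `build` arguments
#' for [build_tube()] and `protocol` arguments for [run_protocol()].
#'
#' @param name preset name.
#' @return A list with elements `build` and `protocol`.
#' @export
preset <- function(name = c("desk_small", "paper_full")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "cgtubes")
  yaml::read_yaml(path)
}

#' Minimum inter-site distance
#'
#' Smallest pairwise distance between sites of different lipids (and any
#' protein sites), under periodic boundaries.  Used to verify that built
#' systems contain no overlapping initial condition.
#'
#' @param system a `cg_system`.
#' @return Distance in nm.
#' @export
min_site_distance <- function(system) {
  pos <- system$pos
  box <- system$box
  n <- nrow(pos)
  # coarse cell binning in R; systems are modest at build time
  cell <- 1.2
  key <- paste(floor(pos[, 1] / cell), floor(pos[, 2] / cell),
               floor(pos[, 3] / cell))
  split_idx <- split(seq_len(n), key)
  dmin <- Inf
  lip <- system$lipid_id
  for (idx in split_idx) {
    # compare within cell and against a neighbourhood ball
    ref <- pos[idx, , drop = FALSE]
    cen <- colMeans(ref)
    d2c <- sweep(pos, 2, cen)
    for (k in 1:3) {
      d2c[, k] <- d2c[, k] - box[k] * round(d2c[, k] / box[k])
    }
    cand <- which(rowSums(d2c^2) < (2 * cell)^2)
    for (a in idx) {
      others <- cand[cand > a]
      if (length(others) == 0) next
      same <- !is.na(lip[a]) & !is.na(lip[others]) & lip[others] == lip[a]
      others <- others[!same]
      if (length(others) == 0) next
      dd <- sweep(pos[others, , drop = FALSE], 2, pos[a, ])
      for (k in 1:3) dd[, k] <- dd[, k] - box[k] * round(dd[, k] / box[k])
      dmin <- min(dmin, sqrt(min(rowSums(dd^2))))
    }
  }
  dmin
}
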