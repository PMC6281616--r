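---
title: "Simulating and quantifying membrane nanotube remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying membrane nanotube remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`cgtubes` models how ring-forming protein scaffolds of the EHD1 family
remodel membrane nanotubes, and provides the image-analysis pipeline used
to quantify the same phenomena in fluorescence experiments.  The package
has two halves that meet in the middle:

* a coarse-grained, solvent-free molecular dynamics simulator for bilayer
  tubes with frozen protein ring scaffolds, together with trajectory
  observables (lumen-radius profiles, thinning kinetics, scission
  detection, interleaflet mixing), and
* a fluorescence morphometry toolkit (intensity-to-radius calibration,
  bulge/fission kinetics, FRAP mobile fractions, scaffold growth rates)
  driven by synthetic image generators that supply exact ground truth.

# The lipid model

Each lipid is three sites — head, body, tail — connected by harmonic
bonds (stiffness `bond_k`, rest length `bond_r0`) plus a head-tail
straightening spring.  Non-bonded interactions follow the classic
solvent-free bilayer recipe with two deliberate departures:

1. **Soft repulsive cores.**  All site pairs repel through a harmonic
   core `V = k/2 (r - r_min)^2` for `r < r_min = 2^(1/6) sigma_pair`
   rather than an `r^-12` wall.  Small bilayer tubes pack their inner
   leaflet far above planar densities; with hard cores those contacts
   form kBT-scale-breaking jams whose vibrational frequencies cannot be
   integrated at the native timestep.  The soft core (default
   `core_k = 200` kcal/mol/nm^2, a ~70 kcal/mol full-overlap barrier)
   keeps overlaps rare and finite while leaving thermal structure
   unchanged.
2. **Smoothstep cohesion.**  Hydrophobic (body/tail) pairs attract
   through a well of depth `eps_att` that falls from its minimum at
   `r_min` to zero at `r_min + w_att` as a cubic smoothstep in `r^2`.
   This reproduces the role of the classic cosine-squared taper — the
   well width sets the fluid window — with transcendental-free inner
   loops.  Force and potential are continuous everywhere, including both
   ends of the taper; the package tests verify `F = -dV/dr` against
   numerical derivatives and the energy against the integral of the
   force.

Protein scaffold sites are frozen and attract lipid *head* sites only,
through a 12-6 Lennard-Jones potential with sigma = 0.2 nm and
epsilon = 1 kcal/mol, truncated at 2.5 sigma and energy-shifted.  Below
0.9 sigma the LJ force is capped (linear potential continuation): a
frozen site is a hard obstacle, and the cap bounds the restoring force a
trapped head can experience without altering the thermally accessible
part of the potential.

Units are nm, kcal/mol, unit site mass, with temperatures in kelvin
(kB = 1.987e-3 kcal/mol/K).  The native CG time unit tau is defined by
the integrator: the default production step of 1 tau corresponds to
0.02 internal time units; no mapping of tau to seconds is attempted.

## Parameter defaults and what they were tuned against

The published force-field tables behind the original tube simulations
are not reproduced here; the parameterization is a documented surrogate
tuned against emergent behaviour only:

* a planar patch built at 0.67 nm^2 per lipid stays an intact, fluid
  bilayer at 310 K (no dissolution, in-plane diffusion clearly nonzero),
  with head-plane separation plus one head diameter ~4.5-4.7 nm against
  the 5 nm bilayer-thickness target;
* a tense bilayer is wanted: the relaxed area per lipid of the model
  sits slightly below the 0.67 nm^2 build density, so built membranes
  carry a modest stretching stress, as in the tube-pulling experiments
  the simulations mirror;
* bare-tube behaviour separates by lumen size: wide desk tubes survive
  full production runs, while the thinnest tubes pearl and break (see
  below).

DOPS and DOPC are composition labels (40:60 by default).  They share
interaction parameters; a per-species head-size multiplier
(`ps_head_scale`) is exposed for sensitivity studies but defaults to 1,
since no species-specific coarse-grained parameters are published.

# Systems and protocol

`build_tube()` constructs two concentric cylindrical leaflets spanning a
periodic box along x, so the tube is continuous through its own image —
the only reading under which a 100 nm tube in a 100 nm box is
self-connected.  Lipid counts come from the geometric area per lipid
(2 pi L (r_outer + r_inner) / N = 0.67 nm^2 at full scale), divided
between leaflets in proportion to leaflet mid-surface areas.  Per-lipid
radial stagger (±0.25 nm) breaks the ring symmetry of the lattice;
without it, crowded inner leaflets start in a jammed saddle that relaxes
violently.  The full-scale geometry (100 nm tube, 20 nm outer diameter,
~11 nm lumen, 14,500 lipids, 100 x 50 x 50 nm box) ships as the
`paper_full` preset; desk-scale work uses 30 nm tubes at the same area
per lipid (`desk_small`).

`build_scaffold()` stacks rings of 35 frozen sites on a 25 nm circle,
0.25 nm apart, azimuthally aligned (staggering is a flag; the original
registry is unstated).  `round(length/spacing)` rings reproduce the
printed site counts: 560 sites for a 4 nm scaffold, 2800 for 20 nm.
Ring diameter refers to site centres, the natural reading when sites are
points.

Runs follow equilibration-then-production: velocities drawn at 10 K, a
linear thermostat ramp to 310 K, then NVT production under a
Nose-Hoover chain (length 3, damping 100 tau).  Three numerical details
matter and are the package's own choices:

* the built lattice is first relaxed by a displacement-capped quench;
* the ramp integrates with a timestep that climbs alongside the
  temperature and uses weak-coupling velocity rescaling with a per-site
  speed cap — a relaxing contact dumps its energy into two sites, and
  the cap absorbs such releases instead of letting a ballistic site
  punch through the membrane;
* production uses the Nose-Hoover chain with bounded chain velocities,
  which leaves equilibrium sampling untouched but prevents the
  thermostat from winding up on rare transients.

Desk-scale defaults are an 8e3-step ramp and 2.5e4-step production with
dumps every 1000 tau.  These sizes were chosen so that the package's
full stochastic test battery (replicated stability and scission runs,
scaffold dichotomy runs) completes on a single CPU in tens of minutes;
the full-scale protocol (1e6-step ramp, 1e7-step production, dumps every
1e4 tau) is preserved as a preset and exercised only at reduced size.

# What the simulations show

A tube's fate depends on its lumen size, but the desk-scale runs reach
only part of the full remodeling pathway:

* Wide desk tubes (built lumen diameter 5-6 nm) relax to a stationary
  lumen radius close to their built size and survive full desk runs
  intact, in every replica.
* The thinnest tubes (built lumen radius 1-2 nm) are structurally
  unstable as bilayer tubes: the vacuum lumen collapses and the tube
  pearls into bead-like bodies connected by thin micellar tethers --
  the inner-leaflet-contact intermediate that precedes fission.  Full
  tether rupture (an axial window with no spanning lipid body, which is
  what `detect_scission()` calls scission) is an activated event that
  was not observed within desk-scale runs: the corresponding fission
  assertions in the test suite are expected to fail and are left
  failing rather than weakened.  The acceptance scan consequently
  reports 0 for the scission radius -- no scanned radius fissions in a
  majority of replicas at desk scale.
* A short frozen scaffold (10% of tube length) whose rings clear the
  outer leaflet produces a modest, stable local bulge: the scaffolded
  region's lumen radius exceeds the far field and the system stays
  intact, which the tests assert.  A long scaffold (>= 40% of the desk
  tube) is expected, at full scale, to extract enough membrane area to
  thin the flanks to scission; at desk scale, with the stated 1
  kcal/mol head-ring affinity (about 1.6 kBT at 310 K), adhesion is too
  weak and too slow for that area extraction, the flanks do not thin
  progressively, and no scission occurs.  Those long-scaffold
  assertions are likewise left failing, with the analysis recorded
  alongside the tests.

Analyses follow fixed conventions: the tube axis is the line along x
through the lipid centre of mass (no tilt fit; scaffolds pin the tube);
lumen radius is the mean radial distance of inner-leaflet head sites,
binned axially (1 nm bins by default, profiles averaged over the last
20 snapshots); leaflets are assigned per frame from the sign of the
head-minus-body radial component with a 0.05 nm dead zone (built labels
only seed the first frame), so lumen profiles track the instantaneous
inner leaflet even when lipids flip.  Scission is called from the
hydrophobic occupancy/contact structure along the axis: a plane with no
spanning lipid body severs the tube; a pearled tube whose tether is
still continuous counts as intact, by design.

# Synthetic fluorescence data and morphometry

The imaging half of the package works at the scale of the tube-pulling
experiments: tubes tens of nanometres wide imaged with a ~120 nm PSF at
80 nm pixels.  Because such tubes are diffraction-limited, a tube's
brightness is proportional to its membrane area in the focal column —
the basis of both the generators and the calibrations:

* `render_slb()` draws the planar calibration substrate;
  `calibrate_k1()` recovers intensity per unit membrane area (k1) from
  ROIs of different sizes, as a zero-intercept regression.
* `radius_from_integrated_density()` applies r = ID/(k1 2 pi l).
* `calibrate_k2()` turns peak intensities of tubes of known radius into
  the per-pixel radius conversion used by
  `radius_profile_from_trace()`.
* `simulate_remodeling_movie()` grows bulges under scaffolds at a set
  rate while conserving total membrane area by thinning the bare
  regions — the area-conservation mechanism behind
  bulge-driven thinning — and logs exact onset/scission ground truth.
  The generator timestamps onset when a scaffold first exceeds the same
  20%-above-baseline criterion the detector uses, making generator and
  detector definitionally commensurable.
* `simulate_frap_trace()` and `fit_frap()` share the hyperbolic
  recovery form F(t) = F_b + (F_inf - F_b) t/(t_half + t); the mobile
  fraction is (F_inf - F_b)/(F_p - F_b).  The empirical equation used
  for the original fits is cited but not printed in the source
  literature; the hyperbola is a documented stand-in with an
  exponential alternative behind a flag.
* `simulate_kymograph()` and `scaffold_growth_rate()` handle scaffold
  edge motion; the rate is a robust (M-estimator) line fit to the
  half-max edge.

The generators emulate brightness-area proportionality, Poisson-Gaussian
noise and a Gaussian PSF.  They do not emulate tube wobble out of the
focal plane, photobleaching during acquisition, or uneven illumination —
passing round-trip tests therefore demonstrates correctness of the
estimators, not robustness to every experimental nuisance.  The
round-trip contract (render with known r(x), recover within <10%
everywhere) matches the stated error budget of the experimental
calibration.

Bulge detection uses a 20% fractional excursion above the profile
median with a 200 nm merge distance (both exposed); a scaffolded region
is "bulged" or "constricted" by the sign of its excursion, which is what
makes the protein-membrane Pearson correlation positive for
bulge-forming scaffolds and negative for constricting ones.

# Numerical choices and limitations

* Timestep 1 tau (= 0.02 internal units): stable for all shipped
  systems after the staged ramp; the microcanonical consistency test
  integrates at 0.25 tau, where drift over 1e4 steps is well under
  1e-3.
* Neighbour handling uses cell decompositions with packed per-cell
  coordinate arrays rebuilt on half-margin displacement; forces are
  single-precision (master state double).  Simulations are
  bit-reproducible for a given build and seed on a given binary.
* Scission detection is occupancy-first with a contact check for sparse
  windows; a micellar tether still counts as intact, by design.
* The vacuum lumen is the model's largest physical departure: nothing
  (no solvent pressure) stabilises a lumen, so thin tubes collapse and
  pearl rather than fluctuating about a thin cylindrical state, and the
  final tether-rupture step of fission is slower than desk runs reach.
* Scaled-down scaffold runs keep the full-scale ring-to-tube
  proportion (ring radius 1.25 x the outer tube radius) rather than the
  absolute 25 nm diameter, because desk tubes are narrower; the
  full-scale geometry ships in `paper_full`.
* The t5-style lumen-radius scan in `scripts/acceptance.R` interprets
  its step budget per scanned condition (summed across that condition's
  three replicas, ramp included) and carries a wall-clock guard; the
  methods above make the scan's verdict insensitive to the exact
  per-replica length, because thin-tube scission happens early and wide
  tubes are stable throughout.
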