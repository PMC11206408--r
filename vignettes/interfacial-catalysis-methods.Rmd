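---
title: "Methods: membrane-interface geometry, free-energy profiles and pathway kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane-interface geometry, free-energy profiles and pathway kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spla2kit)
```

## What the package models

Secreted phospholipase A2 (sPLA2) enzymes hydrolyze the sn-2 ester bond of
membrane phospholipids. They only become highly active once docked onto a
lipid interface, and two catalytic mechanisms have been proposed for the
chemical step: a *single-water* pathway, in which one water molecule is
activated by the catalytic histidine and attacks the ester carbon, and an
*assisting-water* pathway, in which a second water shuttles the proton
between the nucleophile and the histidine. `spla2kit` implements the
trajectory-analysis side of that question: given simulation coordinates
(or synthetic stand-ins with the same statistical structure), it
quantifies how the enzyme sits in the bilayer, how water populates the
active site, which catalytic microstates occur and how often, how biased
sampling converts into free-energy profiles, and how populations and
barriers combine into an observable rate difference between pathways.

Everything is tibble-first: analysis functions take a tidy trajectory
table and return tibbles (or small S3 result objects with `tidy()`,
`glance()` and `autoplot()` methods), so pipelines compose with the pipe.

## Units and constants

Coordinates are in angstrom, times in ps, energies in kcal mol^-1,
charges in elementary-charge units, temperatures in kelvin. The default
temperature everywhere is 310.15 K. Constants are CODATA 2018:
k_B = 1.380649e-23 J/K, h = 6.62607015e-34 J s,
R = 1.987204e-3 kcal mol^-1 K^-1, Coulomb prefactor
332.0637 kcal A mol^-1 e^-2. At 310.15 K, RT = 0.61633 kcal/mol and
k_B T / h = 6.462e12 s^-1; these two numbers make the kinetics
reproductions bit-stable.

## Membrane-interface geometry

The bilayer reference is the *upper-leaflet phosphate plane*: per frame,
the mean and standard deviation (population convention) of the z
coordinates of upper-leaflet P atoms. Penetration depth of a residue is
`dz = mean_z(P) - z(cog)`, with an unweighted center of geometry; the
sign convention (documented in the output attributes) is that positive
`dz` means buried below the plane. A residue is flagged buried when its
deepest excursion passes the pooled `mean - sigma` level of the plane,
i.e. `max_dz > sigma`; contiguously numbered flagged residues merge into
hotspots. Pooled (all-frame) statistics are used for the sigma band; a
per-frame sigma would flag transient noise rather than persistent burial.
Leaflet assignment is static (P atoms above the time-averaged box
midplane), since lipids do not flip between leaflets on the timescales
analysed.

In-plane structure is summarised by an xy histogram over frames,
optionally smoothed with an isotropic Gaussian. Smoothing pads the grid
with zeros to at least four kernel widths and uses a renormalized
truncated kernel, so total mass is conserved exactly - a property the
tests assert rather than assume.

## Solvation

`rdf()` computes g(r) around an atom or a two-atom midpoint (recomputed
per frame), with minimum-image distances and reference density
`rho = N/V` pooled over frames; the cumulative count `n(r)` is reported
alongside, and the quadrature identity
`n(r) = rho * integral g 4 pi s^2 ds` is a test invariant.
`shell_statistics()` counts waters in `[r_lo, r_hi)` either exactly from
the trajectory or from an RDF by quadrature; the two-shell defaults
(2.5-3.2 and 3.2-4.4 A) follow the first and second hydration shells of
the His/substrate midpoint in this system. SASA uses the Shrake-Rupley
construction - 960 golden-spiral points on each solvent-expanded sphere,
Bondi radii (overridable), probe 1.4 A. On an isolated sphere the method
is exact by construction; tests also pin monotonicity under approaching
neighbors.

## Catalytic-microstate classification

Each frame's candidate waters (oxygen within 8 A of the substrate carbon,
a performance guard) are scored by three distances: the His-water
hydrogen bond d(Nd-H) (minimum over the water's two hydrogens), the
attack distance d(C-O), and the water-water bridge d(O_W1-H_W2) (minimum
over the donor's hydrogens). A frame is `single_water` if one water alone
passes d(Nd-H) < 2.5 and d(C-O) < 4.0 A; failing that, `assisting_water`
if a nucleophile/donor pair passes d(C-O_W1) < 4.0, d(Nd-H_W2) < 2.5 and
bridge < 2.5 A; otherwise `nonproductive`. All inequalities are strict -
boundary geometries fall into `nonproductive` - and the single-water test
takes precedence because the categories are reported as disjoint
alternatives. The classifier is validated frame-by-frame against a
brute-force enumeration over all waters and pairs.

Microstate clustering works on the d(Nd-C) vs d(Ca-O_POPC) plane: a
binned kernel-density estimate (Gaussian width `kde_sigma`, grid spacing
`kde_sigma/3`), a density level at the `density_quantile` of the strictly
positive grid cells, 8-connected components above the level, and record
assignment by cell membership (below-level records are noise). The
quantile runs over positive grid cells rather than record densities so
that well-separated clusters of very different weight - a 6% minority
cluster next to two large ones - survive thresholding.

## Umbrella sampling and WHAM

`umbrella_window()` carries one biased simulation's collective-variable
series with its harmonic bias; `time_block_check()` splits the retained
series into equal blocks and compares each block's histogram to the
pooled one by the Bhattacharyya coefficient (equilibrated when all blocks
reach 0.9). The default discard fraction is 0.2 of the series, matching
the production convention of dropping 2.5 of 12.5 ps.

`wham_solve()` iterates the standard self-consistency equations on a
fixed grid (default bin 0.05 A) until the largest window-offset change
falls below 1e-7 kcal/mol. Empty terminal bins are truncated; empty
interior bins are kept as `NA` with a warning rather than given infinite
free energy. The profile is zeroed at its minimum. `profile_features()`
locates the reactant and product minima inside user-stated ranges and the
transition state as the interior maximum between them.

The synthetic side feeds WHAM with Metropolis Monte Carlo samples from
`F(x) + k/2 (x - x0)^2`. Only the stationary distribution matters for
WHAM validation, so a Markov chain sampler suffices. The proposal width
defaults to optimal Metropolis scaling, `2.4 sqrt(RT/k)` per window
(about 2.4 times the stationary spread of the biased target, acceptance
~0.4). A fixed narrow proposal would inflate the integrated
autocorrelation time and with it the window-stitching random walk that
dominates the error of the reconstructed profile; with optimal scaling,
24 windows of 10^4 retained samples recover a planted 17.0 kcal/mol
barrier and a -7.9 kcal/mol well offset to about +/-0.15 kcal/mol across
seeds.

The 1-D double-well test surface is piecewise-cosine: minima at
+/- separation/2 (energies 0 and `offset`), an interior maximum of
exactly `barrier`, and curvature-matched harmonic walls outside - so the
planted features are exact by construction, not fitted. Only 1-D WHAM is
implemented; a two-CV case is projected onto its band coordinate before
reconstruction.

## CI-NEB on analytic surfaces

`neb_optimize()` relaxes a chain of images under improved-tangent
(upwind) NEB forces with a FIRE-style damped-dynamics optimizer, and
switches the highest image to climbing mode (inverted parallel true
force, no spring) once the force norm drops below ten times the final
tolerance (default 1e-4). Endpoints never move. The module works on
arbitrary-dimension coordinates with analytic gradients; molecular
forces are out of scope. `verify_saddle()` accepts a point only when its
gradient norm is below tolerance and its central-difference Hessian has
exactly one negative eigenvalue. The default 2-D benchmark is a
three-well/one-barrier Gaussian sum whose stationary points are located
by `find_stationary_points()` (dense grid + Newton refinement), never
hard-coded; the climbing image is required to agree with that independent
search to 0.01 length units.

## Kinetics

`eyring_rate()`/`eyring_barrier()` convert between barriers and rates
with a transmission coefficient of one. `kcat_from_specific_activity()`
turns an interfacial assay activity (umol min^-1 mg^-1) into a turnover
number via the enzyme molar mass; the default 13.9 kg/mol is the mature
~124-residue human group IIA enzyme, a constant activity assays usually
leave implicit, so it is an explicit argument here. `compare_pathways()` weights
each pathway's Eyring rate by the population of its productive reactant
conformation, reports the fast/slow ratio both raw and rounded to one
significant figure (the precision such estimates are usually quoted at),
and decomposes the effective `ddG = RT ln(ratio)` exactly into a
population term and a barrier term. A zero population is reported as an
infinite ratio with a flag rather than an error.

## Per-residue energetics

`residue_deletion_scan()` computes, for every MM charge group,
`ddEa = E_int(group, TS) - E_int(group, R)` with vacuum point-charge
Coulomb sums (no cutoff, dielectric 1), each state using its own
geometry. Negative values mark transition-state-stabilizing residues. The
sign convention is declared in the output rather than inferred, and the
decomposition is exactly additive: summing `ddEa` over groups returns the
total interaction-energy difference to machine precision. This
point-charge realization approximates deletion single-points that would
otherwise need full QM/MM energies - a documented fidelity limit, not an
approximation the tests hide. `axis_projection()` supplies the display
axis: the difference between a group's distances to the proton-receiving
and proton-donating references, which splits the protein into two regions
about the dividing plane.

## The synthetic-data generators

The generators are pure functions of (spec, seed) and exist so every
stage is testable without production simulations.

* **Membrane fixture**: upper/lower-leaflet P atoms at
  `z ~ Normal(+/- plane_z, plane_sigma)` and one cog marker per residue at
  `plane_z - depth_mean + noise`; xy uniform. The default residue-depth
  table plants five contiguous buried runs (residues 1-6, 16-20, 30,
  62-65, 111-116) in a 124-residue protein, emulating the hotspot
  structure of a membrane-docked sPLA2. It does not emulate lipid chain
  packing, curvature or protein shape - so passing tests demonstrate the
  depth/hotspot arithmetic, not membrane physics.
* **Active-site fixture**: each frame draws a state from
  (0.75, 0.04, 0.21) for single-water / assisting-water / nonproductive,
  draws the state's catalytic distances from truncated Gaussians
  (single-water water-Ca 3.6 +/- 1.5 A; assisting-water 4.8 +/- 0.2 A;
  the remaining laws are package defaults chosen to sit well clear of the
  classification thresholds), and realizes them by explicit geometric
  placement: His Nd at the origin, substrate C on +x, waters by
  sphere-sphere trilateration, then a uniform random rotation of the
  whole site and uniform bulk waters outside a 6 A exclusion zone. The
  headline water-Ca distance is drawn *first* and the nuisance distances
  are redrawn until the triangle inequalities admit a solution; the
  carbonyl direction and the H-bond bend are additional free construction
  parameters solved for feasibility. This keeps the headline marginal
  nearly intact: its hard geometric reach truncates the law to
  [0.1, 7.6] A (~1.2% of the mass), which by the truncated-normal moment
  formulas depresses the recovered sd to ~1.43 - the price of demanding
  that a water simultaneously hydrogen-bond the histidine and sit at the
  attack distance. In nonproductive frames the water-Ca distance is
  emergent rather than drawn. Frames whose draws remain contradictory
  after the retry budget raise a construction error naming the offending
  distances.
* **Charge fixture**: reproducible QM charge sets for reactant and
  transition state (identical charges, shifted geometry) plus MM residue
  groups at 6-12 A, so deletion-scan identities (zero for identical
  states, linearity in charges, additivity) have closed-form answers.

## Problem sizes and tolerances

The shipped tests run the full chain at sizes a laptop handles in
minutes: 24 windows x 10^4 retained samples for the double-well WHAM
recovery (+/-0.3 kcal/mol), 5000 frames for classification recovery
(+/-2% on fractions, +/-0.1 A on distance summaries), 400-2000 frames
for membrane statistics, 16 images for CI-NEB (0.01 length-unit
agreement with the grid saddle), 960 sphere points for SASA (1% on the
analytic sphere). `scripts/acceptance.R` re-runs the same computations
from scratch at these sizes and writes the headline numbers as JSON.

## Known limitations

* PDB support covers the fixed-width ATOM/HETATM/MODEL/CRYST1 subset the
  pipeline needs; no altLoc, insertion codes or triclinic boxes.
* WHAM is 1-D; no MBAR, no 2-D surfaces, no statistical error bars on
  the profile beyond the block diagnostics.
* The residue-deletion energetics are vacuum point-charge sums; no
  polarization or dielectric screening.
* The NEB module requires analytic gradients; it is a test-surface
  optimizer, not a molecular one.
* The generators reproduce the statistical structure the analyses
  consume, not physical water structure or lipid conformations; recovery
  tests validate the estimators, not the simulations they stand in for.
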