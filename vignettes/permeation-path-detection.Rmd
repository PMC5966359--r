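---
title: "Locating ion permeation paths by 3D scale-space ridge detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating ion permeation paths by 3D scale-space ridge detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionpath)
```

## The problem

In an equilibrium molecular-dynamics simulation of an ion channel, permeating
ions wander through the pore along whatever route the protein's electrostatics
and sterics favor. For symmetric (e.g. homotetrameric) channels that route is
well approximated by the pore axis, but in channels with an asymmetric
selectivity filter — such as eukaryotic voltage-gated sodium channels, whose
DEKA constriction site places an aspartate, a glutamate, a lysine and an
alanine at four inequivalent positions — ions hug one side wall and no axis
of symmetry describes their motion. `ionpath` recovers the *most probable
permeation path* directly from the simulated ion positions: the positions are
accumulated into a 3D probability density map, and the axes of the elongated
high-density regions of that map are extracted as ridge curves. The same
machinery applies to any non-negative volumetric signal; tracing filament-like
features in a medium-resolution cryo-EM map (helix axes follow strong density)
is the same computation applied to an experimental map read with `read_mrc()`.

Throughout, coordinates follow the pore-axis convention: Z is the membrane
normal with Z = 0 at the protein's center of mass, and all lengths are in
Angstrom. Inputs are assumed unwrapped and centered; the trajectory validator
rejects per-frame coordinate jumps above 20 A rather than attempting
periodic-image reconstruction.

## From trajectory to density map

`filter_valid_samples()` keeps ions during contiguous dwells inside the
selectivity-filter slab, by default $-5\,\mathrm{\AA} < Z < 20\,\mathrm{\AA}$
for at least 1 ns. Dwells are evaluated at frame resolution: a dwell of $n$
consecutive in-region frames at interval $\Delta t$ has duration
$(n-1)\,\Delta t$, a single-frame visit has duration 0, and a one-frame exit
breaks the dwell. We read "stayed within" as contiguous residence; a
cumulative variant (total in-region time per ion) is available via
`mode = "cumulative"` for sensitivity checks.

`build_density_map()` histograms the filtered positions on an isotropic grid
(default voxel 0.5 A), optionally convolves with an isotropic Gaussian
(default 1.0 A), and normalizes to unit integral. The defaults trade
sub-Angstrom path resolution against per-voxel counting noise at the sample
sizes a few hundred nanoseconds of trajectory provides; smoothing sigma 0
reproduces a pure histogram. The grid covers the samples plus a margin of at
least three smoothing sigmas so that the kernel never truncates against the
box.

Contour envelopes summarize where the mass sits: `contour_level_for_fraction()`
returns the highest level whose superlevel set holds a stated fraction of the
probability mass, computed by sorting voxel masses in descending order and
accumulating. This makes nesting automatic — the 60% envelope lies inside
70%, inside 80%, inside 90% — which is the property that lets a drifting
envelope center reveal asymmetric ion entry. "Fraction of the density" could
also mean fraction of the raw sample points; both readings agree for smooth
maps, and the raw-count variant is available via `weight = "count"`.

## Ridge detection in scale space

A *curve ridge* of a 3D scalar field is a one-dimensional locus that is
locally maximal in the two directions transverse to its tangent. At a ridge
point the Hessian has two negative eigenvalues
$\lambda_1 \le \lambda_2 < 0$ whose eigenvectors $e_1, e_2$ span the
transverse plane, the gradient's projections onto $e_1$ and $e_2$ vanish,
and the tangent is the remaining eigenvector $e_3$.

`build_scale_space()` computes Gaussian-smoothed volumes and all first and
second Gaussian-derivative volumes at a ladder of scales $\sigma$ (default:
12 logarithmically spaced values from 0.6 to 4.8 A, bracketing plausible
pore-tube widths at 0.5 A voxels). Derivatives are true Gaussian-derivative
kernels, applied separably as one banded matrix multiplication per axis, not
finite differences of smoothed data. The sampled kernels are moment-corrected
so the discrete operators are exact on low-order polynomials: the smoothing
kernel sums to 1, first-derivative kernels are zero-sum with unit first
moment, second-derivative kernels are zero-sum with second moment 2. This
makes the response to constant maps exactly zero (also at clipped boundary
rows) and keeps analytic test oracles — the Gaussian semigroup law, the
closed-form tube Hessian — within a percent or two on modest grids.

Strengths are compared across scales with the scale-normalized measure

$$ S(\mathbf{x}, \sigma) \;=\; (\sigma^2)^{\gamma}\,\bigl|\lambda_1\,
\lambda_2\bigr| \quad (\lambda_2 < 0, \text{ else } 0), $$

the product of the two transverse curvatures under the normalization that
makes the maximizing scale track feature width ($\gamma = 0$ removes the
prefactor entirely). The default $\gamma = 0.75$ follows the classical
recommendation for ridge detection with scale selection; it is exposed in
every entry point for sensitivity analysis.

`detect_ridge_points()` accepts a voxel at a scale when (i) both transverse
eigenvalues are negative and the anisotropy gate $|\lambda_2| \ge 2\,
|\lambda_3|$ holds, (ii) the gradient projection onto each transverse
eigenvector changes sign between the two neighbors one voxel away along
$\pm e_i$ (trilinear interpolation), (iii) the strength is a local maximum
over neighboring scales, and (iv) the strength reaches a relative threshold
(default 10% of the global maximum). Sub-voxel positions come from the
linear zero crossing of the projections; the selected scale is refined by a
log-parabolic fit through the three scales around the maximum. Voxels within
one kernel radius of the grid edge are excluded — derivative estimates there
are untrustworthy — so maps should carry a margin beyond the region of
interest. Degenerate Hessians (constant regions, where eigenvalues are pure
round-off) are floored to zero strength.

### Width and its calibration

The scale $\sigma^*$ of maximal normalized strength encodes the transverse
extent of the feature. For the Gaussian-tube model — cross-section
$\exp(-\rho^2 / 2a^2)$ — the on-axis normalized strength is
$\sigma^{2\gamma} a^4 (a^2 + \sigma^2)^{-4}$, maximized at
$\sigma^{*2} = \gamma a^2 / (4 - \gamma)$. The reported width is therefore
$\sqrt{(4-\gamma)/\gamma}\;\sigma^*$, which recovers $a$ exactly in the
continuum and within 5% over $a \in [1, 4]$ A on the default scale grid
(the log-parabolic refinement is what keeps the discretization error inside
that band). The width measures the ion's positional fluctuation
perpendicular to the path — one transverse standard deviation — and is what
later sets umbrella-window restraint radii.

### A known degeneracy

A perfectly isotropic blob admits no curve ridge through its core (the
anisotropy gate rejects $r < \sigma/\sqrt{2}$), but on the thin shell where
the radial curvature crosses zero the eigenvalue signature of a curve ridge
reappears and a ring of spurious points can survive. Second-order local
information genuinely cannot distinguish that shell from a curved tube; the
principal-curve step resolves it globally, because only the longest linked
curve is returned and shell fragments are short. The unit tests pin this
behavior down so it is a documented property, not a surprise.

## Linking ridge points into a path

Detected ridge points are scattered voxel-level samples of the underlying
curve. `build_neighbor_graph()` connects each point to its $k = 8$ nearest
neighbors (undirected, Euclidean weights); `extract_principal_curve()` then
performs a one-dimensional isometric mapping of the largest connected
component: the two points at maximal graph-geodesic distance become the
endpoints, every point receives the geodesic distance from one endpoint as
its 1D coordinate, and ordering by that coordinate linearizes the curve.
Consecutive groups of `smoothing_span = 7` ordered points are locally
averaged (the geodesic endpoints themselves are preserved), which suppresses
the transverse voxel jitter that would otherwise inflate the arclength. An
alternative backend realizes the full classical-scaling eigen-embedding of
the geodesic distance matrix (`backend = "isomap"`); on tube-like clouds the
two orderings agree up to direction reversal, and the tests enforce that.
Ties in endpoint selection are broken lexicographically on coordinates, so
the result is independent of input order; paths are reported
extracellular-to-intracellular (decreasing Z).

The defaults ($k = 8$, span 7) are robust for the $10^2$–$10^4$-point ridge
sets that 0.5 A voxel maps produce; smaller $k$ risks fragmenting the graph,
larger spans shave curvature from tightly wound paths.

## Umbrella windows

`make_umbrella_windows()` divides the path evenly along Z: main window
centers from 17.5 A down to 5.5 A at 1 A spacing (13 windows), plus
extension windows from 22.5 A down to 18.5 A (5 windows) that prolong the
path toward the bulk solution. Main centers are path points interpolated at
each Z — the path must cover the window range monotonically in Z, and a
violation is reported with the offending interval — while extension centers
extrapolate along the path's end tangent (a vertical variant is available;
the choice only matters when the path tilts at its extracellular end). Each
window's cylindrical restraint radius is the mean ridge width within half a
spacing of its center, so the restraint admits the transverse fluctuation
the equilibrium ions actually showed. The window table exports as CSV and as
a JSON restraint specification (center, tangent, radius) for building the
biased simulations downstream; running them, and any free-energy estimation,
is out of scope.

## Trajectory statistics

The remaining analyses quantify selectivity directly from trajectories.
`region_bounds()` estimates a residue-defined slab (e.g. the DEKA site, via
the C$\gamma$, C$\delta$, N$\zeta$ and C$\beta$ side-chain atoms of the four
residues) as `max(mean + sd)` over atoms for the upper bound and
`min(mean - sd)` for the lower, from per-atom Z statistics over frames.
`residence_times()` reports one duration per maximal contiguous run of
frames below a boundary, with the same $(n-1)\Delta t$ convention as the
dwell filter. `ion_trails()` flags ions that ever entered a Z interval.
`coordination_events()` applies the standard first-shell criterion — minimum
ion-to-carboxylate-oxygen distance strictly below 3.1 A (OD1/OD2 for Asp,
OE1/OE2 for Glu) — and `coordination_number()` counts water plus carboxylate
oxygens in the first shell; both cutoffs default to 3.1 A and are
configurable, since hydration-shell conventions vary across force fields.
All boundary comparisons are strict inequalities, matching the strictness of
the distance criterion.

## Synthetic fixtures: what they do and do not show

Every algorithm above is exercised without any MD data by the fixtures
module: `sample_tube_cloud()` draws points at uniform random arclength on an
analytic curve with isotropic Gaussian offsets of standard deviation `sigma`
in the plane orthogonal to the local tangent (plus along-tangent jitter of
the same magnitude), so the cloud's true radial width *is* `sigma` — the
quantity ridge width must recover. `analytic_density_grid()` samples named
closed-form fields (constant, Gaussian blob, straight and helical Gaussian
tubes) for which Hessians, contour radii and ridge loci are known exactly.
`scripted_trajectory()` turns an interval script into a trajectory whose
region occupancy is exact ground truth: an interval $[t_\mathrm{in},
t_\mathrm{out})$ sampled at $\Delta t$ occupies $(t_\mathrm{out} -
t_\mathrm{in})/\Delta t$ frames, so the recoverable dwell duration is
$t_\mathrm{out} - t_\mathrm{in} - \Delta t$ and the round trip through
`residence_times()` is exact, not approximate.

These fixtures emulate the *geometry* of permeation data — elongated clouds,
known widths, known dwell structure — but not its physics: no correlated ion
motion, no anisotropic or position-dependent fluctuation, no density
gradients along the path, no counting noise beyond Poisson. Passing tests
demonstrate that the estimators recover known ground truth under the stated
noise model; they do not validate force fields or sampling adequacy of any
particular simulation. Generator defaults (cloud `sigma` 1 A, frame interval
20 ps) were chosen once to resemble selectivity-filter ion clouds at
sub-Angstrom voxel resolution.

The test and acceptance workloads use problem sizes chosen for thorough
coverage at interactive runtimes: 64³ analytic-tube grids, helix clouds of
$5 \times 10^4$ points, $10^6$-point Gaussian samples for contour
calibration, and 25 random smooth fields of 16³ voxels for the exhaustive
oracle comparison, where a brute-force per-voxel evaluation of the ridge
conditions must match the production detector voxel-for-voxel.

## Numerical choices and limitations

* Scales below half a voxel are rejected (undersampled kernels); kernel
  radius is $\lceil 4\sigma \rceil$ voxels with a floor of 3.
* Eigenvalues are computed everywhere with the closed-form trigonometric
  solver for symmetric 3×3 matrices; eigenvectors only at candidate voxels,
  via LAPACK. Tangent signs are fixed (positive Z component) for
  reproducible output.
* Map I/O is MRC/CCP4 mode 2 (little-endian float32, MRC2014 origin words);
  anisotropic cells are rejected rather than resampled.
* The synthetic generators use R's seeded RNG with local state save/restore,
  and the seed is recorded in the sample metadata; seeded pipeline reruns
  reproduce deterministic outputs checksum-for-checksum.
* Not covered: periodic-boundary unwrapping, variable-bandwidth density
  estimation, 2D or sheet (2-negative-eigenvalue surface) ridges, string
  method refinement, PMF/WHAM or free-energy-perturbation estimation, and
  RMSD/RMSF — standard tooling exists for all of these.
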