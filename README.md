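# ionpath

Ion permeation path detection in 3D probability density maps by
gamma-normalized scale-space ridge analysis.

## What it does, and for whom

Channels with an asymmetric selectivity filter — eukaryotic voltage-gated
sodium channels with their DEKA constriction site are the motivating case —
conduct ions along a route that no symmetry axis describes. Given ion
positions from an equilibrium molecular-dynamics trajectory, `ionpath`
recovers that route as the axis of the elongated high-density region of the
ions' 3D probability density map, together with the statistics needed to
characterize selectivity (dwell filtering, residence times, ion trails,
carboxylate coordination) and to set up umbrella-sampling windows along the
detected path. The ridge machinery applies to any non-negative volumetric
signal, including experimental cryo-EM maps read from MRC/CCP4.

The core is a 3D extension of ridge detection with gamma-normalized
derivatives. At scale $\sigma$, a voxel is a curve-ridge point when the two
transverse Hessian eigenvalues are negative ($\lambda_1 \le \lambda_2 < 0$,
with anisotropy gate $|\lambda_2| \ge 2|\lambda_3|$) and the gradient
projections on their eigenvectors vanish; scales are compared through the
normalized strength

$$ S = (\sigma^2)^{\gamma}\,|\lambda_1 \lambda_2|, \qquad \gamma = 0.75, $$

and the per-point scale of maximal strength yields a width,
$\sqrt{(4-\gamma)/\gamma}\,\sigma^*$, calibrated so that a Gaussian tube of
cross-section standard deviation $a$ reports $a$. Scattered ridge points are
linked into one long continuous curve by isometric mapping: geodesic
distances on a k-nearest-neighbor graph order the points along the curve,
and only the longest curve is returned as the principal path.

## Worked example

Recover a known helical path from a synthetic ion cloud (radius 10 A, pitch
15 A, 2 turns, transverse spread 1 A):

```r
library(ionpath)

hx    <- curve_helix(radius = 10, pitch = 15, turns = 2)
cloud <- sample_tube_cloud(hx, sigma = 1, n = 50000, seed = 1)
map   <- build_density_map(cloud, voxel_size = 0.5, smoothing_sigma = 1)
ridge <- detect_ridge_points(build_scale_space(map))
path  <- extract_principal_curve(build_neighbor_graph(ridge, k = 8), ridge)

map
#> density_map: 70 x 70 x 89 voxels @ 0.5 A, origin (-17.36, -17.82, -6.97), normalized
ridge
#> ridge_points: 945 points (gamma=0.75, rel_threshold=0.10, 12 scales)
path
#> permeation_path: 137 points, length 130.22 A, Z 29.45 -> -0.23 A
```

The recovered length, 130.2 A, is within 1% of the analytic arclength
$2\sqrt{(2\pi \cdot 10)^2 + 15^2} = 129.2$ A, and the median reported width,

```r
median(path$width)
#> [1] 1.442177
```

matches the map's true transverse spread
$\sqrt{\sigma_\mathrm{cloud}^2 + \sigma_\mathrm{smooth}^2} = \sqrt{2} \approx
1.41$ A — the width measures the ion positional fluctuation perpendicular to
the path, smoothing included. Umbrella windows then tile the path along Z
with restraint radii taken from that width profile:

```r
make_umbrella_windows(path, z_hi = 17.5, z_lo = 5.5, spacing = 1,
                      ext_hi = NULL, ext_lo = NULL)
#>   index center_z        x        y    z   radius kind
#> 1     1     17.5 5.001321 8.440128 17.5 1.414377 main
#> 2     2     16.5 7.930725 5.785109 16.5 1.418268 main
#> 3     3     15.5 9.605012 2.161114 15.5 1.461601 main
#> ... 13 windows
```

For real trajectories, start from `read_trajectory_csv()` (or build an
`ion_trajectory()` from any reader, e.g. bio3d), apply
`filter_valid_samples()` for the selectivity-filter dwell criterion
(-5 A < Z < 20 A, at least 1 ns), and proceed identically. The methods
vignette (`vignettes/permeation-path-detection.Rmd`) documents the model,
parameters and numerical choices in full.

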