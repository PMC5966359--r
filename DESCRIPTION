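Package: ionpath
Title: Ion Permeation Path Detection in 3D Density Maps by Scale-Space Ridge Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Locates the most probable ion permeation pathway of a membrane
    channel from equilibrium molecular-dynamics trajectories. Ion positions are
    filtered by a dwell criterion, accumulated into a normalized 3D probability
    density map, and the axes of elongated high-density regions are detected as
    curve ridges using gamma-normalized scale-space Hessian analysis extended
    to three dimensions; scattered ridge points are linked into long continuous
    curves by isometric mapping of graph-geodesic distances. Additional
    trajectory analyses cover region boundaries from side-chain atom
    statistics, residence times, time-dependent ion trails, carboxylate
    coordination events and coordination numbers, density contour envelopes,
    and umbrella-sampling window construction along the detected path with
    cylindrical restraint radii derived from the ridge width.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
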