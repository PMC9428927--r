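Package: romap
Title: Osteological Range-of-Motion Mapping for Ball-and-Socket Joints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the osteologically viable range of motion (ROM) of
    ball-and-socket joints from triangle meshes of the two articulating
    skeletal elements. Spheres and cylinders are fitted to articular
    surfaces to define joint centers and long axes; disarticulated elements
    are rearticulated by superimposing fitted-shape centroids; an anatomical
    coordinate system (ACS) with a fixed XYZ rotation order poses the distal
    element over a regular Euler-angle grid; poses that produce bone-mesh
    interpenetration are discarded by BVH-accelerated triangle-mesh
    collision tests. Viable poses are mapped into a cosine-corrected Euler
    shape space and summarised as alpha-shape volumes (degree^3). Joint
    spacing (a proxy for articular cartilage thickness) can be swept as a
    static translation (4-DOF) or sampled dynamically over the vertices of a
    small offset sphere (6-DOF), and empirical joint-angle traces can be
    tested against a viable-pose envelope. A synthetic joint generator with
    known ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
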