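Package: catchvol
Title: Catchment Volumes of Panoramic Snapshots in Synthetic 3D Worlds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the navigational information carried by panoramic
    snapshots in three dimensions. Procedurally generates outdoor-like 3D
    scenes (textured ground, trees, clutter, hard cast shadows, optional
    distant background sphere), renders six-camera cube-maps at points of a
    regular 3D grid and projects them to 384x192 equirectangular greyscale
    panoramas, computes rotational and translational image difference
    functions (r.m.s. pixel differences), and extracts catchment volumes by
    thresholded steepest-gradient hill climbing over the grid, with a
    continuous gradient-descent variant as a cross-check. Includes
    above-horizon masking and distant-background ablation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
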