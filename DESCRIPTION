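Package: mconn
Title: Mouse Structural and Functional Connectome Analysis on Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for mouse-brain resting-state functional MRI
    and diffusion MRI connectomics, exercised entirely on synthetic phantoms
    with known ground truth. Provides ground-truthed functional (BOLD-like)
    and diffusion phantom generators; temporal concatenation and group spatial
    independent component analysis with automated noise-component screening;
    hierarchical clustering of components into resting-state networks;
    seed-based correlation (default-mode-network) mapping; edge-wise group
    comparison with false-discovery-rate control; diffusion-tensor fitting,
    fractional anisotropy, probabilistic streamline tractography and
    structural connectome construction; and graph-theory characterization
    (proportional thresholding, global and local efficiency, transitivity,
    degree). All stages are deterministic under an explicit seed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
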