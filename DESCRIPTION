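Package: condensateSPT
Title: Intra-Condensate Single-Molecule Tracking Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for single-molecule tracking inside
    biomolecular condensates: spot detection and gap-free linear-assignment
    linking, three-way diffusion classification (immobile, confined, normal)
    from mean step size and the anomalous exponent alpha, motion-blur
    corrected MSD fitting of apparent diffusion coefficients and
    localization error, a state-array diffusion spectrum, localization
    density maps and step-size heatmaps with weighted pixel-wise
    correlation, edge-corrected pair-correlation functions with exponential
    clustering fits and bootstrap, ring-area normalized radial profiles of
    nanodomains, running-window HMM segmentation of diffusion states, and
    characteristic fusion-time fitting of optical-tweezers force traces.
    Includes a synthetic-data generator (trajectories, rendered videos,
    force traces) that provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
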