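Package: coilqa
Title: Quality Assurance Benchmarking of RF Coils for 13C MRI at 3T
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a multi-site quality-assurance protocol for clinical
    carbon-13 radiofrequency coils at 3T. Reconstructs two-dimensional
    chemical shift imaging (CSI) acquisitions of an ethylene glycol phantom
    to per-voxel, per-channel signal estimates at the first J-coupling
    in-phase time point, estimates the channel noise covariance from a
    noise-only acquisition with a noise-equivalent-bandwidth correction,
    extracts complex coil sensitivity profiles by SNR-adaptive Perona-Malik
    anisotropic diffusion, and produces signal-to-noise-ratio maps via
    noise-covariance-weighted (Roemer) coil combination that are comparable
    across volume coils and arrays with different channel counts. Also
    computes array noise-correlation summaries, SENSE geometry-factor maps
    for retrospective uniform undersampling, and transmit-inhomogeneity SNR
    loss estimates. A phantom simulator with Biot-Savart loop sensitivities
    and known ground truth makes every stage testable without scanner data;
    raw and derived data travel in a documented HDF5 container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
SystemRequirements: HDF5 (libhdf5)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
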