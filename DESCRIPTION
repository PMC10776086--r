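Package: axdiam
Title: Axonal Diameter Mapping from Multi-Shell Multi-Diffusion-Time MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and voxelwise estimation of an MRI axonal
    diameter proxy from multi-shell, multi-diffusion-time diffusion-weighted
    data. Implements a multicompartment model with restricted diffusion in
    impermeable cylinders (Gaussian phase distribution), a single-parameter
    Poisson distribution of axon diameters, a diffusion-time-dependent
    extra-axonal compartment, stimulated-echo T1 decay and Rician noise; a
    cascade fitting procedure (DTI, then a stick-model initialisation at the
    shortest diffusion time, then tortuosity-constrained and
    constraint-released stages); BIC-based model selection for the
    diffusion-time and T1 decay forms; synthetic-data generators including a
    two-hemisphere tract phantom; along-tract paired statistics with
    false-discovery-rate correction; and readers and writers for NIfTI volumes
    with bval/bvec/bdelta sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
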