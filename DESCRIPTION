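Package: coevomech
Title: Coupling Sequence Coevolution to Coarse-Grained Protein Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connects mutual-information coevolution signals in multiple
    sequence alignments to reduced biophysical models of the encoded protein.
    Builds sequence-specific anisotropic network models (one bead per C-alpha,
    Miyazawa-Jernigan-weighted springs), obtains covariance matrices by
    Moore-Penrose pseudo-inversion of the Hessian, predicts isotropic
    B-factors, screens non-covalent contacts by breaking them one at a time
    and scoring the mechanical impact with the Frobenius norm of the
    covariance change, and includes a self-consistent pair contact
    probability (SCPCP) solver for temperature-dependent fluctuations and
    finite-size unfolding. Ships a synthetic structure/alignment generator
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    seqinr,
    optparse,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
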