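Package: discoqa
Title: Protein Model Quality Estimation with Template-Derived Distance
    Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-residue and global quality estimates for single 3D protein
    structure models. Combines knowledge-based statistical potentials of mean
    force, sequence-based agreement terms (secondary structure and solvent
    accessibility), and a distance-constraint (DisCo) score that measures the
    agreement of model Calpha-Calpha distances with Gaussian constraint
    ensembles derived from homologous template structures. The components are
    fused by an ensemble of small feed-forward neural networks that tolerate
    missing feature blocks, trained against the superposition-free lDDT score.
    Includes a full synthetic-data generator so the pipeline can be trained
    and evaluated without external downloads, ROC-based evaluation utilities,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
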