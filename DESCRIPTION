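Package: psbind
Title: Phosphorothioate Oligonucleotide-Protein Binding and Stereochemistry Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for protein-phosphorothioate (PS) oligonucleotide
    interaction studies. Implements the 1:1 ligand-binding isotherm with a
    noncompetitive nonspecific term for fluorescence-anisotropy titrations,
    global fitting across replicates with AIC model selection and studentized
    outlier screening; assignment of Rp/Sp configurations at PS linkages from
    atomic coordinates and sulfur anomalous difference density maps; van der
    Waals contact analysis between protein and oligonucleotide; Kabsch
    superposition with iterative outlier rejection; and seeded synthetic-data
    generators (titrations, idealized PS-DNA strands, anomalous maps) for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
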