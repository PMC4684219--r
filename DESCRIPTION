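Package: hotspotRF
Title: Protein Binding Hot-Spot Prediction from Co-Occurring Atomic Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes protein-protein binding hot spots from crystal
    structures. Builds beta-skeleton atomic contact graphs across an
    interface (with aromatic-ring pseudo-atoms and buried-water handling),
    normalizes crystallographic B factors, derives a 143-element descriptor
    per alanine mutation (B-factor and accessibility features, typed atomic
    contacts, and co-occurring contact pairs within three covalent-bond
    steps), and regresses the binding free energy change upon mutation with
    a random forest evaluated by leave-complex-out cross-validation. A
    synthetic-complex generator with planted contact geometry supports fully
    hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
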