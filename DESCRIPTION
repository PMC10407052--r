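Package: numsense
Title: Group Coding of Visual Numerosity in Classifier Layers of Object-Recognition Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how the number of objects in a visual scene is
    carried by the joint activation pattern of the category (classifier) layer
    of an object-recognition network. Provides controlled stimulus synthesis
    (mosaics, area-matched elliptical-patch scenes, noise, clip and
    phase-scramble variants), activation extraction and per-picture
    normalization, group-level mean and standard-deviation summaries with
    decile statistics and resampling, selection of monotonically tuned units
    and a small numerosity-decoding network, a two-alternative numerosity
    comparison task with psychometric curves, embedding-coefficient scoring
    against category activation profiles, and representational similarity
    analysis across agents. Includes seeded synthetic-data generators
    (planted-structure activation sets, procedural toy images, a trainable
    mock backbone, and logistic trial logs) so the whole pipeline runs
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
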