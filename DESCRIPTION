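Package: teleCT
Title: Client-Server Streaming Engine for Remote CT Stroke Reading
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A server-side rendering and streaming engine for remote
    interpretation of head CT, modelled on client-server teleradiology
    for acute stroke. DICOM CT series are reconstructed into calibrated
    Hounsfield-unit volumes; the server renders window/levelled 2-D
    slices, multiplanar reformats and ray-cast 3-D views, and streams
    viewport updates as changed-8x8-block JPEG payloads while keeping
    clients synchronized through diffs of a hierarchical state model.
    Includes a synthetic head-CT phantom generator (skull, parenchyma,
    ventricles, hemorrhage, dense-vessel and occlusion inserts) with
    exact ground truth, and diagnostic-accuracy statistics
    (sensitivity, specificity, accuracy, Cohen's kappa, ASPECTS
    discrepancy rule) for reader studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jpeg, xml2, jsonlite
Suggests: testthat (>= 3.0.0), withr, png, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'dicom.R'
    'volume.R'
    'mpr.R'
    'render.R'
    'codec.R'
    'state.R'
    'phantom.R'
    'server.R'
    'readerEval.R'
    'teleCT-package.R'
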