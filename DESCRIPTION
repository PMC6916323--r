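Package: radsem
Title: Ontology-Annotated Radiomics from DICOM-RT with Semantic Provenance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained radiomics workflow for radiotherapy imaging
    data. Reads DICOM image series and RTSTRUCT structure sets, converts
    planar volume-of-interest (VOI) contours into binary voxel masks on the
    image grid, computes a standard panel of 105 radiomic features across
    seven families (first order, shape, GLCM, GLRLM, GLSZM, GLDM, NGTDM)
    with formulas aligned to the Image Biomarker Standardisation Initiative
    (IBSI), and publishes results as a semantically annotated RDF triple
    graph carrying full computational provenance (software, settings, VOI,
    patient), queryable by basic graph patterns and exportable to CSV.
    Includes a synthetic DICOM phantom generator so the whole pipeline is
    testable without clinical data, plus an independent ray-casting
    rasterization oracle and Dice/concordance agreement measures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
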