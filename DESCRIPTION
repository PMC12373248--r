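Package: chinpoint
Title: Modified Chin Point Analysis for Soft-Tissue Cephalometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for soft-tissue cephalometric analysis of orthognathic
    surgery profiles built around the modified chin point (MCP): a chin
    reference obtained by horizontally projecting the actual soft-tissue
    pogonion (ACP) onto the ray from subnasale that forms a 170 degree angle
    of facial convexity with the glabella-subnasale line. The package fits a
    midsagittal measurement frame from 3D landmarks, performs the MCP
    construction, measures upper- and lower-lip position against the Steiner
    S line and Ricketts E line under both ACP- and MCP-based pogonion, and
    provides the method-agreement statistics (paired tests, exact Wilcoxon
    signed-rank, mean error and mean absolute error, Pearson correlation)
    used to validate MCP as a predictor of the post-surgery profile. A
    synthetic paired-cohort generator with known ground truth supports
    end-to-end testing and parameter-recovery experiments without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
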