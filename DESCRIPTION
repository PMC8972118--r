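Package: emanet
Title: Temporal Dynamic Network Analysis of Ecological Momentary Assessment
    and Actigraphy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and comparing directed lag-1 temporal
    networks from intensive longitudinal data. Covers the full workflow:
    simulation of two-group multilevel VAR(1) ecological momentary assessment
    (EMA) datasets and raw wrist accelerometer traces; conversion of raw
    triaxial acceleration to per-beep physical-activity summaries via the
    Euclidean-norm-minus-one (ENMO) metric with std/range nonwear exclusion;
    rank-based gaussianization (nonparanormal transformation) and
    stationarity diagnostics (two-level autoregressive inertia, per-subject
    KPSS tests); nodewise multilevel VAR(1) network estimation with
    within-person centering; in-/out-strength centrality and overall
    connectivity; and subject-level permutation tests for group differences
    in edges, centrality, and connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
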