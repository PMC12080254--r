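Package: pmtscreen
Title: Screening Detected Organic Compounds for Persistent, Mobile and
    Toxic (PMT/vPvM) Hazard Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-step screening pipeline that classifies organic
    compounds detected in environmental media (e.g. permafrost active-layer
    soils) as persistent, mobile and toxic (PMT) or very persistent and very
    mobile (vPvM) under the EU CLP-derived cutoff criteria. Compounds are
    resolved by known-list lookup, by rule-based assessment of experimental
    freshwater half-lives, pH-resolved log Koc and toxicity flags, or - when
    experimental data are missing - by a tree-ensemble classifier gated by a
    Euclidean-distance applicability domain and interpreted with exact
    tree-SHAP attributions. Downstream tools compute MACCS structural-key
    fingerprint prevalence tables, origin-stratified contrasts, molecular
    descriptor sets, and concentration summaries, and a motif-grammar
    simulator generates fully labelled synthetic rosters so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
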