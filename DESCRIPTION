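Package: chanatomy
Title: Detection and Anatomy of Enzyme Active-Site Access Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voronoi-diagram based detection of access channels connecting
    buried enzyme active sites to the protein exterior: a clearance-annotated
    void graph is built on the Delaunay triangulation of the atomic centers
    and traversed with Dijkstra's algorithm. Channels are characterized
    geometrically (length, radius profile, bottleneck, local minima) and
    physico-chemically (length-weighted Kyte-Doolittle hydropathy, Zimmerman
    polarity, charge census of the lining residues, internal/middle/external
    layers), and cohorts of structures are aggregated into occurrence tables,
    amino-acid channel propensities and compartment compositions. A
    synthetic-structure generator plants tunnels of known geometry and lining
    composition in protein-like sphere packings so the whole pipeline can be
    validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
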