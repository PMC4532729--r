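Package: migpatterns
Title: Migration Patterns of Structured Populations as Spherical
    Tessellations and Polytope Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents gene-flow among geographically structured populations
    as weighted Voronoi/Delaunay patterns on the unit sphere and their temporal
    dynamics as paths on polytope complexes.  Provides a brute-force spherical
    Delaunay triangulation with circumcircles and inner intersection angles,
    validation of circle-pattern (Rivin) angle conditions, sphere-embedded
    multigraphs as combinatorial maps with contraction, expansion and Whitehead
    moves, enumeration of the combinatorial space of migration graphs,
    H-polytopes for per-population load and angle systems with feasibility,
    interior points and vertex enumeration, assembly of the polytope complex of
    labelled cubic graphs, and population split/merge dynamics.  Ships the
    eight-population Sumba (eastern Indonesia) worked example with FST-based
    edge weights as a plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
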