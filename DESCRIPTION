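Package: photosub
Title: Enhanced-Sampling Analysis of Ligand Photosubstitution on Triplet
    Free-Energy Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying light-induced ligand exchange in ruthenium
    polypyridyl complexes on the triplet hypersurface. Provides a Langevin
    sampler for analytic model potentials under combined umbrella-sampling and
    well-tempered metadynamics bias, WHAM reconstruction of two-dimensional
    free-energy surfaces over the Ru-S and Ru-O(water) reaction coordinates,
    classification of cis/trans attack geometries and of
    dissociative/interchange/associative substitution mechanisms, chelate
    planarity and rigidity descriptors from the inter-plane dihedral of the
    bidentate ligand, and the rank-correlation and regression analyses linking
    descriptors to photosubstitution quantum yields. Ships the photophysical
    and computed-barrier tables for a nine-complex series as fixtures.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
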