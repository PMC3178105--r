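Package: binqtl
Title: Binary-Trait Linkage Mapping in F2 Intercrosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping a binary trait in an F2 intercross, built
    around the design of a zebrafish sex-determination cross: genetic-map
    construction from two-point recombination fractions (EM estimation,
    linkage grouping, collapsing of co-segregating markers, marker insertion
    with LOD support), hidden-Markov-model genotype-error detection
    (per-genotype error LOD), binary-trait interval mapping with
    permutation-based genome-wide significance thresholds, 1.5-LOD support
    intervals, variance-explained estimates and two-locus penetrance tables,
    plus genetic-versus-physical map diagnostics (sliding-window cM/Mb
    recombination rates, chromosome-assignment and marker-order LOD
    comparisons). A calibrated cross simulator generates F2 genotypes and a
    two-locus binary phenotype so the whole pipeline can be exercised and
    validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
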