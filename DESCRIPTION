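Package: nucleoidwalk
Title: Lattice Monte Carlo Models of Bacterial Chromosome Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A geometrical model of chromosome organization in bacteria such as
    Caulobacter crescentus and Escherichia coli. The chromosome is represented
    as a random walk on a three-dimensional cubic lattice confined to the cell
    volume, either as a non-self-avoiding chain of Kuhn segments (non-compacted
    DNA) or as a self-avoiding chain of blobs (DNA compacted into topological
    domains), with the replication origin and terminus pinned to prescribed
    subcellular positions. Ensembles of configurations with fixed length and
    fixed pinned loci are constructed by hook-insertion growth and sampled with
    the Madras-Orlitsky-Shepp (MOS) move set (bead flips, crankshafts and a
    three-dimensional crankshaft composite). The package provides exact
    enumeration and transfer-matrix oracles for validation on small instances,
    the summary statistics used to characterise spatial ordering (axial
    mean-position profiles, root-mean-square deviation from a linear
    arrangement, plateau onset, correlation-sign fractions, occupation
    densities, chromosome demixing), organism presets and parameter sweeps, and
    a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
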