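Package: fgassembly
Title: Bundle, Pore and Brush Analysis of Coarse-Grained FG-Nucleoporin Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building and analysing bead-level models of
    intrinsically disordered FG-nucleoporin assemblies such as those lining
    the nuclear pore complex central channel.  Provides worm-like-chain
    self-avoiding-walk conformation generators with fixed bond length, fixed
    bend angle and excluded-volume rejection; tethered ring, tethered array
    and free-bath assembly builders; residue contact-graph construction and
    connected-component bundle decomposition with thickness distributions,
    cross-link detection and amino-acid bundle propensities; lattice-based
    pore characterization by maximum-bottleneck (widest) path search;
    polymer brush height, radius of gyration and Shrake-Rupley solvent
    accessible surface area; synthetic assemblies with planted ground truth
    for validating the analyses; and PDB / extended-XYZ input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
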