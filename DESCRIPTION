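Package: modescore
Title: Ranking Protonation and Tautomer Models Against X-Ray Difference Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-refinement scoring of candidate protonation and tautomer
    models of a ligand or residue against X-ray diffraction data. Synthesizes
    sigma-A style difference-density maps from reflection amplitudes and model
    phases, normalizes them to real-space Z scores, and summarizes the signed
    difference density over each atom's footprint with an order-statistic
    chi-square probability maximization (the ZDD metric). Combines ZDD with a
    local strain energy into an ensemble z-score (XModeScore) that ranks the
    candidate modes, and drives resolution-truncation sweeps of the ranking.
    Includes a self-contained synthetic toy-crystal generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
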