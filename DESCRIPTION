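Package: scramblescan
Title: Quantify Lipid Scrambling in Coarse-Grained Membrane Simulations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies lipid scrambling (flip-flop) by membrane
    proteins in coarse-grained molecular dynamics trajectories. Per-lipid
    orientation angles against the membrane normal are tracked on a fixed
    sampling grid and leaflet crossings are counted with a buffered
    two-threshold state machine that is robust to angular noise. Event counts
    are binned per microsecond after an equilibration discard, summarised as
    boxplot statistics and classified against an events-per-microsecond
    cut-off. Companion analyses compute protein-proximal hydrophobic membrane
    thinning from z-density profiles and localise the scrambling pathway onto
    protein residues from headgroup transit positions. A synthetic bilayer
    generator with a ground-truth event ledger allows the full pipeline to be
    exercised and validated without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
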