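Package: gatekeepR
Title: Contact-Based Design of Inhibitor-Resistant Kinase Gatekeeper Mutants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate "gatekeeper" mutation sites in kinases from
    conformational ensembles of inhibitor-bound and nucleotide-bound
    complexes. Close contacts between ligand and protein atoms are counted
    per frame at a distance cutoff (default 4.5 Angstrom) and aggregated
    into per-residue profiles. A multi-stage triage then nominates residues
    that anchor the inhibitor but not the natural nucleotide: proximity
    filtering by frame occupancy, exclusion of backbone-mediated and
    structurally critical residues, differential inhibitor-versus-nucleotide
    contact comparison, removal of low-contact sites, and exclusion of
    positions that vary across the kinase family. A seeded synthetic
    ensemble generator with planted contact propensities supports testing
    of every stage without molecular-dynamics trajectories, and a bundled
    worked example reproduces the MERTK/MRX-2843 selection of L593 and L671.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
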