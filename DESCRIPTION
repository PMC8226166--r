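Package: ptmdimer
Title: Contact, Persistence and Buried-Surface Analysis of Modified
    Histone Tail Peptide Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse the self-association of short, variably
    modified peptides (the histone H3 N-terminal tail being the motivating
    system) from two-chain trajectories stored as multi-model PDB files.
    Provides a PTM-aware formal-charge model for annotated peptide
    sequences (phosphorylation, lysine/arginine methylation, lysine
    acetylation, terminal caps), heavy-atom close-contact detection with
    the N_cc statistic, residue-pair interaction-persistence maps with
    salt-bridge typing, Shrake-Rupley solvent-accessible surface area and
    the buried-area statistic dA = <A1 + A2 - A12>, and a synthetic
    two-chain trajectory generator with exact contact-schedule ground
    truth for validating every analysis stage without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
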