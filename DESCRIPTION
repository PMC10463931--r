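Package: ddpd3
Title: Dynamic Protein Descriptors from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Condenses molecular dynamics trajectories of proteins into
    fixed-length dynamic descriptor vectors for proteochemometric (PCM)
    bioactivity modelling. Per-atom coordinate statistics over sub-trajectories
    are combined with Gasteiger (PEOE) partial charges and reduced by a
    two-stage principal component analysis into residue-specific (rs3DDPD)
    vectors aligned to a multiple sequence alignment, or protein-specific
    (ps3DDPD) embedding-like vectors computed jointly over a set of targets.
    Includes trajectory analysis (RMSD, RMSF, alignment of RMSF profiles to an
    MSA), classical one-hot residue-scale descriptors and folded circular
    fingerprints for compounds, a random-forest PCM/QSAR benchmarking harness
    with random and temporal splits, seed-replicate significance testing and
    the AVE chemical-bias statistic, hierarchical clustering of descriptor
    vectors for variant discrimination, and synthetic fixture generators for
    topologies, trajectories, alignments and bioactivity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    ChemmineR,
    ChemmineOB,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
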