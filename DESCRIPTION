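Package: barriereng
Title: Mechanism-Guided Barrier Engineering of BHET Hydrolases
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for mechanism-guided barrier engineering of
    PET/BHET hydrolases. Designs truncation variants that remove rigid
    barrier segments occluding the substrate binding cleft and bridge the
    junction with a flexible Gly-Gly linker; ranks variants with a weighted
    min-max normalized four-factor docking score (binding energy, hydrogen
    bonds, serine attack distance, cavity volume); computes the structural
    and trajectory observables used to identify barriers and verify
    variants (RMSD, radius of gyration, per-residue RMSF, solvent
    accessible surface area, substrate/water site occupancy, Ser-carbonyl
    distance series, spatial distribution grids, grid-based cavity
    volumes); and evaluates the wet-lab-side models (first-order thermal
    inactivation and half-life, DSC percent crystallinity, BHET purity and
    yield, theoretical maximum hydrolysis yield, Michaelis-Menten kinetics,
    fold-change summaries). Ships seeded synthetic-data generators for
    every stage so the whole pipeline is testable without external
    structures or trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
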