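Package: cavitherm
Title: Binding-Site Hydration and Calorimetric Thermodynamics of
    Protein-Ligand Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for dissecting ligand specificity of
    substrate-binding proteins from two complementary angles: single-site
    isothermal titration calorimetry (peak integration, dilution
    subtraction, nonlinear isotherm fitting, derived Kd/dG/dS, cross-ligand
    ddH/ddS comparison) and binding-cavity hydration (per-frame water
    census, pairwise Lennard-Jones/Coulomb per-water potential energies,
    bulk-water reference, desolvation penalty score). Also provides
    protein-ligand contact chemistry (hydrogen bonds, van der Waals
    contacts), Kabsch superposition, conserved-water matching between
    complexes, and a synthetic-data module that generates ITC thermograms
    and labeled solvated-pocket configurations with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
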