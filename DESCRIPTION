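Package: dockrank
Title: Docking Post-Processing, Thermodynamics and Ligand-Efficiency Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Post-processing of multi-crystal molecular docking campaigns for
    structure-based ligand prioritization. Converts estimated binding free
    energies to inhibition constants and pKi, screens compound libraries with
    the Lipinski rule of five, aggregates run-level docking scores per
    receptor crystal and per target with standard errors and confidence
    intervals, computes Abad-Zapatero binding-efficiency and lipophilicity
    indices (NSEI, NBEI, nBEI, mBEI, LLE), and selects lead compounds from
    bivariate efficiency plots. Includes a synthetic docking-campaign
    generator with known ground truth and a bundled berberine-derivative
    RAF-kinase reference dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
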